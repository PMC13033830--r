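# Shared fixtures and independently coded oracles.

# small cohort for fast unit tests
tiny_cohort <- function(n = 40, seed = 1, embeddable = TRUE, ...) {
  simulate_cohort(cohort_config(
    n_patients = n, seed = seed,
    stream_dims = c(wsi_deep = 6, wsi_morph = 5, wsi_top = 4,
                    us_deep = 5, us_omic = 7, us_text = 4),
    n_wsi_patches = 3, n_us_tokens = 3, ...))
}

tiny_fusion <- function(E = 8, ...) fusion_config(embed_dim = E, dropout = 0, ...)

# random cross-attention parameter set (dense, nonzero output map)
rand_ca_params <- function(E, seed = 1) {
  set.seed(seed)
  r <- function(a, b) matrix(rnorm(a * b, sd = 0.5), a, b)
  list(Wq = r(E, E), bq = rnorm(E, sd = 0.1),
       Wk = r(E, E), bk = rnorm(E, sd = 0.1),
       Wv = r(E, E), bv = rnorm(E, sd = 0.1),
       Wo = r(E, E), bo = rnorm(E, sd = 0.1))
}

# prefix a CA parameter set the way the network expects (ca_<stage>_*)
prefix_ca <- function(p, stage) {
  stats::setNames(p, paste0("ca_", stage, "_", names(p)))
}

# independently coded dense scaled-dot-product cross-attention
# (plain matrix algebra, no shared code with the tape implementation)
oracle_ca <- function(Q, K, p, n_heads = 1) {
  Qp <- sweep(Q %*% p$Wq, 2, p$bq, "+")
  Kp <- sweep(K %*% p$Wk, 2, p$bk, "+")
  Vp <- sweep(K %*% p$Wv, 2, p$bv, "+")
  E <- ncol(Qp); dh <- E / n_heads
  out <- NULL
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    S <- Qp[, cols, drop = FALSE] %*% t(Kp[, cols, drop = FALSE]) / sqrt(dh)
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    out <- cbind(out, A %*% Vp[, cols, drop = FALSE])
  }
  sweep(out %*% p$Wo, 2, p$bo, "+")
}

# brute-force O(n^2) Harrell concordance oracle
oracle_cindex <- function(risks, time, event) {
  conc <- 0; comp <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      comp <- comp + 1
      if (risks[i] > risks[j]) conc <- conc + 1
      else if (risks[i] == risks[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# literal O/E/V log-rank tabulation over pooled event times
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a == 1], time_b[event_b == 1])))
  O <- E <- V <- 0
  for (s in times) {
    n1 <- sum(time_a >= s); n2 <- sum(time_b >= s)
    d1 <- sum(time_a == s & event_a == 1); d2 <- sum(time_b == s & event_b == 1)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    O <- O + d1
    E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chi_square = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# product-limit estimator by hand
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ts, surv = surv)
}

# Breslow partial-likelihood score for a binary covariate at coefficient b
oracle_cox_score <- function(b, g, time, event) {
  o <- order(time)
  g <- g[o]; tt <- time[o]; ev <- event[o]
  sc <- 0
  for (i in which(ev == 1)) {
    rs <- which(tt >= tt[i])
    w <- exp(b * g[rs])
    sc <- sc + g[i] - sum(g[rs] * w) / sum(w)
  }
  sc
}

random_survival_fixture <- function(n, seed, cens_prob = 0.3, tie_prob = 0.2) {
  set.seed(seed)
  time <- round(rexp(n, 0.1), ifelse(runif(1) < tie_prob, 0, 2)) + 0.1
  list(time = time,
       event = rbinom(n, 1, 1 - cens_prob),
       risks = rnorm(n))
}
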