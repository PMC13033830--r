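# Survival metrics against brute-force and tabulation oracles.

test_that("concordance index handles the canonical examples", {
  expect_equal(concordance_index(-(1:5), 1:5, rep(1, 5)), 1)
  expect_equal(concordance_index(rep(0.3, 5), 1:5, rep(1, 5)), 0.5)
  # pairs (1,2) and (1,3) concordant, (2,3) discordant
  expect_equal(concordance_index(c(3, 1, 2), c(1, 2, 3), c(1, 1, 0)), 2 / 3)
  expect_error(concordance_index(1:3, c(2, 2, 2), c(0, 0, 1)), "comparable")
})

test_that("concordance matches the brute-force pair count on 100 fixtures", {
  for (s in 1:100) {
    n <- sample(5:50, 1)
    fx <- random_survival_fixture(n, seed = 1000 + s)
    if (sum(fx$event) == 0) fx$event[1] <- 1
    got <- tryCatch(concordance_index(fx$risks, fx$time, fx$event),
                    error = function(e) NA)
    want <- oracle_cindex(fx$risks, fx$time, fx$event)
    if (is.nan(want)) next
    expect_identical(got, want)
  }
})

test_that("concordance agrees with the survival package and is rank-invariant", {
  # continuous times (no ties): the package counts only strictly ordered
  # pairs as comparable, so tie-free fixtures are the common ground
  set.seed(3)
  fx <- list(time = rexp(80, 0.1), event = rbinom(80, 1, 0.7), risks = rnorm(80))
  ours <- concordance_index(fx$risks, fx$time, fx$event)
  ref <- survival::concordance(survival::Surv(fx$time, fx$event) ~ fx$risks,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_equal(concordance_index(exp(3 * fx$risks), fx$time, fx$event), ours)
})

test_that("time-dependent AUC reduces to the rank-sum AUC without censoring", {
  set.seed(4)
  n <- 120
  time <- rexp(n, 0.05)
  event <- rep(1, n)
  risks <- -time + rnorm(n, sd = 5)
  h <- stats::median(time)
  got <- time_dependent_auc(risks, time, event, h)
  lab <- as.integer(time <= h)
  ranksum <- (sum(rank(risks)[lab == 1]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(1 - lab))
  expect_equal(got, ranksum, tolerance = 1e-10)
  # perfectly separating risks
  expect_equal(time_dependent_auc(-time, time, event, h), 1)
  # monotone-transform invariance
  expect_equal(time_dependent_auc(exp(risks / 3), time, event, h), got,
               tolerance = 1e-12)
})

test_that("time-dependent AUC is near 0.5 for uninformative risks", {
  set.seed(5)
  n <- 4000
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.8)
  aucs <- time_dependent_auc(rnorm(n), time, event, stats::median(time))
  expect_lt(abs(aucs - 0.5), 0.03)
  expect_error(time_dependent_auc(rnorm(3), c(1, 2, 3), c(1, 1, 1), 99), "follow-up")
})

test_that("Brier score matches its degenerate closed forms", {
  time <- c(1, 2, 10, 12); event <- c(1, 1, 0, 0)
  # survival probabilities exactly matching outcomes at h = 5 -> Brier 0
  sp <- matrix(c(0, 0, 1, 1), 4, 1)
  # keep everyone uncensored so the IPCW weights are 1
  bc <- brier_and_calibration(sp, time, rep(1, 4), horizons = 5, n_bins = 2)
  expect_equal(unname(bc$brier), 0)
  # constant predicted event probability 0.5 without censoring -> 0.25
  bc2 <- brier_and_calibration(matrix(0.5, 4, 1), time, rep(1, 4),
                               horizons = 5, n_bins = 1)
  expect_equal(unname(bc2$brier), 0.25)
  expect_error(brier_and_calibration(sp, time, event, horizons = 99), "follow-up")
})

test_that("without censoring the IPCW Brier equals the plain MSE", {
  set.seed(6)
  n <- 60
  time <- rexp(n, 0.1); event <- rep(1, n)
  h <- stats::median(time)
  sp <- matrix(runif(n), n, 1)
  bc <- brier_and_calibration(sp, time, event, horizons = h)
  lab <- as.numeric(time <= h)
  expect_equal(unname(bc$brier), mean((lab - (1 - sp[, 1]))^2), tolerance = 1e-10)
})

test_that("Kaplan-Meier matches the hand product-limit and its properties", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_at(km, c(1, 2, 3)), c(2 / 3, 2 / 3, 0))
  km_cens <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km_at(km_cens, c(1, 5, 10)), c(1, 1, 1))
  # no censoring: empirical survival function; non-increasing from 1
  set.seed(7)
  t <- rexp(30); km2 <- kaplan_meier(t, rep(1, 30))
  expect_equal(km_at(km2, sort(t)), 1 - seq_len(30) / 30, tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 1e-12))
  ora <- oracle_km(t, rep(1, 30))
  expect_equal(km_at(km2, ora$time), ora$surv, tolerance = 1e-12)
})

test_that("log-rank matches an independent O/E/V tabulation on random fixtures", {
  for (s in 1:20) {
    a <- random_survival_fixture(sample(8:25, 1), seed = 2000 + s)
    b <- random_survival_fixture(sample(8:25, 1), seed = 3000 + s)
    if (sum(a$event) + sum(b$event) == 0) next
    got <- tryCatch(logrank_test(a$time, a$event, b$time, b$event),
                    error = function(e) NULL)
    if (is.null(got)) next
    want <- oracle_logrank(a$time, a$event, b$time, b$event)
    expect_equal(got$chi_square, want$chi_square, tolerance = 1e-8)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
    swap <- logrank_test(b$time, b$event, a$time, a$event)
    expect_equal(swap$chi_square, got$chi_square, tolerance = 1e-10)
  }
})

test_that("log-rank on identical groups is null", {
  t <- c(1, 3, 5, 7, 9); e <- c(1, 0, 1, 1, 0)
  got <- logrank_test(t, e, t, e)
  expect_equal(got$chi_square, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(t, rep(0, 5), t, rep(0, 5)), "no events")
})

test_that("hazard ratio estimation satisfies the score equation and symmetry", {
  set.seed(8)
  n <- 120
  g <- rep(c("low", "high"), each = n / 2)
  time <- rexp(n, 0.05 * ifelse(g == "high", 3, 1))
  event <- rbinom(n, 1, 0.8)
  hr <- cox_hazard_ratio(g, time, event)
  # score of the Breslow partial likelihood vanishes at the fitted coef
  gnum <- as.integer(factor(g)) - 1L
  expect_lt(abs(oracle_cox_score(hr$coef, gnum, time, event)), 1e-6)
  flip <- cox_hazard_ratio(ifelse(g == "high", "low", "high"), time, event)
  expect_equal(flip$hr, 1 / hr$hr, tolerance = 1e-8)
  expect_true(hr$ci_lower <= hr$hr && hr$hr <= hr$ci_upper)
})

test_that("null-group hazard ratios are near one and monotone cases flagged", {
  set.seed(9)
  n <- 400
  g <- sample(c("a", "b"), n, replace = TRUE)
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.7)
  hr <- cox_hazard_ratio(g, time, event)
  expect_true(hr$ci_lower <= 1 && 1 <= hr$ci_upper)
  g2 <- rep(c("a", "b"), each = 10)
  expect_warning(
    hr2 <- cox_hazard_ratio(g2, rep(1:10, 2), c(rep(1, 10), rep(0, 10))),
    "monotone")
  expect_true(hr2$monotone)
  expect_equal(hr2$ci_upper, Inf)
})

test_that("bootstrap CIs are degenerate for constant metrics and seed-stable", {
  fx <- random_survival_fixture(40, seed = 10)
  const_fn <- function(r, t, e) 0.7
  b <- bootstrap_ci(const_fn, fx$risks, fx$time, fx$event, n_boot = 50, seed = 1)
  expect_equal(b$lower, 0.7)
  expect_equal(b$upper, 0.7)
  expect_equal(b$cv, 0)
  b1 <- bootstrap_ci(concordance_index, fx$risks, fx$time, fx$event,
                     n_boot = 100, seed = 5)
  b2 <- bootstrap_ci(concordance_index, fx$risks, fx$time, fx$event,
                     n_boot = 100, seed = 5)
  expect_identical(b1[c("lower", "upper", "cv")], b2[c("lower", "upper", "cv")])
  expect_true(b1$lower <= b1$point && b1$point <= b1$upper)
})

test_that("decision curves reduce to the classification net benefit", {
  set.seed(11)
  n <- 200
  p_hat <- runif(n)
  time <- rexp(n, 0.1); event <- rep(1, n)
  h <- stats::median(time)
  lab <- as.integer(time <= h)
  th <- c(0.1, 0.25, 0.4)
  dc <- decision_curve(p_hat, time, event, h, thresholds = th)
  for (k in seq_along(th)) {
    pos <- p_hat >= th[k]
    tp <- sum(pos & lab == 1); fp <- sum(pos & lab == 0)
    expect_equal(dc$net_benefit[k], tp / n - fp / n * th[k] / (1 - th[k]),
                 tolerance = 1e-10)
  }
  expect_equal(dc$treat_none, rep(0, 3))
  # treat-all at a vanishing threshold approaches the event prevalence
  dc0 <- decision_curve(p_hat, time, event, h, thresholds = 1e-6)
  expect_equal(dc0$treat_all, mean(lab), tolerance = 1e-4)
  expect_error(decision_curve(p_hat, time, event, h, thresholds = 1.5), "\\(0, 1\\)")
})

test_that("quantile stratification uses training cutoffs only", {
  s <- stratify_by_quantile(c(1, 2, 3, 4), c(2, 3), quantiles = 0.5)
  expect_equal(s$cutoffs, 2.5)
  expect_equal(as.character(s$groups), c("low", "high"))
  set.seed(12)
  tr <- rnorm(400); te <- rnorm(401)
  s2 <- stratify_by_quantile(tr, te, 0.5)
  expect_lte(abs(diff(table(s2$groups))), 25)  # near-balanced for matched dists
  s3 <- stratify_by_quantile(tr, te, c(1 / 3, 2 / 3))
  expect_length(s3$cutoffs, 2)
  expect_equal(levels(s3$groups), c("Q1", "Q2", "Q3"))
  expect_equal(sum(table(s3$groups)), 401)
  expect_error(stratify_by_quantile(rep(1, 5), te), "degenerate")
})

test_that("the evaluation report assembles coherent, in-range metrics", {
  set.seed(13)
  n <- 240
  z <- rnorm(n)
  time <- rexp(n, 0.02 * exp(z)) ; cens <- runif(n, 0, 80)
  event <- as.integer(time <= cens); time <- pmin(time, cens)
  tr <- 1:160; te <- 161:n
  rep_ <- evaluate_risk_model(z[tr], time[tr], event[tr],
                              z[te], time[te], event[te],
                              horizons = c(12, 24), n_boot = 50, seed = 1)
  expect_s3_class(rep_, "survival_report")
  expect_true(rep_$c_index > 0.5 && rep_$c_index <= 1)
  expect_true(all(rep_$td_auc > 0.5, na.rm = TRUE))
  expect_true(all(rep_$brier >= 0 & rep_$brier <= 1))
  expect_true(rep_$bootstrap_ci["lower"] <= rep_$c_index + 1e-9)
  expect_true(rep_$bootstrap_ci["upper"] >= rep_$c_index - 1e-9)
  # calibration: predicted means increase across bins within each horizon
  for (h in unique(rep_$calibration$horizon)) {
    cal <- rep_$calibration[rep_$calibration$horizon == h, ]
    expect_true(all(diff(cal$predicted) > -1e-12))
  }
  expect_output(print(rep_), "C-index")
  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "dca.csv")))
})
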