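# Survival metric suite: discrimination, calibration, stratification and
# clinical-utility measures for right-censored risk predictions.

#' Harrell's concordance index
#'
#' Probability that, among comparable patient pairs, the patient with the
#' higher predicted risk experiences the event first. Comparable pairs are
#' `(i, j)` with `t_i < t_j` and `event_i = 1`; ties in risk count 1/2.
#'
#' @param risks numeric risk scores (higher = worse prognosis).
#' @param time,event right-censored outcome.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(risks, time, event) {
  n <- length(risks)
  stopifnot(length(time) == n, length(event) == n)
  o <- order(time)
  r <- risks[o]; tt <- time[o]; ev <- event[o]
  conc <- 0; comp <- 0
  for (i in which(ev == 1)) {
    later <- which(tt > tt[i])
    if (!length(later)) next
    comp <- comp + length(later)
    conc <- conc + sum(r[i] > r[later]) + 0.5 * sum(r[i] == r[later])
  }
  if (comp == 0) stop("no comparable pairs for the concordance index", call. = FALSE)
  conc / comp
}

# Kaplan-Meier estimate of the censoring distribution G(t) = P(C > t),
# evaluated just before t (left-continuous) for IPCW weights
.censor_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  list(time = fit$time, surv = fit$surv)
}

.km_eval <- function(km, t, left = FALSE) {
  # step-function evaluation of KM at t (right-continuous) or t- (left)
  vapply(t, function(ti) {
    idx <- if (left) which(km$time < ti) else which(km$time <= ti)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Time-dependent AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Discrimination between patients who experience the event by the horizon
#' (cases) and patients still at risk beyond it (controls), with inverse
#' probability-of-censoring weights from the Kaplan-Meier estimate of the
#' censoring distribution. Without censoring this reduces to the rank-sum
#' AUC for the binary event-by-horizon label.
#'
#' @param risks numeric risk scores.
#' @param time,event right-censored outcome.
#' @param horizon evaluation time (months).
#' @return AUC in `[0, 1]`.
#' @export
time_dependent_auc <- function(risks, time, event, horizon) {
  if (horizon <= 0 || horizon > max(time))
    stop("horizon must lie within observed follow-up", call. = FALSE)
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (!length(cases) || !length(controls))
    stop("need both cases and controls at the horizon", call. = FALSE)
  G <- .censor_km(time, event)
  w_case <- 1 / pmax(.km_eval(G, time[cases], left = TRUE), 1e-12)
  w_ctrl <- rep(1 / pmax(.km_eval(G, horizon), 1e-12), length(controls))
  num <- 0
  for (k in seq_along(cases)) {
    gt <- risks[cases[k]] > risks[controls]
    eq <- risks[cases[k]] == risks[controls]
    num <- num + w_case[k] * sum(w_ctrl * (gt + 0.5 * eq))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Breslow baseline survival estimate
#'
#' Estimates the cumulative baseline hazard `H0(t)` from training risks by
#' the Breslow estimator, giving `S_i(t) = S0(t)^exp(r_i)`.
#'
#' @param risks training log-relative-hazard scores.
#' @param time,event training outcome.
#' @return object of class `breslow_baseline` (step function of `H0`).
#' @export
breslow_baseline <- function(risks, time, event) {
  o <- order(time)
  r <- risks[o]; tt <- time[o]; ev <- event[o]
  er <- exp(r)
  rev_cum <- rev(cumsum(rev(er)))
  first_tie <- match(tt, tt)
  etimes <- sort(unique(tt[ev == 1]))
  dH <- vapply(etimes, function(s) {
    d <- sum(ev == 1 & tt == s)
    d / rev_cum[first_tie[match(s, tt)]]
  }, numeric(1))
  structure(list(time = etimes, cumhaz = cumsum(dH)), class = "breslow_baseline")
}

#' Predicted survival probability at a horizon
#'
#' @param baseline a [breslow_baseline()].
#' @param risks log-relative-hazard scores.
#' @param horizon time in months.
#' @return vector of `S_i(horizon)`.
#' @export
survival_probability <- function(baseline, risks, horizon) {
  idx <- which(baseline$time <= horizon)
  H0 <- if (!length(idx)) 0 else baseline$cumhaz[max(idx)]
  exp(-H0 * exp(risks))
}

#' IPCW Brier score and calibration table
#'
#' Censoring-weighted mean squared error between predicted event
#' probabilities and observed status at each horizon, plus a calibration
#' table pairing mean predicted event probability per risk-quantile bin
#' with the Kaplan-Meier observed event probability. Without censoring the
#' Brier score equals the plain mean squared error against the binary
#' horizon label.
#'
#' @param surv_probs matrix (`n x length(horizons)`) of predicted survival
#'   probabilities, or a function `f(horizon)` returning them; typically
#'   built from [breslow_baseline()] on training data.
#' @param time,event outcome.
#' @param horizons evaluation times.
#' @param n_bins calibration bins.
#' @return list with `brier` (named vector) and `calibration` (data
#'   frame: horizon, bin, mean predicted and KM-observed event
#'   probabilities).
#' @export
brier_and_calibration <- function(surv_probs, time, event, horizons, n_bins = 4) {
  if (any(horizons > max(time)))
    stop("horizon beyond observed follow-up", call. = FALSE)
  getS <- if (is.function(surv_probs)) surv_probs else {
    sp <- as.matrix(surv_probs)
    function(h) sp[, match(h, horizons)]
  }
  G <- .censor_km(time, event)
  briers <- stats::setNames(numeric(length(horizons)), horizons)
  cal <- list()
  for (h in horizons) {
    S <- getS(h)
    died <- time <= h & event == 1
    alive <- time > h
    w <- numeric(length(time))
    w[died] <- 1 / pmax(.km_eval(G, time[died], left = TRUE), 1e-12)
    w[alive] <- 1 / pmax(.km_eval(G, h), 1e-12)
    briers[as.character(h)] <- mean(w * (died * S^2 + alive * (1 - S)^2))
    # calibration: bin by predicted event probability
    p <- 1 - S
    qs <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- if (length(qs) < 2) rep(1L, length(p))
            else cut(p, breaks = qs, include.lowest = TRUE, labels = FALSE)
    for (b in sort(unique(bins))) {
      idx <- which(bins == b)
      km <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
      obs <- 1 - .km_eval(list(time = km$time, surv = km$surv), h)
      cal[[length(cal) + 1L]] <- data.frame(
        horizon = h, bin = b, n = length(idx),
        predicted = mean(p[idx]), observed = obs)
    }
  }
  list(brier = briers, calibration = do.call(rbind, cal))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator as a right-continuous step function.
#'
#' @param time,event right-censored outcome.
#' @return object of class `km_curve`: data frame columns `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a [kaplan_meier()] curve.
#' @param t times.
#' @return survival probabilities `S(t)`.
#' @export
km_at <- function(km, t) .km_eval(list(time = km$time, surv = km$surv), t)

#' Two-sided log-rank test
#'
#' Observed-minus-expected statistic over pooled event times with
#' hypergeometric variance; p-value from a chi-square distribution with
#' one degree of freedom.
#'
#' @param time_a,event_a outcome of group A.
#' @param time_b,event_b outcome of group B.
#' @return list with `chi_square` and `p_value`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    stop("both groups must be nonempty", call. = FALSE)
  if (sum(event_a) + sum(event_b) == 0)
    stop("no events: the log-rank statistic is undefined", call. = FALSE)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(0:1, c(length(time_a), length(time_b)))
  sd <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ grp),
                 error = function(e) stop("log-rank test failed: ",
                                          conditionMessage(e), call. = FALSE))
  if (!is.finite(sd$chisq))
    stop("zero variance in the log-rank statistic", call. = FALSE)
  list(chi_square = as.numeric(sd$chisq),
       p_value = stats::pchisq(as.numeric(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Univariate hazard ratio between two risk groups
#'
#' Proportional-hazards model with a single binary covariate, fitted on
#' the Breslow partial likelihood; returns the hazard ratio with its Wald
#' 95% confidence interval. Monotone likelihood (no events in one group)
#' is flagged and yields an unbounded interval.
#'
#' @param group_labels factor/character/logical with two levels; the
#'   second level is the high-risk group.
#' @param time,event outcome.
#' @return list with `hr`, `ci_lower`, `ci_upper`, `coef`, `se`,
#'   `monotone` flag.
#' @export
cox_hazard_ratio <- function(group_labels, time, event) {
  g <- as.integer(factor(group_labels)) - 1L
  if (length(unique(g)) != 2)
    stop("`group_labels` must contain exactly two groups", call. = FALSE)
  ev_by <- tapply(event, g, sum)
  monotone <- any(ev_by == 0)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ g, ties = "breslow"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (monotone) {
    warning("monotone likelihood: one group has no events; CI is unbounded",
            call. = FALSE)
    return(list(hr = exp(beta), ci_lower = 0, ci_upper = Inf,
                coef = beta, se = Inf, monotone = TRUE))
  }
  list(hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se),
       coef = beta, se = se, monotone = FALSE)
}

#' Percentile bootstrap confidence interval for a survival metric
#'
#' Patient-level resampling with replacement; resamples on which the
#' metric fails (e.g. no comparable pairs) are redrawn a bounded number of
#' times.
#'
#' @param metric_fn function `(risks, time, event) -> scalar`.
#' @param risks,time,event the evaluation data.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `lower`, `upper`, `cv` (coefficient of variation of
#'   the bootstrap distribution), `point`, `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, risks, time, event, n_boot = 2000, seed = 1L,
                         conf = 0.95) {
  stopifnot(n_boot >= 1)
  n <- length(risks)
  set.seed(as.integer(seed))
  vals <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (tr in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric_fn(risks[idx], time[idx], event[idx]),
                    error = function(e) NULL)
      if (!is.null(v) && is.finite(v)) { vals[b] <- v; ok <- TRUE; break }
      redrawn <- redrawn + 1L
    }
    if (!ok) stop("metric failed on all bootstrap resamples", call. = FALSE)
  }
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  m <- mean(vals)
  list(lower = qs[1], upper = qs[2],
       cv = if (m == 0) 0 else stats::sd(vals) / abs(m),
       point = metric_fn(risks, time, event),
       n_redrawn = redrawn)
}

#' Decision-curve analysis for censored outcomes
#'
#' Net benefit of treating patients whose predicted event probability
#' exceeds a threshold, with the event rate among treat-positive patients
#' estimated by Kaplan-Meier at the horizon:
#' `NB(p) = P(pos) * [ (1 - S_pos(t)) - S_pos(t) * p / (1 - p) ]`.
#' Treat-all and treat-none reference curves are included. Without
#' censoring this reduces to the classification net benefit
#' `TP/n - FP/n * p/(1-p)`.
#'
#' @param predicted_event_probs predicted event probabilities by the
#'   horizon.
#' @param time,event outcome.
#' @param horizon evaluation time.
#' @param thresholds probability thresholds in `(0, 1)`.
#' @return data frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(predicted_event_probs, time, event, horizon,
                           thresholds = seq(0.05, 0.5, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  n <- length(predicted_event_probs)
  km_all <- kaplan_meier(time, event)
  s_all <- km_at(km_all, horizon)
  out <- lapply(thresholds, function(p) {
    pos <- predicted_event_probs >= p
    nb <- if (!any(pos)) 0 else {
      km_pos <- kaplan_meier(time[pos], event[pos])
      s_pos <- km_at(km_pos, horizon)
      mean(pos) * ((1 - s_pos) - s_pos * p / (1 - p))
    }
    ta <- (1 - s_all) - s_all * p / (1 - p)
    data.frame(threshold = p, net_benefit = nb, treat_all = ta, treat_none = 0)
  })
  do.call(rbind, out)
}

#' Quantile-based risk stratification with training-set cutoffs
#'
#' Cutoffs are computed on the training risks only (median by default;
#' arbitrary percentiles, tertiles or quartiles are supported) and test
#' patients are assigned by comparison with them.
#'
#' @param train_risks training risk scores (cutoff source).
#' @param test_risks risk scores to stratify.
#' @param quantiles a single probability (two groups), or a vector of cut
#'   probabilities (ordered bins), e.g. `c(1/3, 2/3)` for tertiles.
#' @return object of class `risk_stratification`: list with `cutoffs`,
#'   `groups` (factor over test patients, ordered low to high) and
#'   `quantiles`.
#' @export
stratify_by_quantile <- function(train_risks, test_risks, quantiles = 0.5) {
  if (!length(train_risks)) stop("training risks are empty", call. = FALSE)
  if (length(unique(train_risks)) == 1L)
    stop("degenerate training risks: all values equal", call. = FALSE)
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must lie strictly inside (0, 1)", call. = FALSE)
  cuts <- stats::quantile(train_risks, probs = sort(quantiles), names = FALSE, type = 7)
  k <- length(cuts) + 1L
  labels <- if (k == 2L) c("low", "high") else paste0("Q", seq_len(k))
  grp <- labels[findInterval(test_risks, cuts, left.open = TRUE) + 1L]
  structure(list(cutoffs = cuts,
                 groups = factor(grp, levels = labels, ordered = TRUE),
                 quantiles = sort(quantiles)),
            class = "risk_stratification")
}

#' Full evaluation report for a risk model on a test cohort
#'
#' Computes the standard survival evaluation battery: Harrell's C-index
#' with bootstrap CI, time-dependent AUC, IPCW Brier score and calibration
#' at each horizon, median-cutoff Kaplan-Meier stratification with
#' log-rank test and hazard ratio, and decision curves.
#'
#' @param train_risks,train_time,train_event training-set risks and
#'   outcome (cutoff and baseline-hazard source).
#' @param test_risks,test_time,test_event test-set risks and outcome.
#' @param horizons evaluation horizons in months (default 36/60/84).
#' @param n_boot bootstrap resamples for the C-index CI.
#' @param seed bootstrap seed.
#' @param dca_thresholds decision-curve thresholds.
#' @return object of class `survival_report`.
#' @export
evaluate_risk_model <- function(train_risks, train_time, train_event,
                                test_risks, test_time, test_event,
                                horizons = c(36, 60, 84),
                                n_boot = 200, seed = 1L,
                                dca_thresholds = seq(0.05, 0.5, by = 0.05)) {
  horizons <- horizons[horizons <= max(test_time)]
  if (!length(horizons)) stop("no horizon lies within test follow-up", call. = FALSE)
  ci <- concordance_index(test_risks, test_time, test_event)
  boot <- bootstrap_ci(concordance_index, test_risks, test_time, test_event,
                       n_boot = n_boot, seed = seed)
  auc <- vapply(horizons, function(h)
    tryCatch(time_dependent_auc(test_risks, test_time, test_event, h),
             error = function(e) NA_real_), numeric(1))
  base <- breslow_baseline(train_risks, train_time, train_event)
  sp <- vapply(horizons, function(h) survival_probability(base, test_risks, h),
               numeric(length(test_risks)))
  bc <- brier_and_calibration(function(h) sp[, match(h, horizons)],
                              test_time, test_event, horizons)
  strat <- stratify_by_quantile(train_risks, test_risks, 0.5)
  hi <- strat$groups == "high"
  lr <- tryCatch(logrank_test(test_time[!hi], test_event[!hi],
                              test_time[hi], test_event[hi]),
                 error = function(e) list(chi_square = NA_real_, p_value = NA_real_))
  hr <- tryCatch(cox_hazard_ratio(factor(ifelse(hi, "high", "low"),
                                         levels = c("low", "high")),
                                  test_time, test_event),
                 error = function(e) NULL)
  km_hi <- if (any(hi)) kaplan_meier(test_time[hi], test_event[hi])
  km_lo <- if (any(!hi)) kaplan_meier(test_time[!hi], test_event[!hi])
  dca <- lapply(stats::setNames(horizons, horizons), function(h)
    decision_curve(1 - sp[, match(h, horizons)], test_time, test_event, h,
                   dca_thresholds))
  structure(list(
    c_index = ci,
    bootstrap_ci = c(lower = boot$lower, upper = boot$upper, cv = boot$cv),
    td_auc = stats::setNames(auc, horizons),
    brier = bc$brier,
    calibration = bc$calibration,
    km_curves = list(high = km_hi, low = km_lo),
    logrank_p = lr$p_value,
    logrank_chisq = lr$chi_square,
    hazard_ratio = hr,
    stratification = strat,
    dca = dca,
    horizons = horizons,
    n_test = length(test_risks), events_test = sum(test_event)
  ), class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("Survival evaluation report\n")
  cat(sprintf("  test patients: %d (%d events)\n", x$n_test, x$events_test))
  cat(sprintf("  C-index: %.3f  [%.3f, %.3f]  (bootstrap cv %.1f%%)\n",
              x$c_index, x$bootstrap_ci["lower"], x$bootstrap_ci["upper"],
              100 * x$bootstrap_ci["cv"]))
  cat("  time-dependent AUC:",
      paste(sprintf("%sm %.3f", names(x$td_auc), x$td_auc), collapse = "  "), "\n")
  cat("  Brier:",
      paste(sprintf("%sm %.3f", names(x$brier), x$brier), collapse = "  "), "\n")
  if (!is.null(x$hazard_ratio))
    cat(sprintf("  high vs low HR: %.2f [%.2f, %.2f], log-rank p = %.3g\n",
                x$hazard_ratio$hr, x$hazard_ratio$ci_lower,
                x$hazard_ratio$ci_upper, x$logrank_p))
  invisible(x)
}

#' Write an evaluation report to delimited text files
#'
#' @param report a `survival_report`.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary_list <- list(
    c_index = report$c_index,
    bootstrap_ci = as.list(report$bootstrap_ci),
    td_auc = as.list(report$td_auc),
    brier = as.list(report$brier),
    logrank_p = report$logrank_p,
    hazard_ratio = if (!is.null(report$hazard_ratio))
      report$hazard_ratio[c("hr", "ci_lower", "ci_upper")] else NULL,
    n_test = report$n_test, events_test = report$events_test)
  jsonlite::write_json(summary_list, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$calibration, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  for (g in names(report$km_curves)) {
    if (!is.null(report$km_curves[[g]]))
      utils::write.csv(as.data.frame(report$km_curves[[g]]),
                       file.path(dir, paste0("km_", g, ".csv")), row.names = FALSE)
  }
  dca <- do.call(rbind, lapply(names(report$dca), function(h)
    cbind(horizon = h, report$dca[[h]])))
  utils::write.csv(dca, file.path(dir, "dca.csv"), row.names = FALSE)
  invisible(dir)
}
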