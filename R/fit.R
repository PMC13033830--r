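# The user-facing model fitting interface.

#' Fit a multimodal cross-attention fusion survival model
#'
#' Trains the hierarchical fusion network end-to-end on a multimodal
#' cohort with the Cox partial-likelihood loss and returns a fitted model
#' object with the usual methods (`print`, `summary`, `coef`, `predict`,
#' `plot`, `residuals`).
#'
#' @param cohort training `fusion_cohort` (see [simulate_cohort()] /
#'   [read_cohort()]).
#' @param fusion a [fusion_config()].
#' @param training a [train_config()].
#' @param valid_cohort optional validation cohort for early stopping.
#' @param quiet suppress per-epoch progress.
#' @return object of class `fusesurv`.
#' @examples
#' cfg <- cohort_config(n_patients = 80, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' sp <- split_cohort(cohort, split_spec(seed = 7))
#' fit <- fusesurv(sp$train,
#'                 fusion = fusion_config(embed_dim = 8, dropout = 0),
#'                 training = train_config(max_epochs = 2, seed = 7))
#' predict(fit, sp$test)[1:3]
#' @export
fusesurv <- function(cohort, fusion = fusion_config(embed_dim = 64),
                     training = train_config(), valid_cohort = NULL,
                     quiet = TRUE) {
  fit <- train_model(cohort, fusion, training, valid_cohort = valid_cohort,
                     quiet = quiet)
  tensors <- cohort_tensors(cohort, fit$schema, fit$center, fit$scale)
  train_risks <- .eval_risks(tensors, fusion, fit$params, fit$schema)
  baseline <- breslow_baseline(train_risks, tensors$time, tensors$event)
  structure(list(
    params = fit$params,
    fusion = fusion, training = training, schema = fit$schema,
    center = fit$center, scale = fit$scale,
    history = fit$history, best_epoch = fit$best_epoch,
    train_risks = stats::setNames(train_risks, tensors$ids),
    train_time = tensors$time, train_event = tensors$event,
    baseline = baseline,
    n = tensors$n, events = sum(tensors$event),
    call = match.call()
  ), class = "fusesurv")
}

#' @export
print.fusesurv <- function(x, ...) {
  cat("Multimodal cross-attention fusion survival model\n")
  cat(sprintf("  trained on %d patients (%d events), %d epochs\n",
              x$n, x$events, nrow(x$history)))
  cat(sprintf("  embed_dim %d, heads %d, intermodal strategy \"%s\", dropout %.2f\n",
              x$fusion$embed_dim, x$fusion$n_heads,
              x$fusion$intermodal_strategy, x$fusion$dropout))
  cat(sprintf("  modalities: %s\n", paste(x$fusion$enabled_modalities, collapse = ", ")))
  cat(sprintf("  final training loss (per event): %.4f\n",
              x$history$loss[nrow(x$history)]))
  if (any(!is.na(x$history$valid_c_index)))
    cat(sprintf("  best validation C-index: %.3f (epoch %d)\n",
                max(x$history$valid_c_index, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @export
summary.fusesurv <- function(object, ...) {
  np <- sum(vapply(object$params, length, numeric(1)))
  med <- stats::median(object$train_risks)
  out <- list(
    n = object$n, events = object$events,
    n_parameters = np,
    epochs = nrow(object$history),
    final_loss = object$history$loss[nrow(object$history)],
    train_c_index = concordance_index(object$train_risks, object$train_time,
                                      object$train_event),
    median_train_risk = med,
    fusion = object$fusion)
  class(out) <- "summary.fusesurv"
  out
}

#' @export
print.summary.fusesurv <- function(x, ...) {
  cat("fusesurv model summary\n")
  cat(sprintf("  patients %d, events %d (%.1f%%)\n", x$n, x$events,
              100 * x$events / x$n))
  cat(sprintf("  trainable parameters: %d\n", x$n_parameters))
  cat(sprintf("  epochs run: %d, final loss %.4f\n", x$epochs, x$final_loss))
  cat(sprintf("  training C-index: %.3f\n", x$train_c_index))
  cat(sprintf("  median training risk (stratification cutoff): %.4f\n",
              x$median_train_risk))
  invisible(x)
}

#' @export
coef.fusesurv <- function(object, ...) object$params

#' Predict from a fitted fusion model
#'
#' @param object a fitted `fusesurv` model.
#' @param cohort a `fusion_cohort` of new patients.
#' @param type `"risk"` for the scalar log-relative-hazard, `"survival"`
#'   for survival probabilities at `horizons` (Breslow baseline from the
#'   training data), `"fused"` for the full per-stage representation.
#' @param horizons months, for `type = "survival"`.
#' @param record_attention collect attention weights (`type = "fused"`).
#' @param ... unused.
#' @return named risk vector, survival probability matrix, or a fused
#'   representation list.
#' @export
predict.fusesurv <- function(object, cohort, type = c("risk", "survival", "fused"),
                             horizons = c(36, 60, 84), record_attention = FALSE,
                             ...) {
  type <- match.arg(type)
  fwd <- fusion_forward(cohort, object$fusion, object$params, object$schema,
                        object$center, object$scale,
                        record_attention = record_attention || type == "fused")
  switch(type,
         risk = fwd$risk,
         survival = {
           out <- vapply(horizons, function(h)
             survival_probability(object$baseline, fwd$risk, h),
             numeric(length(fwd$risk)))
           out <- matrix(out, nrow = length(fwd$risk),
                         dimnames = list(names(fwd$risk), horizons))
           out
         },
         fused = fwd)
}

#' Martingale residuals of the fitted model on its training data
#'
#' `r_i = event_i - H0(t_i) * exp(risk_i)` with the Breslow baseline
#' cumulative hazard.
#'
#' @param object a fitted `fusesurv` model.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.fusesurv <- function(object, ...) {
  H0 <- vapply(object$train_time, function(t) {
    idx <- which(object$baseline$time <= t)
    if (!length(idx)) 0 else object$baseline$cumhaz[max(idx)]
  }, numeric(1))
  object$train_event - H0 * exp(object$train_risks)
}

#' Plot training history
#'
#' Training loss per epoch and, when available, validation C-index.
#'
#' @param x a fitted `fusesurv` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fusesurv <- function(x, ...) {
  h <- x$history
  has_vc <- any(!is.na(h$valid_c_index))
  if (has_vc) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "Cox loss / event", main = "training loss", ...)
  if (has_vc)
    graphics::plot(h$epoch, h$valid_c_index, type = "l", xlab = "epoch",
                   ylab = "validation C-index", main = "validation", ...)
  invisible(x)
}

#' Evaluate a fitted model on a test cohort
#'
#' Convenience wrapper producing the full [evaluate_risk_model()] report
#' using the model's training risks for cutoffs and baseline hazard.
#'
#' @param object a fitted `fusesurv` model.
#' @param cohort test `fusion_cohort`.
#' @param horizons evaluation horizons in months.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return a `survival_report`.
#' @export
evaluate.fusesurv <- function(object, cohort, horizons = c(36, 60, 84),
                              n_boot = 200, seed = 1L, ...) {
  risks <- predict(object, cohort)
  out <- cohort_outcomes(cohort)
  evaluate_risk_model(object$train_risks, object$train_time, object$train_event,
                      risks, out$time_months, out$event,
                      horizons = horizons, n_boot = n_boot, seed = seed)
}

#' @rdname evaluate.fusesurv
#' @param object model object.
#' @param ... method arguments.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")
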