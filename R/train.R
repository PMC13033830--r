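# Cox partial-likelihood training of the fusion network.

#' Negative log Cox partial likelihood (Breslow ties)
#'
#' `L = -sum_{i: event} [ r_i - log sum_{j: t_j >= t_i} exp(r_j) ]`, the
#' standard deep-survival training loss. Tied event times share the
#' Breslow risk-set denominator. Returns 0 when there are no events.
#'
#' @param risks numeric vector of log-relative-hazard scores.
#' @param time,event right-censored outcome: time in months, event
#'   indicator in `{0, 1}`.
#' @return nonnegative scalar loss.
#' @export
cox_loss <- function(risks, time, event) {
  cox_loss_grad(risks, time, event)$loss
}

# loss plus analytic gradient d loss / d risks
cox_loss_grad <- function(risks, time, event) {
  n <- length(risks)
  if (n == 0L) stop("empty input to the Cox loss", call. = FALSE)
  if (length(time) != n || length(event) != n)
    stop("risks and outcomes have different lengths", call. = FALSE)
  if (sum(event) == 0) return(list(loss = 0, grad = numeric(n)))
  o <- order(time)                       # increasing time
  r <- risks[o]; tt <- time[o]; ev <- event[o]
  er <- exp(r)
  # risk-set denominator at each subject's time: sum over t_j >= t_i,
  # ties grouped so equal times share the same denominator
  rev_cum <- rev(cumsum(rev(er)))
  first_tie <- match(tt, tt)             # first position with this time
  denom <- rev_cum[first_tie]
  loss <- -sum(ev * (r - log(denom)))
  # gradient: -ev_k + exp(r_k) * sum_{events i: t_i <= t_k} 1/denom_i
  inv <- ev / denom
  cum_inv <- cumsum(inv)
  last_tie <- n + 1L - match(tt, rev(tt))  # last position with this time
  grad_o <- -ev + er * cum_inv[last_tie]
  grad <- numeric(n)
  grad[o] <- grad_o
  list(loss = loss, grad = grad)
}

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient added to every gradient
#'   (default `4e-6`).
#' @param max_epochs maximum training epochs.
#' @param risk_set_batching `"full_cohort"` (the partial likelihood over
#'   the whole training set each step) or a list
#'   `list(mode = "large_batch", batch_size =, min_events = 1)`; with
#'   batching the partial likelihood is computed within each batch (a
#'   documented approximation).
#' @param early_stop_patience stop after this many epochs without
#'   improvement in validation C-index (0 disables early stopping).
#' @param valid_fraction fraction of the training cohort carved out for
#'   early-stopping validation when no validation cohort is supplied.
#' @param seed integer seed controlling initialization, dropout and any
#'   batching.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4,
                         weight_decay = 4e-6,
                         max_epochs = 100,
                         risk_set_batching = "full_cohort",
                         early_stop_patience = 0,
                         valid_fraction = 0.15,
                         seed = 1L) {
  if (learning_rate < 0) stop("`learning_rate` must be nonnegative", call. = FALSE)
  if (weight_decay < 0) stop("`weight_decay` must be nonnegative", call. = FALSE)
  if (max_epochs < 0) stop("`max_epochs` must be nonnegative", call. = FALSE)
  if (is.list(risk_set_batching)) {
    stopifnot(identical(risk_set_batching$mode, "large_batch"),
              risk_set_batching$batch_size >= 2)
    risk_set_batching$min_events <- risk_set_batching$min_events %||% 1L
  } else if (!identical(risk_set_batching, "full_cohort")) {
    stop("`risk_set_batching` must be \"full_cohort\" or a large_batch spec", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 risk_set_batching = risk_set_batching,
                 early_stop_patience = as.integer(early_stop_patience),
                 valid_fraction = valid_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/test split specification
#'
#' @param train_fraction fraction assigned to the training part
#'   (default 5/6).
#' @param stratify_on stratification variable; only `"event"` is
#'   supported.
#' @param seed integer seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 5 / 6, stratify_on = "event", seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  stopifnot(identical(stratify_on, "event"))
  structure(list(train_fraction = train_fraction, stratify_on = stratify_on,
                 seed = as.integer(seed)), class = "split_spec")
}

# largest-remainder allocation of `total` across strata of sizes `sizes`
.allocate <- function(sizes, total) {
  raw <- sizes * total / sum(sizes)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a cohort into stratified train and test parts
#'
#' Event-stratified random split: disjoint, exhaustive, with the event
#' fraction of each part within one patient of proportional.
#'
#' @param cohort a `fusion_cohort`.
#' @param spec a [split_spec()].
#' @return list with `train`, `test` (cohorts) and `train_idx`,
#'   `test_idx`.
#' @export
split_cohort <- function(cohort, spec = split_spec()) {
  ev <- vapply(cohort$patients, function(p) p$outcome$event, numeric(1))
  n <- length(ev)
  if (sum(ev) < 2) stop("cohort must contain at least 2 events", call. = FALSE)
  n_train <- round(n * spec$train_fraction)
  if (n - n_train < 2)
    stop("train fraction leaves fewer than 2 test patients", call. = FALSE)
  strata <- split(seq_len(n), ev)
  alloc <- .allocate(lengths(strata), n_train)
  set.seed(spec$seed)
  train_idx <- sort(unlist(mapply(function(idx, k) {
    if (k == 0) return(integer(0))
    sample(idx, k)
  }, strata, alloc, SIMPLIFY = FALSE), use.names = FALSE))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = cohort_subset(cohort, train_idx),
       test = cohort_subset(cohort, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# Adam with plain L2 weight decay folded into the gradient
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- 0
    g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# forward in evaluation mode on prebuilt tensors; returns risks
.eval_risks <- function(tensors, config, params, schema) {
  tape <- ad_tape()
  pids <- leaf_params(tape, params)
  out <- build_forward(tape, pids, tensors, config, schema, training = FALSE)
  as.numeric(ad_value(tape, out$risk))
}

.make_batches <- function(n, event, batching, max_tries = 25L) {
  if (identical(batching, "full_cohort")) return(list(seq_len(n)))
  bs <- batching$batch_size
  for (tr in seq_len(max_tries)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    batches <- lapply(starts, function(s) perm[s:min(s + bs - 1L, n)])
    batches <- Filter(function(b) length(b) >= 2L, batches)
    ok <- all(vapply(batches, function(b) sum(event[b]) >= batching$min_events, logical(1)))
    if (ok) return(batches)
  }
  stop("could not form batches with the required minimum events per batch", call. = FALSE)
}

#' Train the fusion network end to end
#'
#' Optimizes all network parameters (stream projections, clinical
#' encoders, cross-attention maps, missing-modality compensation
#' embeddings and the risk head) jointly with Adam on the negative log Cox
#' partial likelihood. Feature streams are fixed inputs. Fully
#' reproducible for a fixed seed.
#'
#' @param cohort training `fusion_cohort`.
#' @param fusion a [fusion_config()].
#' @param training a [train_config()].
#' @param valid_cohort optional validation cohort for early stopping /
#'   monitoring; if `NULL` and `early_stop_patience > 0`, a stratified
#'   `valid_fraction` carve-out of `cohort` is used.
#' @param params optional warm-start parameter list.
#' @param quiet suppress progress output.
#' @return list with `params`, `history` (data frame with per-epoch loss
#'   and validation C-index), `center`/`scale` clinical standardization
#'   and the configs.
#' @export
train_model <- function(cohort, fusion, training = train_config(),
                        valid_cohort = NULL, params = NULL, quiet = TRUE) {
  stopifnot(inherits(cohort, "fusion_cohort"), inherits(fusion, "fusion_config"))
  schema <- cohort$schema
  set.seed(training$seed)

  if (is.null(valid_cohort) && training$early_stop_patience > 0 &&
      training$valid_fraction > 0) {
    sp <- split_cohort(cohort, split_spec(train_fraction = 1 - training$valid_fraction,
                                          seed = training$seed))
    valid_cohort <- sp$test
    cohort <- sp$train
  }

  # clinical standardization fitted on the training part
  ncont <- length(schema$continuous)
  center <- scale <- NULL
  if (ncont) {
    cm <- t(vapply(cohort$patients,
                   function(p) as.numeric(p$clinical$continuous[schema$continuous]),
                   numeric(ncont)))
    if (ncont == 1L) cm <- matrix(cm, ncol = 1L)
    center <- colMeans(cm)
    scale <- apply(cm, 2L, stats::sd)
    scale[!is.finite(scale) | scale < 1e-8] <- 1
  }

  tensors <- cohort_tensors(cohort, schema, center, scale)
  vtensors <- if (!is.null(valid_cohort)) cohort_tensors(valid_cohort, schema, center, scale)
  stream_dims <- vapply(tensors$streams, function(a) dim(a)[3], integer(1))
  if (is.null(params))
    params <- init_fusion_params(fusion, stream_dims, schema, seed = training$seed)
  state <- .adam_init(params)

  hist_loss <- hist_vc <- numeric(0)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  epochs_run <- 0L
  for (epoch in seq_len(training$max_epochs)) {
    batches <- .make_batches(tensors$n, tensors$event, training$risk_set_batching)
    tot_nll <- 0; tot_events <- 0
    for (b in batches) {
      bt <- .subset_tensors(tensors, b)
      tape <- ad_tape()
      pids <- leaf_params(tape, params)
      out <- build_forward(tape, pids, bt, fusion, schema, training = TRUE)
      risks <- as.numeric(ad_value(tape, out$risk))
      cl <- cox_loss_grad(risks, bt$time, bt$event)
      ne <- max(sum(bt$event), 1)
      if (!is.finite(cl$loss))
        stop("Cox loss became non-finite at epoch ", epoch,
             " (risk range ", paste(signif(range(risks), 4), collapse = " .. "), ")",
             call. = FALSE)
      grads_all <- ad_backward(tape, out$risk, matrix(cl$grad / ne, ncol = 1L))
      grads <- lapply(pids, function(id) grads_all[[id]])
      upd <- .adam_step(params, grads, state, training$learning_rate, training$weight_decay)
      params <- upd$params; state <- upd$state
      tot_nll <- tot_nll + cl$loss; tot_events <- tot_events + sum(bt$event)
    }
    epoch_loss <- tot_nll / max(tot_events, 1)
    vc <- NA_real_
    if (!is.null(vtensors)) {
      vr <- .eval_risks(vtensors, fusion, params, schema)
      vc <- tryCatch(concordance_index(vr, vtensors$time, vtensors$event),
                     error = function(e) NA_real_)
    }
    hist_loss <- c(hist_loss, epoch_loss)
    hist_vc <- c(hist_vc, vc)
    epochs_run <- epoch
    if (!quiet) message(sprintf("epoch %3d  loss %.4f  valid C %.3f", epoch, epoch_loss, vc))
    if (training$early_stop_patience > 0 && !is.na(vc)) {
      if (vc > best$metric + 1e-6) best <- list(metric = vc, params = params, epoch = epoch)
      if (epoch - best$epoch >= training$early_stop_patience) break
    }
  }
  if (training$early_stop_patience > 0 && best$epoch > 0) params <- best$params

  list(params = params,
       history = data.frame(epoch = seq_len(epochs_run), loss = hist_loss,
                            valid_c_index = hist_vc),
       center = center, scale = scale,
       fusion = fusion, training = training, schema = schema,
       best_epoch = if (best$epoch > 0) best$epoch else epochs_run)
}

.subset_tensors <- function(tensors, idx) {
  list(n = length(idx),
       streams = lapply(tensors$streams, function(a) a[idx, , , drop = FALSE]),
       clin_cont = tensors$clin_cont[idx, , drop = FALSE],
       clin_cat = tensors$clin_cat[idx, , drop = FALSE],
       avail = tensors$avail[idx, , drop = FALSE],
       time = tensors$time[idx], event = tensors$event[idx],
       ids = tensors$ids[idx])
}

#' Repeated stratified k-fold cross-validation
#'
#' Each repeat draws event-stratified folds under its own seed, trains the
#' model on the complement of each fold and scores the held-out fold with
#' Harrell's C-index. Folds without events are redrawn a bounded number of
#' times before erroring.
#'
#' @param cohort a `fusion_cohort`.
#' @param k number of folds (>= 2).
#' @param repeats number of repetitions.
#' @param seeds integer vector of per-repeat seeds (defaults to
#'   `1:repeats`).
#' @param fusion,training model and training configuration.
#' @param quiet suppress progress output.
#' @return data frame with one row per (repeat, fold): `rep`, `fold`,
#'   `n_test`, `events_test`, `c_index`; per-repeat mean C-indexes are in
#'   `attr(, "per_repeat")`.
#' @export
cross_validate <- function(cohort, k = 5, repeats = 10, seeds = NULL,
                           fusion = fusion_config(embed_dim = 64),
                           training = train_config(), quiet = TRUE) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  seeds <- seeds %||% seq_len(repeats)
  stopifnot(length(seeds) == repeats)
  ev <- vapply(cohort$patients, function(p) p$outcome$event, numeric(1))
  n <- length(ev)
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- .stratified_folds(ev, k, seeds[r])
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      tr_cfg <- training
      tr_cfg$seed <- seeds[r]
      fit <- train_model(cohort_subset(cohort, -test_idx), fusion, tr_cfg)
      te <- cohort_tensors(cohort_subset(cohort, test_idx), fit$schema,
                           fit$center, fit$scale)
      ci <- concordance_index(.eval_risks(te, fusion, fit$params, fit$schema),
                              te$time, te$event)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, n_test = length(test_idx),
        events_test = sum(ev[test_idx]), c_index = ci)
      if (!quiet) message(sprintf("repeat %d fold %d: C = %.3f", r, f, ci))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_repeat") <- tapply(out$c_index, out$rep, mean)
  out
}

.stratified_folds <- function(event, k, seed, max_tries = 20L) {
  n <- length(event)
  set.seed(as.integer(seed))
  for (tr in seq_len(max_tries)) {
    folds <- integer(n)
    for (s in unique(event)) {
      idx <- sample(which(event == s))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    ev_per_fold <- tapply(event, folds, sum)
    if (length(ev_per_fold) == k && all(ev_per_fold >= 1)) return(folds)
  }
  stop("could not draw ", k, " folds that all contain events", call. = FALSE)
}

# apply one ablation delta to a fusion config, revalidating it
apply_config_delta <- function(base, delta) {
  streams <- setdiff(base$enabled_streams, delta$drop_stream %||% character(0))
  mods <- setdiff(base$enabled_modalities, delta$drop_modality %||% character(0))
  # a modality whose streams are all dropped is itself dropped
  if ("pathology" %in% mods && !any(PATH_STREAMS %in% streams))
    mods <- setdiff(mods, "pathology")
  if ("ultrasound" %in% mods && !any(US_STREAMS %in% streams))
    mods <- setdiff(mods, "ultrasound")
  fusion_config(
    embed_dim = base$embed_dim, n_heads = base$n_heads, dropout = base$dropout,
    wsi_query = delta$wsi_query %||% base$wsi_query,
    us_query = delta$us_query %||% base$us_query,
    intermodal_strategy = delta$intermodal_strategy %||% base$intermodal_strategy,
    enabled_streams = streams, enabled_modalities = mods,
    use_missing_compensation = delta$use_missing_compensation %||% base$use_missing_compensation,
    token_pooling = base$token_pooling)
}

#' Run a grid of ablation configurations
#'
#' Trains and evaluates one model per grid cell under a shared
#' train/test split and shared seeds, reporting the held-out C-index and
#' its difference from the reference cell. Cells may drop modalities or
#' streams, reassign the intramodality query, switch the intermodal
#' strategy, or toggle missing-modality compensation (evaluated on a
#' missingness-injected copy of the cohort that is identical across
#' cells).
#'
#' @param cohort a `fusion_cohort`.
#' @param base_fusion the full-model [fusion_config()].
#' @param training a [train_config()].
#' @param grid named list of cells; each cell is a list with any of
#'   `drop_modality`, `drop_stream`, `wsi_query`, `us_query`,
#'   `intermodal_strategy`, `use_missing_compensation`, and `cohort`:
#'   `"complete"` (the default), `"missing"` (missingness injected in both
#'   training and test data, so compensation embeddings are learned), or
#'   `"missing_test"` (trained on complete data, confronted with the same
#'   injected missingness at test time only).
#' @param split a [split_spec()] shared by all cells.
#' @param missing_rates,missing_seed missingness injected once and shared
#'   by all `cohort = "missing"` cells.
#' @param reference label of the reference cell for the C-index delta
#'   (default: first cell).
#' @param quiet suppress progress output.
#' @return data frame with `label`, `c_index`, `delta_c_index`,
#'   `n_train`, `n_test`; skipped cells are dropped with a warning.
#' @export
run_ablation_grid <- function(cohort, base_fusion, training, grid,
                              split = split_spec(),
                              missing_rates = NULL, missing_seed = 1L,
                              reference = NULL, quiet = TRUE) {
  if (!length(grid)) stop("empty ablation grid", call. = FALSE)
  if (is.null(names(grid)) || any(!nzchar(names(grid))))
    stop("grid cells must be named", call. = FALSE)
  sp <- split_cohort(cohort, split)
  sp_missing <- NULL
  needs_missing <- vapply(grid, function(g)
    identical(g$cohort, "missing") || identical(g$cohort, "missing_test"), logical(1))
  if (any(needs_missing)) {
    if (is.null(missing_rates))
      stop("grid contains `cohort = \"missing\"` cells but no `missing_rates`", call. = FALSE)
    cm <- inject_missingness(cohort, missing_rates, seed = missing_seed)
    sp_missing <- list(train = cohort_subset(cm, sp$train_idx),
                       test = cohort_subset(cm, sp$test_idx))
  }
  rows <- list()
  for (lab in names(grid)) {
    cell <- grid[[lab]]
    cfg <- tryCatch(apply_config_delta(base_fusion, cell), error = function(e) {
      warning("skipping ablation cell `", lab, "`: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(cfg)) next
    use <- switch(cell$cohort %||% "complete",
                  missing = sp_missing,
                  missing_test = list(train = sp$train, test = sp_missing$test),
                  sp)
    fit <- train_model(use$train, cfg, training)
    te <- cohort_tensors(use$test, fit$schema, fit$center, fit$scale)
    ci <- concordance_index(.eval_risks(te, cfg, fit$params, fit$schema),
                            te$time, te$event)
    rows[[lab]] <- data.frame(label = lab, c_index = ci,
                              n_train = length(use$train$patients),
                              n_test = length(use$test$patients))
    if (!quiet) message(sprintf("cell %-24s C = %.3f", lab, ci))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ref <- reference %||% out$label[1]
  if (!ref %in% out$label)
    stop("reference cell `", ref, "` not present in results", call. = FALSE)
  out$delta_c_index <- out$c_index - out$c_index[out$label == ref]
  attr(out, "reference") <- ref
  out[, c("label", "c_index", "delta_c_index", "n_train", "n_test")]
}
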