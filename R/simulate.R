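# Synthetic multimodal cohort generator.
#
# Emulates, at the feature level, a breast-cancer cohort carrying three data
# modalities (pathology, ultrasound, structured clinical variables). Each
# modality m has a per-patient latent factor vector f_m ~ N(0, I); its
# unit-variance scalar summary s_m = sum(f_m)/sqrt(latent_dim) contributes
# signal_weights[m] * s_m to the planted log-hazard z. Event times are
# exponential given z (T = -log(U) / (h0 * exp(z))) so censoring can be
# calibrated analytically; censoring is a mix of early random dropout and an
# administrative cutoff. Feature streams are linear mixtures of their
# modality's latent factor plus independent Gaussian noise, so every stream
# is informative of exactly one modality.

MODALITIES <- c("pathology", "ultrasound", "clinical")
STREAM_NAMES <- c("wsi_deep", "wsi_morph", "wsi_top", "us_deep", "us_omic", "us_text")
STREAM_MODALITY <- c(wsi_deep = "pathology", wsi_morph = "pathology", wsi_top = "pathology",
                     us_deep = "ultrasound", us_omic = "ultrasound", us_text = "ultrasound")

#' Configuration for the synthetic multimodal cohort simulator
#'
#' Defines the study conditions under which synthetic cohorts are drawn:
#' sample size, latent signal structure, per-stream dimensions, noise,
#' baseline hazard, censoring, target event fraction and modality
#' missingness.
#'
#' @param n_patients number of patients to simulate.
#' @param latent_dim dimension of each modality's latent factor vector.
#' @param signal_weights named nonnegative weights (`pathology`,
#'   `ultrasound`, `clinical`) giving each modality's contribution to the
#'   planted log-hazard. The default is pathology-dominant.
#' @param stream_dims named positive integer widths for the six feature
#'   streams (`wsi_deep`, `wsi_morph`, `wsi_top`, `us_deep`, `us_omic`,
#'   `us_text`).
#' @param n_wsi_patches number of pathology patch tokens per patient.
#' @param n_us_tokens number of ultrasound deep-feature tokens per patient.
#' @param noise_sd standard deviation of independent feature noise.
#' @param stream_offset mean of the fixed per-dimension constant offsets
#'   added to every stream (drawn once per dimension, sd 0.25), emulating
#'   the non-centered activations of pretrained feature encoders; 0 gives
#'   zero-centered streams.
#' @param baseline_hazard constant baseline hazard per month.
#' @param admin_censor_time administrative censoring time in months, or
#'   `NULL` to calibrate it by bisection so the expected event fraction
#'   equals `target_event_fraction` (see [calibrate_admin_censor_time()]).
#' @param target_event_fraction expected fraction of patients with an
#'   observed event; default 0.162.
#' @param missing_rates named rates in `[0, 1]` at which the pathology /
#'   ultrasound modality is flagged unavailable.
#' @param n_continuous_clinical,n_categorical_clinical number of continuous
#'   and categorical clinical variables (categorical level counts taken from
#'   `clinical_levels`, recycled).
#' @param clinical_levels integer vector of category counts for the
#'   categorical clinical variables.
#' @param clinical_noise_sd noise added to the clinical latent summary
#'   before producing clinical variables.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 2000,
                          latent_dim = 4,
                          signal_weights = c(pathology = 1.0, ultrasound = 0.4, clinical = 0.4),
                          stream_dims = c(wsi_deep = 32, wsi_morph = 16, wsi_top = 16,
                                          us_deep = 16, us_omic = 24, us_text = 16),
                          n_wsi_patches = 8,
                          n_us_tokens = 8,
                          noise_sd = 0.5,
                          stream_offset = 1.0,
                          baseline_hazard = 0.002,
                          admin_censor_time = NULL,
                          target_event_fraction = 0.162,
                          missing_rates = c(pathology = 0, ultrasound = 0),
                          n_continuous_clinical = 2,
                          n_categorical_clinical = 7,
                          clinical_levels = c(3L, 3L, 2L, 2L, 2L, 2L, 3L),
                          clinical_noise_sd = 0.5,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("`n_patients` must be a positive integer", call. = FALSE)
  if (latent_dim < 1) stop("`latent_dim` must be >= 1", call. = FALSE)
  if (!all(names(signal_weights) %in% MODALITIES))
    stop("`signal_weights` names must be among: ", paste(MODALITIES, collapse = ", "), call. = FALSE)
  if (any(signal_weights < 0)) stop("`signal_weights` must be nonnegative", call. = FALSE)
  w <- stats::setNames(numeric(3), MODALITIES)
  w[names(signal_weights)] <- signal_weights
  if (!all(STREAM_NAMES %in% names(stream_dims)))
    stop("`stream_dims` must name all of: ", paste(STREAM_NAMES, collapse = ", "), call. = FALSE)
  if (any(stream_dims < 1)) stop("all stream dims must be >= 1", call. = FALSE)
  if (n_wsi_patches < 1 || n_us_tokens < 1) stop("token counts must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be positive", call. = FALSE)
  if (target_event_fraction <= 0 || target_event_fraction >= 1)
    stop("`target_event_fraction` must be in (0, 1)", call. = FALSE)
  if (!all(names(missing_rates) %in% c("pathology", "ultrasound")))
    stop("`missing_rates` may name only pathology and ultrasound", call. = FALSE)
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("missing rates must be in [0, 1]", call. = FALSE)
  if (n_continuous_clinical < 0 || n_categorical_clinical < 0)
    stop("clinical variable counts must be nonnegative", call. = FALSE)
  levs <- rep_len(as.integer(clinical_levels), max(n_categorical_clinical, 1L))
  structure(list(
    n_patients = as.integer(n_patients), latent_dim = as.integer(latent_dim),
    signal_weights = w,
    stream_dims = stats::setNames(as.integer(stream_dims[STREAM_NAMES]), STREAM_NAMES),
    n_wsi_patches = as.integer(n_wsi_patches), n_us_tokens = as.integer(n_us_tokens),
    noise_sd = noise_sd, stream_offset = stream_offset,
    baseline_hazard = baseline_hazard,
    admin_censor_time = admin_censor_time,
    target_event_fraction = target_event_fraction,
    missing_rates = missing_rates,
    n_continuous_clinical = as.integer(n_continuous_clinical),
    n_categorical_clinical = as.integer(n_categorical_clinical),
    clinical_levels = levs[seq_len(n_categorical_clinical)],
    clinical_noise_sd = clinical_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# P(observed event | admin censor time tau) under the simulator's model:
# z ~ N(0, sigma2), T | z ~ Exp(h0 * e^z), censoring C = min(3 tau U, tau).
# Given lambda = h0 e^z:
#   P(T < C | z) = integral_0^tau (1 - e^{-lambda c}) dc / (3 tau)
#                  + (2/3) (1 - e^{-lambda tau})
.event_prob_given_tau <- function(tau, h0, sigma2) {
  sig <- sqrt(sigma2)
  inner <- function(z) {
    lam <- h0 * exp(z)
    a <- (tau - (1 - exp(-lam * tau)) / lam) / (3 * tau)
    p <- a + (2 / 3) * (1 - exp(-lam * tau))
    p * stats::dnorm(z, 0, max(sig, .Machine$double.eps))
  }
  if (sig < 1e-12) {
    lam <- h0
    return((tau - (1 - exp(-lam * tau)) / lam) / (3 * tau) + (2 / 3) * (1 - exp(-lam * tau)))
  }
  stats::integrate(inner, -8 * sig, 8 * sig, rel.tol = 1e-9)$value
}

#' Calibrate the administrative censoring time analytically
#'
#' Solves for the administrative censoring time `tau` such that the expected
#' fraction of observed events equals the target, by root bisection on the
#' closed-form event-probability integral of the simulator's generative
#' model (exponential event times given a Gaussian log-hazard, censoring
#' `C = min(3*tau*U, tau)` with `U ~ Unif(0,1)`).
#'
#' @param config a [cohort_config()].
#' @return administrative censoring time in months.
#' @export
calibrate_admin_censor_time <- function(config) {
  sigma2 <- sum(config$signal_weights^2)
  f <- function(tau) .event_prob_given_tau(tau, config$baseline_hazard, sigma2) -
    config$target_event_fraction
  stats::uniroot(f, lower = 1e-3, upper = 1e6, tol = 1e-8)$root
}

#' Simulate a multimodal survival cohort with planted risk
#'
#' Draws a cohort under the generative model described in
#' [cohort_config()]: per-modality latent factors, a planted log-hazard
#' `z = sum_m w_m * s_m`, exponential event times with constant baseline
#' hazard, mixed uniform/administrative censoring, six linear-mixture
#' feature streams, structured clinical variables derived from the clinical
#' latent summary, and per-modality availability masks (all available;
#' use [inject_missingness()] to flag modalities unavailable).
#'
#' @param config a [cohort_config()].
#' @return a list of class `fusion_cohort` with elements
#'   `patients` (list of patient records: `patient_id`, `streams`,
#'   `clinical`, `outcome`, `availability`), `truth` (ground truth:
#'   `true_log_risk`, `latent_factors`), `schema` (clinical variable
#'   schema) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  ld <- config$latent_dim
  tau <- config$admin_censor_time
  if (is.null(tau)) tau <- calibrate_admin_censor_time(config)

  set.seed(config$seed)
  # latent factors and planted risk
  fac <- lapply(stats::setNames(MODALITIES, MODALITIES),
                function(m) matrix(stats::rnorm(n * ld), n, ld))
  s <- vapply(fac, function(f) rowSums(f) / sqrt(ld), numeric(n))
  z <- as.numeric(s %*% config$signal_weights[MODALITIES])

  # outcomes: T = -log(U)/(h0 e^z); C = min(3 tau V, tau), draws tau-free
  u_event <- stats::runif(n)
  v_cens <- stats::runif(n)
  t_event <- -log(u_event) / (config$baseline_hazard * exp(z))
  t_cens <- pmin(3 * tau * v_cens, tau)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, 1e-6)

  # fixed seeded mixing maps: stream s of modality m = A_s f_m + noise
  mix <- lapply(stats::setNames(STREAM_NAMES, STREAM_NAMES), function(sn) {
    d <- config$stream_dims[[sn]]
    list(A = matrix(stats::rnorm(ld * d, sd = 1 / sqrt(ld)), ld, d),
         mu = stats::rnorm(d, mean = config$stream_offset %||% 0, sd = 0.25))
  })
  n_tok <- c(wsi_deep = config$n_wsi_patches, wsi_morph = 1L, wsi_top = 1L,
             us_deep = config$n_us_tokens, us_omic = 1L, us_text = 1L)
  streams <- lapply(stats::setNames(STREAM_NAMES, STREAM_NAMES), function(sn) {
    d <- config$stream_dims[[sn]]; tk <- n_tok[[sn]]
    base <- sweep(fac[[STREAM_MODALITY[[sn]]]] %*% mix[[sn]]$A, 2L, mix[[sn]]$mu, "+")
    arr <- array(0, c(n, tk, d))
    for (j in seq_len(tk))
      arr[, j, ] <- base + matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
    arr
  })

  # clinical variables: noisy copies of the clinical latent summary
  s_clin <- s[, "clinical"]
  csd <- config$clinical_noise_sd
  cont <- NULL
  if (config$n_continuous_clinical > 0) {
    cont <- vapply(seq_len(config$n_continuous_clinical), function(j)
      s_clin + stats::rnorm(n, sd = csd), numeric(n))
    # map the first two onto realistic clinical scales (age yrs, size cm)
    cont[, 1] <- 47 + 10 * cont[, 1]
    if (ncol(cont) >= 2) cont[, 2] <- pmax(0.2, 2 + 0.8 * cont[, 2])
    colnames(cont) <- c("age", "tumor_size", paste0("cont", seq_len(max(0, config$n_continuous_clinical - 2))))[
      seq_len(config$n_continuous_clinical)]
  }
  cat_names <- c("ln_status", "grade", "er", "pr", "her2", "ki67_band", "subtype")
  cat <- NULL
  if (config$n_categorical_clinical > 0) {
    nm <- c(cat_names, paste0("cat", seq_len(max(0, config$n_categorical_clinical - 7))))[
      seq_len(config$n_categorical_clinical)]
    marg_sd <- sqrt(1 + csd^2)
    cat <- vapply(seq_len(config$n_categorical_clinical), function(j) {
      q <- s_clin + stats::rnorm(n, sd = csd)
      L <- config$clinical_levels[j]
      cuts <- stats::qnorm(seq_len(L - 1) / L, 0, marg_sd)
      as.integer(findInterval(q, cuts) + 1L)
    }, integer(n))
    colnames(cat) <- nm
  }
  schema <- clinical_schema(
    continuous = if (is.null(cont)) character(0) else colnames(cont),
    categorical = if (is.null(cat)) integer(0) else
      stats::setNames(config$clinical_levels, colnames(cat)))

  ids <- sprintf("P%04d", seq_len(n))
  patients <- lapply(seq_len(n), function(i) {
    st <- lapply(streams, function(a) matrix(a[i, , ], dim(a)[2], dim(a)[3]))
    list(
      patient_id = ids[i],
      streams = st,
      clinical = list(
        continuous = if (is.null(cont)) numeric(0) else stats::setNames(cont[i, ], colnames(cont)),
        categorical = if (is.null(cat)) integer(0) else stats::setNames(cat[i, ], colnames(cat))),
      outcome = list(time_months = time[i], event = event[i]),
      availability = c(pathology = TRUE, ultrasound = TRUE, clinical = TRUE)
    )
  })

  cohort <- structure(list(
    patients = patients,
    truth = list(true_log_risk = stats::setNames(z, ids),
                 latent_factors = fac,
                 latent_summaries = s),
    schema = schema,
    config = config,
    admin_censor_time = tau
  ), class = "fusion_cohort")

  if (any(config$missing_rates > 0))
    cohort <- inject_missingness(cohort, config$missing_rates, seed = config$seed + 1L)
  cohort
}

#' @export
print.fusion_cohort <- function(x, ...) {
  n <- length(x$patients)
  ev <- vapply(x$patients, function(p) p$outcome$event, numeric(1))
  cat("Synthetic multimodal survival cohort\n")
  cat(sprintf("  patients: %d   events: %d (%.1f%%)\n", n, sum(ev), 100 * mean(ev)))
  cat(sprintf("  streams:  %s\n", paste(STREAM_NAMES, collapse = ", ")))
  av <- cohort_masks(x)
  miss <- tapply(!av$available, av$modality, sum)
  cat(sprintf("  missing:  %s\n",
              paste(sprintf("%s=%d", names(miss), miss), collapse = ", ")))
  invisible(x)
}

#' Flag modalities as unavailable at given rates
#'
#' Flips each patient's per-modality availability mask to unavailable,
#' independently per patient and modality, with the given probabilities.
#' Feature content of masked streams is retained internally (models must
#' not look at it when the mask is off).
#'
#' @param cohort a `fusion_cohort`.
#' @param missing_rates named vector of rates in `[0, 1]`; names must be
#'   `pathology` and/or `ultrasound` (clinical is always available).
#' @param seed integer seed.
#' @return the cohort with updated availability masks.
#' @export
inject_missingness <- function(cohort, missing_rates, seed = 1L) {
  stopifnot(inherits(cohort, "fusion_cohort"))
  bad <- setdiff(names(missing_rates), c("pathology", "ultrasound"))
  if (length(bad))
    stop("unknown modality in `missing_rates`: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("missing rates must be in [0, 1]", call. = FALSE)
  n <- length(cohort$patients)
  set.seed(as.integer(seed))
  for (m in names(missing_rates)) {
    flip <- stats::runif(n) < missing_rates[[m]]
    for (i in which(flip)) cohort$patients[[i]]$availability[[m]] <- FALSE
  }
  cohort
}

# long-format availability table
cohort_masks <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(patient_id = p$patient_id, modality = MODALITIES,
               available = as.logical(p$availability[MODALITIES]))))
}

cohort_outcomes <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    time_months = vapply(cohort$patients, function(p) p$outcome$time_months, numeric(1)),
    event = vapply(cohort$patients, function(p) p$outcome$event, numeric(1))
  )
}

#' Write a cohort to a directory of delimited text files
#'
#' One wide CSV per feature stream (token-major flattened columns), plus
#' `outcomes.csv`, `masks.csv`, `clinical.csv`, `ground_truth.csv` and a
#' JSON metadata file describing dimensions and the clinical schema.
#'
#' @param cohort a `fusion_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  for (sn in STREAM_NAMES) {
    m0 <- cohort$patients[[1]]$streams[[sn]]
    flat <- t(vapply(cohort$patients, function(p) as.numeric(t(p$streams[[sn]])),
                     numeric(nrow(m0) * ncol(m0))))
    colnames(flat) <- paste0("tok", rep(seq_len(nrow(m0)), each = ncol(m0)),
                             "_d", rep(seq_len(ncol(m0)), nrow(m0)))
    utils::write.csv(data.frame(patient_id = ids, flat, check.names = FALSE),
                     file.path(dir, paste0("stream_", sn, ".csv")), row.names = FALSE)
  }
  utils::write.csv(cohort_outcomes(cohort), file.path(dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(cohort_masks(cohort), file.path(dir, "masks.csv"), row.names = FALSE)
  cont <- t(vapply(cohort$patients, function(p) as.numeric(p$clinical$continuous),
                   numeric(length(cohort$patients[[1]]$clinical$continuous))))
  cat <- t(vapply(cohort$patients, function(p) as.numeric(p$clinical$categorical),
                  numeric(length(cohort$patients[[1]]$clinical$categorical))))
  clin <- data.frame(patient_id = ids)
  if (ncol(cont)) { colnames(cont) <- cohort$schema$continuous; clin <- cbind(clin, cont) }
  if (ncol(cat)) { colnames(cat) <- names(cohort$schema$categorical); clin <- cbind(clin, cat) }
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = ids,
                              true_log_risk = as.numeric(cohort$truth$true_log_risk)),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  meta <- list(
    n_patients = length(ids),
    stream_tokens = lapply(cohort$patients[[1]]$streams, nrow),
    stream_dims = lapply(cohort$patients[[1]]$streams, ncol),
    schema = list(continuous = as.list(cohort$schema$continuous),
                  categorical = as.list(cohort$schema$categorical)),
    admin_censor_time = cohort$admin_censor_time
  )
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from the tabular layout written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `fusion_cohort` (without ground truth if absent).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  out_path <- file.path(dir, "outcomes.csv")
  outcomes <- utils::read.csv(out_path)
  for (col in c("time_months", "event")) {
    v <- suppressWarnings(as.numeric(outcomes[[col]]))
    if (anyNA(v)) {
      stop(sprintf("malformed outcomes table %s: non-numeric `%s` at line %d",
                   out_path, col, which(is.na(v))[1] + 1L), call. = FALSE)
    }
    outcomes[[col]] <- v
  }
  masks <- utils::read.csv(file.path(dir, "masks.csv"))
  clin <- utils::read.csv(file.path(dir, "clinical.csv"), check.names = FALSE)
  ids <- outcomes$patient_id
  n <- length(ids)
  streams <- lapply(stats::setNames(STREAM_NAMES, STREAM_NAMES), function(sn) {
    f <- file.path(dir, paste0("stream_", sn, ".csv"))
    if (!file.exists(f)) stop("missing stream file for stream `", sn, "`: ", f, call. = FALSE)
    tab <- utils::read.csv(f, check.names = FALSE)
    tk <- meta$stream_tokens[[sn]]; d <- meta$stream_dims[[sn]]
    list(tab = as.matrix(tab[match(ids, tab$patient_id), -1, drop = FALSE]), tk = tk, d = d)
  })
  cont_names <- unlist(meta$schema$continuous)
  cat_levels <- unlist(meta$schema$categorical)
  schema <- clinical_schema(continuous = cont_names %||% character(0),
                            categorical = cat_levels %||% integer(0))
  patients <- lapply(seq_len(n), function(i) {
    st <- lapply(streams, function(s) matrix(s$tab[i, ], s$tk, s$d, byrow = TRUE))
    mk <- masks[masks$patient_id == ids[i], ]
    av <- stats::setNames(as.logical(mk$available[match(MODALITIES, mk$modality)]), MODALITIES)
    ci <- match(ids[i], clin$patient_id)
    list(patient_id = ids[i], streams = st,
         clinical = list(
           continuous = stats::setNames(as.numeric(clin[ci, cont_names]), cont_names),
           categorical = stats::setNames(as.integer(clin[ci, names(cat_levels)]), names(cat_levels))),
         outcome = list(time_months = outcomes$time_months[i], event = outcomes$event[i]),
         availability = av)
  })
  truth <- NULL
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) {
    g <- utils::read.csv(gt)
    truth <- list(true_log_risk = stats::setNames(g$true_log_risk[match(ids, g$patient_id)], ids))
  }
  structure(list(patients = patients, truth = truth, schema = schema,
                 config = NULL, admin_censor_time = meta$admin_censor_time),
            class = "fusion_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset a cohort by patient index, keeping truth aligned
cohort_subset <- function(cohort, idx) {
  out <- cohort
  out$patients <- cohort$patients[idx]
  if (!is.null(cohort$truth)) {
    out$truth$true_log_risk <- cohort$truth$true_log_risk[idx]
    if (!is.null(cohort$truth$latent_factors))
      out$truth$latent_factors <- lapply(cohort$truth$latent_factors,
                                         function(f) f[idx, , drop = FALSE])
    if (!is.null(cohort$truth$latent_summaries))
      out$truth$latent_summaries <- cohort$truth$latent_summaries[idx, , drop = FALSE]
  }
  out
}
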