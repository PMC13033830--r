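# Structured clinical variable schema and encoder.

#' Declare the clinical variable schema
#'
#' Orders the structured clinical variables and declares their kind. The
#' default mirrors a breast-cancer recurrence setting: age and tumor size
#' as continuous variables; lymph node status, histological grade, ER, PR,
#' HER2, a Ki67 band and molecular subtype as categorical variables. Ki67
#' is treated as a categorical band by default; declaring it in
#' `continuous` instead is supported by the schema.
#'
#' @param continuous character vector of continuous variable names.
#' @param categorical named integer vector: names are categorical variable
#'   names, values the number of levels (codes `1..L`).
#' @return object of class `clinical_schema`.
#' @export
clinical_schema <- function(continuous = c("age", "tumor_size"),
                            categorical = c(ln_status = 3L, grade = 3L, er = 2L, pr = 2L,
                                            her2 = 2L, ki67_band = 2L, subtype = 3L)) {
  if (length(categorical) && is.null(names(categorical)))
    stop("`categorical` must be a named vector of level counts", call. = FALSE)
  structure(list(continuous = as.character(continuous),
                 categorical = if (length(categorical))
                   stats::setNames(as.integer(categorical), names(categorical))
                 else stats::setNames(integer(0), character(0))),
            class = "clinical_schema")
}

n_clinical_tokens <- function(schema) length(schema$continuous) + length(schema$categorical)

# validate one profile (named continuous vector + named integer codes)
check_clinical_profile <- function(profile, schema) {
  for (v in schema$continuous) {
    x <- profile$continuous[[v]]
    if (is.null(x) || !is.finite(x))
      stop("continuous clinical variable `", v, "` missing or non-finite", call. = FALSE)
  }
  for (v in names(schema$categorical)) {
    code <- profile$categorical[[v]]
    L <- schema$categorical[[v]]
    if (is.null(code) || is.na(code))
      stop("categorical clinical variable `", v, "` missing", call. = FALSE)
    if (code < 1 || code > L)
      stop("out-of-vocabulary code ", code, " for clinical variable `", v,
           "` (declared levels 1..", L, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Encode a structured clinical profile as a token matrix
#'
#' Maps each clinical variable to one `embed_dim`-wide token: continuous
#' variables through a learnable affine map (`x * w + b`), categorical
#' variables through a learnable lookup table, concatenated along the token
#' axis in schema order.
#'
#' @param profile list with named `continuous` values and named integer
#'   `categorical` codes.
#' @param params named parameter list containing `clin_cont_<name>_w`,
#'   `clin_cont_<name>_b` (length `embed_dim`) and `clin_cat_<name>_E`
#'   (levels x `embed_dim`); see [init_fusion_params()].
#' @param schema a [clinical_schema()].
#' @return numeric token matrix, one row per clinical variable.
#' @export
encode_clinical <- function(profile, params, schema = clinical_schema()) {
  check_clinical_profile(profile, schema)
  rows <- list()
  for (v in schema$continuous) {
    w <- params[[paste0("clin_cont_", v, "_w")]]
    b <- params[[paste0("clin_cont_", v, "_b")]]
    rows[[v]] <- as.numeric(profile$continuous[[v]]) * as.numeric(w) + as.numeric(b)
  }
  for (v in names(schema$categorical)) {
    E <- params[[paste0("clin_cat_", v, "_E")]]
    rows[[v]] <- as.numeric(E[profile$categorical[[v]], ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- c(schema$continuous, names(schema$categorical))
  out
}

#' Project a token stream to a target width
#'
#' Applies a learnable per-token affine map, preserving the token count.
#' Used to align every feature stream to the shared attention width.
#'
#' @param tokens numeric token matrix (`n_tokens x dim`).
#' @param W,b projection weights (`dim x target_dim`) and bias.
#' @return `n_tokens x target_dim` matrix.
#' @export
project_stream <- function(tokens, W, b = NULL) {
  tokens <- as.matrix(tokens)
  if (ncol(tokens) != nrow(W))
    stop("projection shape mismatch: stream width ", ncol(tokens),
         " vs weight rows ", nrow(W), call. = FALSE)
  out <- tokens %*% W
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  out
}

#' Substitute learnable embeddings for missing modality inputs
#'
#' Given per-modality fused-input representations and an availability mask,
#' passes available modalities through unchanged and replaces unavailable
#' ones with the corresponding learnable compensation embedding (which is
#' all zeros until trained). With `use_compensation = FALSE`, unavailable
#' modalities are zeroed instead (the ignore-missing baseline).
#'
#' @param fused named list of per-modality representations (numeric vectors
#'   or one-row matrices of equal width).
#' @param availability named logical vector over the same modalities.
#' @param comp named list of compensation embeddings (same width).
#' @param use_compensation replace with the learnable embedding (`TRUE`) or
#'   with zeros (`FALSE`).
#' @return named list matching `fused` with unavailable slots substituted.
#' @export
apply_missing_compensation <- function(fused, availability, comp,
                                       use_compensation = TRUE) {
  out <- fused
  for (m in names(fused)) {
    if (isTRUE(availability[[m]])) next
    v <- fused[[m]]
    rep_val <- if (use_compensation) {
      e <- comp[[m]]
      if (is.null(e)) stop("no compensation embedding for modality `", m, "`", call. = FALSE)
      if (length(e) != length(v))
        stop("compensation embedding for `", m, "` has length ", length(e),
             ", expected ", length(v), call. = FALSE)
      e
    } else {
      numeric(length(v))
    }
    attributes(rep_val) <- attributes(v)
    out[[m]] <- rep_val
  }
  out
}
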