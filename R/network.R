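# Hierarchical multimodal fusion network.
#
# Three fusion stages over embed_dim-wide token streams:
#   1. intramodality: the modality's query stream cross-attends to each of
#      its other streams in parallel; outputs are element-wise summed with
#      the query tokens (residual) and pooled to one vector per patient
#      (F_path, F_us);
#   2. intermodality: F_path and F_us are combined by the configured
#      strategy (affine-align + concat by default; add / multiply /
#      bidirectional single-token cross-attention as alternatives), with
#      dropout applied here during training;
#   3. clinical residual: the intermodal vector, as a single query token,
#      cross-attends to the clinical variable tokens and the output is
#      added back residually (F_final).
# A single affine head maps F_final to the scalar log-relative-hazard.

PATH_STREAMS <- c(deep = "wsi_deep", morph = "wsi_morph", top = "wsi_top")
US_STREAMS <- c(deep = "us_deep", omic = "us_omic", text = "us_text")

#' Fusion architecture configuration
#'
#' @param embed_dim shared attention width (default 1024; smaller values
#'   such as 64 are appropriate for desk-scale experiments).
#' @param n_heads number of attention heads (default 1).
#' @param dropout dropout rate applied in the intermodal fusion stage
#'   during training (default 0.2).
#' @param wsi_query which pathology stream serves as the intramodality
#'   query: `"deep"`, `"morph"` or `"top"`.
#' @param us_query which ultrasound stream serves as the query: `"deep"`,
#'   `"omic"` or `"text"`.
#' @param intermodal_strategy how the pathology and ultrasound vectors are
#'   combined: `"concat"`, `"add"`, `"multiply"` or `"cross_attention"`.
#' @param enabled_streams subset of the six stream names to use.
#' @param enabled_modalities subset of `pathology`, `ultrasound`,
#'   `clinical`.
#' @param use_missing_compensation replace unavailable modalities with
#'   learnable embeddings (`TRUE`) or zero them (`FALSE`).
#' @param token_pooling `"mean"` or `"attention"` pooling of intramodality
#'   tokens.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(embed_dim = 1024,
                          n_heads = 1,
                          dropout = 0.2,
                          wsi_query = "deep",
                          us_query = "deep",
                          intermodal_strategy = c("concat", "add", "multiply", "cross_attention"),
                          enabled_streams = STREAM_NAMES,
                          enabled_modalities = MODALITIES,
                          use_missing_compensation = TRUE,
                          token_pooling = c("mean", "attention")) {
  intermodal_strategy <- match.arg(intermodal_strategy)
  token_pooling <- match.arg(token_pooling)
  if (embed_dim < 1) stop("`embed_dim` must be >= 1", call. = FALSE)
  if (n_heads < 1 || embed_dim %% n_heads != 0)
    stop("`n_heads` must divide `embed_dim`", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  wsi_query <- match.arg(wsi_query, names(PATH_STREAMS))
  us_query <- match.arg(us_query, names(US_STREAMS))
  if (!length(enabled_modalities))
    stop("at least one modality must be enabled", call. = FALSE)
  enabled_streams <- match.arg(enabled_streams, STREAM_NAMES, several.ok = TRUE)
  enabled_modalities <- match.arg(enabled_modalities, MODALITIES, several.ok = TRUE)
  cfg <- structure(list(
    embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads), dropout = dropout,
    wsi_query = wsi_query, us_query = us_query,
    intermodal_strategy = intermodal_strategy,
    enabled_streams = enabled_streams, enabled_modalities = enabled_modalities,
    use_missing_compensation = isTRUE(use_missing_compensation),
    token_pooling = token_pooling
  ), class = "fusion_config")
  if ("pathology" %in% enabled_modalities &&
      !length(intersect(PATH_STREAMS, enabled_streams)))
    stop("pathology enabled but no pathology stream is enabled", call. = FALSE)
  if ("ultrasound" %in% enabled_modalities &&
      !length(intersect(US_STREAMS, enabled_streams)))
    stop("ultrasound enabled but no ultrasound stream is enabled", call. = FALSE)
  cfg
}

# query + key-value slot assignment within one modality, honouring the
# declared stream order and falling back to the next enabled stream when
# the configured query stream is disabled
modality_slots <- function(config, modality) {
  cand <- if (modality == "pathology") PATH_STREAMS else US_STREAMS
  enabled <- cand[cand %in% config$enabled_streams]
  if (!length(enabled)) return(NULL)
  qname <- cand[[if (modality == "pathology") config$wsi_query else config$us_query]]
  q <- if (qname %in% enabled) qname else enabled[[1]]
  list(query = q, kv = setdiff(enabled, q))
}

#' Initialize fusion network parameters
#'
#' Builds the flat named list of parameter arrays for a fusion
#' configuration: per-stream projections, clinical variable encoders,
#' query/key/value/output maps for every cross-attention stage, intermodal
#' alignment maps, pooling vectors, the missing-modality compensation
#' embeddings (initialized to zeros) and the scalar risk head. Weights are
#' drawn `N(0, 1/fan_in)`; biases start at zero.
#'
#' @param config a [fusion_config()].
#' @param stream_dims named integer vector of input widths for the enabled
#'   streams.
#' @param schema a [clinical_schema()].
#' @param seed integer seed for the initialization draw.
#' @return named list of numeric arrays.
#' @export
init_fusion_params <- function(config, stream_dims, schema = clinical_schema(), seed = 1L) {
  set.seed(as.integer(seed))
  E <- config$embed_dim
  w <- function(din, dout) matrix(stats::rnorm(din * dout, sd = 1 / sqrt(din)), din, dout)
  p <- list()
  for (sn in intersect(STREAM_NAMES, config$enabled_streams)) {
    d <- stream_dims[[sn]]
    if (is.null(d)) stop("no input width declared for stream `", sn, "`", call. = FALSE)
    p[[paste0("proj_", sn, "_W")]] <- w(d, E)
    p[[paste0("proj_", sn, "_b")]] <- numeric(E)
  }
  if ("clinical" %in% config$enabled_modalities) {
    for (v in schema$continuous) {
      p[[paste0("clin_cont_", v, "_w")]] <- stats::rnorm(E, sd = 1)
      p[[paste0("clin_cont_", v, "_b")]] <- numeric(E)
    }
    for (v in names(schema$categorical)) {
      L <- schema$categorical[[v]]
      p[[paste0("clin_cat_", v, "_E")]] <- matrix(stats::rnorm(L * E, sd = 1), L, E)
    }
  }
  ca_stages <- c("path_a", "path_b", "us_a", "us_b", "clin", "inter_pu", "inter_up")
  for (st in ca_stages) {
    p[[paste0("ca_", st, "_Wq")]] <- w(E, E); p[[paste0("ca_", st, "_bq")]] <- numeric(E)
    p[[paste0("ca_", st, "_Wk")]] <- w(E, E); p[[paste0("ca_", st, "_bk")]] <- numeric(E)
    p[[paste0("ca_", st, "_Wv")]] <- w(E, E); p[[paste0("ca_", st, "_bv")]] <- numeric(E)
    # zero-initialized output maps: every attention branch starts as the
    # identity residual, so the untrained network is a linear model on the
    # pooled query streams and attention refinements grow in during training
    p[[paste0("ca_", st, "_Wo")]] <- matrix(0, E, E); p[[paste0("ca_", st, "_bo")]] <- numeric(E)
  }
  p$align_path_W <- w(E, E); p$align_path_b <- numeric(E)
  p$align_us_W <- w(E, E); p$align_us_b <- numeric(E)
  p$inter_concat_W <- w(2 * E, E); p$inter_concat_b <- numeric(E)
  if (config$token_pooling == "attention") {
    p$pool_path_w <- stats::rnorm(E, sd = 1 / sqrt(E))
    p$pool_us_w <- stats::rnorm(E, sd = 1 / sqrt(E))
  }
  p$comp_pathology <- numeric(E)   # learnable missing-modality embeddings,
  p$comp_ultrasound <- numeric(E)  # zero-initialized
  p$head_W <- w(E, 1)
  p$head_b <- 0
  p
}

# -- tape builders ------------------------------------------------------------

# push every parameter as a leaf; returns name -> id map
leaf_params <- function(tape, params) {
  ids <- vector("list", length(params))
  names(ids) <- names(params)
  for (nm in names(params)) ids[[nm]] <- ad_leaf(tape, params[[nm]])
  ids
}

record_attention <- function(record, stage, A) {
  if (is.null(record)) return(invisible())
  record$items[[length(record$items) + 1L]] <- list(stage = stage, weights = A)
}

# scaled dot-product cross-attention with learnable Q/K/V/O maps; supports
# n_heads column-partitioned heads
build_ca <- function(tape, pids, prefix, q_id, kv_id, n_heads, record = NULL,
                     stage = prefix) {
  nm <- function(s) pids[[paste0("ca_", prefix, "_", s)]]
  Qp <- ad_linear(tape, q_id, nm("Wq"), nm("bq"))
  Kp <- ad_linear(tape, kv_id, nm("Wk"), nm("bk"))
  Vp <- ad_linear(tape, kv_id, nm("Wv"), nm("bv"))
  E <- dim(ad_value(tape, Qp))[3]
  dh <- E %/% n_heads
  outs <- integer(n_heads)
  att <- NULL
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- if (n_heads == 1L) Qp else ad_cols3(tape, Qp, cols)
    Kh <- if (n_heads == 1L) Kp else ad_cols3(tape, Kp, cols)
    Vh <- if (n_heads == 1L) Vp else ad_cols3(tape, Vp, cols)
    S <- ad_scores(tape, Qh, Kh, scale = 1 / sqrt(dh))
    A <- ad_softmax_last(tape, S)
    att <- if (is.null(att)) ad_value(tape, A) / n_heads else att + ad_value(tape, A) / n_heads
    outs[h] <- ad_attn_apply(tape, A, Vh)
  }
  O <- if (n_heads == 1L) outs[1] else ad_bind3(tape, outs)
  record_attention(record, stage, att)
  ad_linear(tape, O, nm("Wo"), nm("bo"))
}

pool_tokens <- function(tape, pids, x_id, config, which_modality, record = NULL) {
  if (config$token_pooling == "mean") return(ad_mean_tokens(tape, x_id))
  wnm <- if (which_modality == "pathology") "pool_path_w" else "pool_us_w"
  S <- ad_token_scores(tape, x_id, pids[[wnm]])
  A <- ad_softmax_rows(tape, S)
  record_attention(record, paste0("pool_", which_modality), ad_value(tape, A))
  ad_weighted_pool(tape, A, x_id)
}

# intramodality fusion: pool( q + sum_kv CA(q, kv) ); projected stream token
# arrays are supplied in `stream_ids` (name -> tape id)
build_intramodal <- function(tape, pids, stream_ids, config, modality, record = NULL) {
  slots <- modality_slots(config, modality)
  if (is.null(slots)) return(NULL)
  pref <- if (modality == "pathology") "path" else "us"
  q_id <- stream_ids[[slots$query]]
  acc <- q_id
  slot_letter <- c("a", "b")
  for (k in seq_along(slots$kv)) {
    ca <- build_ca(tape, pids, paste0(pref, "_", slot_letter[k]), q_id,
                   stream_ids[[slots$kv[k]]], config$n_heads, record,
                   stage = paste0(pref, "_", slots$kv[k]))
    acc <- ad_add(tape, acc, ca)
  }
  pool_tokens(tape, pids, acc, config, modality, record)
}

build_intermodal <- function(tape, pids, fp_id, fu_id, config, training, record = NULL) {
  strategy <- config$intermodal_strategy
  if (is.null(fp_id) && is.null(fu_id)) return(NULL)
  if (is.null(fp_id) || is.null(fu_id)) {
    f <- if (is.null(fp_id)) fu_id else fp_id
    return(ad_dropout(tape, f, config$dropout, training))
  }
  f_inter <- switch(
    strategy,
    concat = {
      pa <- ad_linear(tape, fp_id, pids$align_path_W, pids$align_path_b)
      ua <- ad_linear(tape, fu_id, pids$align_us_W, pids$align_us_b)
      cc <- ad_concat_cols(tape, pa, ua)
      ad_linear(tape, cc, pids$inter_concat_W, pids$inter_concat_b)
    },
    add = {
      pa <- ad_linear(tape, fp_id, pids$align_path_W, pids$align_path_b)
      ua <- ad_linear(tape, fu_id, pids$align_us_W, pids$align_us_b)
      ad_add(tape, pa, ua)
    },
    multiply = {
      pa <- ad_linear(tape, fp_id, pids$align_path_W, pids$align_path_b)
      ua <- ad_linear(tape, fu_id, pids$align_us_W, pids$align_us_b)
      ad_mul(tape, pa, ua)
    },
    cross_attention = {
      pt <- ad_as_token(tape, fp_id)
      ut <- ad_as_token(tape, fu_id)
      a1 <- build_ca(tape, pids, "inter_pu", pt, ut, config$n_heads, record,
                     stage = "inter_path_to_us")
      a2 <- build_ca(tape, pids, "inter_up", ut, pt, config$n_heads, record,
                     stage = "inter_us_to_path")
      ad_add(tape, ad_drop_token(tape, a1), ad_drop_token(tape, a2))
    },
    stop("unknown intermodal strategy: ", strategy, call. = FALSE)
  )
  ad_dropout(tape, f_inter, config$dropout, training)
}

build_clinical_residual <- function(tape, pids, fi_id, clin_id, config, record = NULL) {
  qt <- ad_as_token(tape, fi_id)
  ca <- build_ca(tape, pids, "clin", qt, clin_id, config$n_heads, record,
                 stage = "clinical")
  ad_add(tape, fi_id, ad_drop_token(tape, ca))
}

# clinical tokens for a batch: cont (n x n_cont, already standardized),
# cat (n x n_cat integer codes)
build_clinical_tokens <- function(tape, pids, cont, cat, schema) {
  tok <- list()
  for (j in seq_along(schema$continuous)) {
    v <- schema$continuous[j]
    tok[[v]] <- ad_outer_affine(tape, cont[, j],
                                pids[[paste0("clin_cont_", v, "_w")]],
                                pids[[paste0("clin_cont_", v, "_b")]])
  }
  for (v in names(schema$categorical)) {
    tok[[v]] <- ad_embed(tape, pids[[paste0("clin_cat_", v, "_E")]], cat[, v])
  }
  ad_stack_tokens(tape, unlist(tok, use.names = FALSE))
}

# full batched forward; tensors as produced by cohort_tensors(). Returns the
# tape plus node ids of the stage outputs and risk.
build_forward <- function(tape, pids, tensors, config, schema, training = FALSE,
                          record = NULL) {
  n <- tensors$n
  # project enabled streams to embed_dim
  stream_ids <- list()
  for (sn in intersect(names(tensors$streams), config$enabled_streams)) {
    x <- ad_leaf(tape, tensors$streams[[sn]])
    stream_ids[[sn]] <- ad_linear(tape, x, pids[[paste0("proj_", sn, "_W")]],
                                  pids[[paste0("proj_", sn, "_b")]])
  }
  fp <- fu <- NULL
  if ("pathology" %in% config$enabled_modalities) {
    fp <- build_intramodal(tape, pids, stream_ids, config, "pathology", record)
    fp <- ad_mask_replace(tape, fp,
                          if (config$use_missing_compensation) pids$comp_pathology
                          else ad_leaf(tape, numeric(config$embed_dim)),
                          tensors$avail[, "pathology"])
  }
  if ("ultrasound" %in% config$enabled_modalities) {
    fu <- build_intramodal(tape, pids, stream_ids, config, "ultrasound", record)
    fu <- ad_mask_replace(tape, fu,
                          if (config$use_missing_compensation) pids$comp_ultrasound
                          else ad_leaf(tape, numeric(config$embed_dim)),
                          tensors$avail[, "ultrasound"])
  }
  fi <- build_intermodal(tape, pids, fp, fu, config, training, record)
  use_clin <- "clinical" %in% config$enabled_modalities && n_clinical_tokens(schema) > 0
  if (use_clin) {
    clin_id <- build_clinical_tokens(tape, pids, tensors$clin_cont, tensors$clin_cat, schema)
    ff <- if (is.null(fi)) ad_mean_tokens(tape, clin_id)
          else build_clinical_residual(tape, pids, fi, clin_id, config, record)
  } else {
    if (is.null(fi))
      stop("all modalities disabled: nothing to fuse", call. = FALSE)
    ff <- fi
  }
  risk <- ad_linear(tape, ff, pids$head_W, pids$head_b)
  list(f_path = fp, f_us = fu, f_inter = fi, f_final = ff, risk = risk)
}

# batch tensors from a cohort; `center`/`scale` standardize continuous
# clinical variables (fitted on the training split)
cohort_tensors <- function(cohort, schema = cohort$schema, center = NULL, scale = NULL) {
  pats <- cohort$patients
  n <- length(pats)
  snames <- names(pats[[1]]$streams)
  streams <- lapply(stats::setNames(snames, snames), function(sn) {
    tk <- nrow(pats[[1]]$streams[[sn]]); d <- ncol(pats[[1]]$streams[[sn]])
    a <- array(0, c(n, tk, d))
    for (i in seq_len(n)) a[i, , ] <- pats[[i]]$streams[[sn]]
    a
  })
  ncont <- length(schema$continuous)
  cont <- matrix(0, n, max(ncont, 1L))
  if (ncont) {
    cont <- t(vapply(pats, function(p) as.numeric(p$clinical$continuous[schema$continuous]),
                     numeric(ncont)))
    if (ncont == 1L) cont <- matrix(cont, n, 1L)
    if (!is.null(center)) cont <- sweep(cont, 2L, center, "-")
    if (!is.null(scale)) cont <- sweep(cont, 2L, pmax(scale, 1e-8), "/")
  }
  ncat <- length(schema$categorical)
  cat <- matrix(1L, n, max(ncat, 1L))
  if (ncat) {
    cat <- t(vapply(pats, function(p) as.integer(p$clinical$categorical[names(schema$categorical)]),
                    integer(ncat)))
    if (ncat == 1L) cat <- matrix(cat, n, 1L)
    colnames(cat) <- names(schema$categorical)
  }
  avail <- t(vapply(pats, function(p) as.logical(p$availability[MODALITIES]), logical(3)))
  colnames(avail) <- MODALITIES
  list(n = n, streams = streams, clin_cont = cont, clin_cat = cat, avail = avail,
       time = vapply(pats, function(p) p$outcome$time_months, numeric(1)),
       event = vapply(pats, function(p) p$outcome$event, numeric(1)),
       ids = vapply(pats, `[[`, character(1), "patient_id"))
}

#' Run the fusion network forward over a cohort
#'
#' Evaluation-mode forward pass: returns the per-stage fused
#' representations, the scalar risk per patient and (optionally) every
#' attention weight matrix.
#'
#' @param cohort a `fusion_cohort`.
#' @param config a [fusion_config()].
#' @param params parameter list from [init_fusion_params()] or a fitted
#'   model.
#' @param schema clinical schema (defaults to the cohort's).
#' @param center,scale standardization for continuous clinical variables.
#' @param record_attention collect attention weights per stage.
#' @return list with `risk` (named numeric vector), `f_path`, `f_us`,
#'   `f_inter`, `f_final` (matrices, patients in rows) and
#'   `attention_records`.
#' @export
fusion_forward <- function(cohort, config, params, schema = NULL,
                           center = NULL, scale = NULL, record_attention = FALSE) {
  schema <- schema %||% cohort$schema
  tensors <- cohort_tensors(cohort, schema, center, scale)
  tape <- ad_tape()
  pids <- leaf_params(tape, params)
  rec <- if (record_attention) new.env(parent = emptyenv()) else NULL
  if (!is.null(rec)) rec$items <- list()
  out <- build_forward(tape, pids, tensors, config, schema, training = FALSE, record = rec)
  gv <- function(id) if (is.null(id)) NULL else ad_value(tape, id)
  risk <- as.numeric(gv(out$risk))
  names(risk) <- tensors$ids
  list(risk = risk,
       f_path = gv(out$f_path), f_us = gv(out$f_us),
       f_inter = gv(out$f_inter), f_final = gv(out$f_final),
       attention_records = if (!is.null(rec)) rec$items else NULL,
       ids = tensors$ids)
}

# -- exported single-fixture stage operations ---------------------------------

# wrap a single patient's token matrix (t x d) as a batch-of-one array
.as_batch1 <- function(m) {
  m <- as.matrix(m)
  array(m, c(1L, nrow(m), ncol(m)))
}

.unbatch1 <- function(a) matrix(a[1, , ], dim(a)[2], dim(a)[3])

#' Scaled dot-product cross-attention block
#'
#' Queries come from one token stream, keys and values from another;
#' learnable query/key/value/output maps; per-query attention weights over
#' keys sum to one. Output token count equals the query token count.
#'
#' @param queries `tq x d` token matrix.
#' @param keys_values `tk x d` token matrix.
#' @param params list with `Wq`, `bq`, `Wk`, `bk`, `Wv`, `bv`, `Wo`, `bo`.
#' @param n_heads number of attention heads (must divide the embed width).
#' @return list with `output` (`tq x d`) and `attention` (`tq x tk`,
#'   rows sum to 1; averaged over heads if `n_heads > 1`).
#' @export
cross_attention_block <- function(queries, keys_values, params, n_heads = 1) {
  queries <- as.matrix(queries); keys_values <- as.matrix(keys_values)
  if (ncol(queries) != ncol(keys_values))
    stop("query and key-value widths differ (", ncol(queries), " vs ",
         ncol(keys_values), ")", call. = FALSE)
  tape <- ad_tape()
  pid <- leaf_params(tape, stats::setNames(params[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")],
                                           paste0("ca_x_", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))))
  q <- ad_leaf(tape, .as_batch1(queries))
  kv <- ad_leaf(tape, .as_batch1(keys_values))
  rec <- new.env(parent = emptyenv()); rec$items <- list()
  out <- build_ca(tape, pid, "x", q, kv, n_heads, rec)
  A <- rec$items[[1]]$weights
  list(output = .unbatch1(ad_value(tape, out)),
       attention = matrix(A[1, , ], nrow(queries), nrow(keys_values)))
}

# run one modality's intramodality fusion for a single patient fixture;
# streams must already be embed_dim wide
.fuse_intra_fixture <- function(streams, config, params, modality) {
  slots <- modality_slots(config, modality)
  if (is.null(slots)) stop("no ", modality, " stream enabled", call. = FALSE)
  missing_streams <- setdiff(c(slots$query, slots$kv), names(streams))
  if (length(missing_streams))
    stop("missing ", modality, " stream(s): ", paste(missing_streams, collapse = ", "),
         call. = FALSE)
  tape <- ad_tape()
  pids <- leaf_params(tape, params)
  stream_ids <- lapply(streams, function(m) ad_leaf(tape, .as_batch1(m)))
  rec <- new.env(parent = emptyenv()); rec$items <- list()
  f <- build_intramodal(tape, pids, stream_ids, config, modality, rec)
  list(fused = as.numeric(ad_value(tape, f)), attention_records = rec$items)
}

#' Intramodality fusion of the pathology streams
#'
#' The configured query stream cross-attends to each other enabled
#' pathology stream in parallel; outputs are element-wise summed with the
#' query tokens and pooled.
#'
#' @param streams named list of `embed_dim`-wide token matrices
#'   (`wsi_deep`, `wsi_morph`, `wsi_top`).
#' @param config a [fusion_config()].
#' @param params parameter list (uses the `ca_path_*` and pooling entries).
#' @return list with `fused` (length-`embed_dim` vector) and
#'   `attention_records`.
#' @export
fuse_pathology <- function(streams, config, params)
  .fuse_intra_fixture(streams, config, params, "pathology")

#' Intramodality fusion of the ultrasound streams
#'
#' Symmetric to [fuse_pathology()] over `us_deep`, `us_omic`, `us_text`.
#'
#' @inheritParams fuse_pathology
#' @return list with `fused` and `attention_records`.
#' @export
fuse_ultrasound <- function(streams, config, params)
  .fuse_intra_fixture(streams, config, params, "ultrasound")

#' Intermodality fusion of pathology and ultrasound vectors
#'
#' Combines the two modality vectors by the configured strategy: affine
#' alignment followed by concatenation back to `embed_dim` (default),
#' element-wise addition or multiplication after alignment, or
#' bidirectional single-token cross-attention with the two outputs summed.
#'
#' @param f_path,f_us length-`embed_dim` fused modality vectors.
#' @param strategy one of `"concat"`, `"add"`, `"multiply"`,
#'   `"cross_attention"`.
#' @param params parameter list.
#' @param config optional [fusion_config()] (its strategy is overridden by
#'   `strategy`).
#' @return length-`embed_dim` intermodal vector.
#' @export
fuse_intermodal <- function(f_path, f_us, strategy, params, config = NULL) {
  if (is.null(config)) {
    E <- length(f_path)
    config <- fusion_config(embed_dim = E, dropout = 0, intermodal_strategy = strategy)
  } else {
    config$intermodal_strategy <- strategy
  }
  if (!strategy %in% c("concat", "add", "multiply", "cross_attention"))
    stop("unknown intermodal strategy: ", strategy, call. = FALSE)
  tape <- ad_tape()
  pids <- leaf_params(tape, params)
  fp <- ad_leaf(tape, matrix(f_path, 1L))
  fu <- ad_leaf(tape, matrix(f_us, 1L))
  fi <- build_intermodal(tape, pids, fp, fu, config, training = FALSE)
  as.numeric(ad_value(tape, fi))
}

#' Clinical residual fusion
#'
#' The intermodal vector, as a single query token, cross-attends to the
#' clinical variable tokens; the attended output is added back through a
#' residual connection. Attention weights over clinical variables are
#' returned for variable-importance export.
#'
#' @param f_inter length-`embed_dim` intermodal vector.
#' @param clinical_tokens `n_vars x embed_dim` clinical token matrix (see
#'   [encode_clinical()]).
#' @param params parameter list (uses the `ca_clin_*` entries).
#' @param n_heads attention heads.
#' @return list with `f_final` (vector) and `attention` (weights over
#'   clinical tokens, summing to 1).
#' @export
fuse_clinical_residual <- function(f_inter, clinical_tokens, params, n_heads = 1) {
  cfg <- list(n_heads = as.integer(n_heads))
  tape <- ad_tape()
  pids <- leaf_params(tape, params)
  fi <- ad_leaf(tape, matrix(f_inter, 1L))
  cl <- ad_leaf(tape, .as_batch1(clinical_tokens))
  rec <- new.env(parent = emptyenv()); rec$items <- list()
  ff <- build_clinical_residual(tape, pids, fi, cl, cfg, rec)
  list(f_final = as.numeric(ad_value(tape, ff)),
       attention = as.numeric(rec$items[[1]]$weights[1, 1, ]))
}

#' Export attention records as a long table
#'
#' @param forward result of [fusion_forward()] with
#'   `record_attention = TRUE`.
#' @param variable_names optional names for the key tokens of the clinical
#'   stage.
#' @return data frame with columns `patient_id`, `stage`, `query_token`,
#'   `key_token`, `weight`.
#' @export
attention_table <- function(forward, variable_names = NULL) {
  recs <- forward$attention_records
  if (is.null(recs)) stop("forward pass was run without attention recording", call. = FALSE)
  out <- list()
  for (r in recs) {
    A <- r$weights
    if (length(dim(A)) == 2L) A <- array(A, c(nrow(A), 1L, ncol(A)))  # pooling weights
    n <- dim(A)[1]; tq <- dim(A)[2]; tk <- dim(A)[3]
    keys <- if (r$stage == "clinical" && !is.null(variable_names)) variable_names
            else as.character(seq_len(tk))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = rep(forward$ids, times = tq * tk),
      stage = r$stage,
      query_token = rep(rep(seq_len(tq), each = n), times = tk),
      key_token = rep(keys, each = n * tq),
      weight = as.numeric(A))
  }
  do.call(rbind, out)
}

#' Save / load a parameter checkpoint
#'
#' The checkpoint is a flat named-array archive with the fusion
#' configuration, clinical schema and standardization snapshot embedded;
#' the round-trip is exact.
#'
#' @param params parameter list.
#' @param config a [fusion_config()].
#' @param path file path.
#' @param schema clinical schema.
#' @param extra optional list of additional snapshot entries.
#' @return `path` invisibly (`save_checkpoint`); the checkpoint list
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(params, config, path, schema = clinical_schema(), extra = list()) {
  obj <- c(list(params = params, config = config, schema = schema,
                package_version = as.character(utils::packageVersion("fusesurv"))),
           extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
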