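# The fusion architecture against independently coded dense oracles, plus
# its residual, pooling, ablation and determinism contracts.

test_that("cross-attention matches the dense oracle and normalizes weights", {
  set.seed(1)
  E <- 8
  Q <- matrix(rnorm(3 * E), 3, E)
  K <- matrix(rnorm(4 * E), 4, E)
  p <- rand_ca_params(E, seed = 2)
  got <- cross_attention_block(Q, K, p)
  expect_equal(got$output, oracle_ca(Q, K, p), tolerance = 1e-6)
  expect_equal(rowSums(got$attention), rep(1, 3), tolerance = 1e-6)
  expect_equal(dim(got$output), c(3, E))
})

test_that("with a single key-value token the output ignores the queries", {
  E <- 6
  p <- rand_ca_params(E, seed = 3)
  kv <- matrix(rnorm(E), 1, E)
  q1 <- matrix(rnorm(2 * E), 2, E)
  q2 <- matrix(rnorm(2 * E), 2, E)
  o1 <- cross_attention_block(q1, kv, p)$output
  o2 <- cross_attention_block(q2, kv, p)$output
  expect_equal(o1, o2, tolerance = 1e-10)
  vp <- sweep(kv %*% p$Wv, 2, p$bv, "+")
  expected <- sweep(vp %*% p$Wo, 2, p$bo, "+")
  expect_equal(o1[1, , drop = FALSE], expected, tolerance = 1e-10)
})

test_that("mismatched widths are rejected", {
  p <- rand_ca_params(4, seed = 1)
  expect_error(cross_attention_block(matrix(0, 2, 4), matrix(0, 2, 5), p), "width")
})

# parameters for a small full network with informative output maps
small_net_params <- function(co, fc, seed = 7) {
  sd_in <- vapply(co$patients[[1]]$streams, ncol, integer(1))
  params <- init_fusion_params(fc, sd_in, co$schema, seed = seed)
  set.seed(seed + 50)
  for (nm in grep("_Wo$", names(params), value = TRUE))
    params[[nm]] <- matrix(rnorm(length(params[[nm]]), sd = 0.3), nrow(params[[nm]]))
  params
}

test_that("pathology fusion equals the hand-composed attention + residual + pool", {
  co <- tiny_cohort(n = 3, seed = 5)
  fc <- tiny_fusion(E = 8)
  params <- small_net_params(co, fc)
  pnames <- c("wsi_deep", "wsi_morph", "wsi_top")
  streams <- lapply(setNames(pnames, pnames), function(nm)
    project_stream(co$patients[[1]]$streams[[nm]],
                   params[[paste0("proj_", nm, "_W")]],
                   params[[paste0("proj_", nm, "_b")]]))
  got <- fuse_pathology(streams, fc, params)$fused
  sub <- function(stage) setNames(params[paste0("ca_", stage, "_",
                                                c("Wq","bq","Wk","bk","Wv","bv","Wo","bo"))],
                                  c("Wq","bq","Wk","bk","Wv","bv","Wo","bo"))
  manual <- streams$wsi_deep +
    cross_attention_block(streams$wsi_deep, streams$wsi_morph, sub("path_a"))$output +
    cross_attention_block(streams$wsi_deep, streams$wsi_top, sub("path_b"))$output
  expect_equal(got, colMeans(manual), tolerance = 1e-8)
  expect_length(got, fc$embed_dim)
})

test_that("zeroed output projections reduce each stage to its residual", {
  co <- tiny_cohort(n = 4, seed = 6)
  fc <- tiny_fusion(E = 8, intermodal_strategy = "add")
  sd_in <- vapply(co$patients[[1]]$streams, ncol, integer(1))
  params <- init_fusion_params(fc, sd_in, co$schema, seed = 3)  # Wo/bo start at zero
  params$align_path_W <- diag(8); params$align_us_W <- diag(8)
  fwd <- fusion_forward(co, fc, params)
  # f_path is exactly the pooled projected query stream
  tens <- fusesurv:::cohort_tensors(co, co$schema)
  proj <- fusesurv:::.flat2(tens$streams$wsi_deep) %*% params$proj_wsi_deep_W
  proj <- sweep(proj, 2, params$proj_wsi_deep_b, "+")
  pooled <- apply(array(proj, c(4, 3, 8)), c(1, 3), mean)
  expect_equal(fwd$f_path, pooled, tolerance = 1e-10)
  # intermodal add with identity alignment, then untouched by clinical stage
  expect_equal(fwd$f_inter, fwd$f_path + fwd$f_us, tolerance = 1e-10)
  expect_equal(fwd$f_final, fwd$f_inter, tolerance = 1e-10)
  expect_equal(as.numeric(fwd$risk),
               as.numeric(fwd$f_final %*% params$head_W + params$head_b),
               tolerance = 1e-10)
})

test_that("ultrasound fusion honours query reassignment", {
  co <- tiny_cohort(n = 2, seed = 8)
  fc <- tiny_fusion(E = 8, us_query = "text")
  params <- small_net_params(co, fc)
  streams <- lapply(c(us_deep = "us_deep", us_omic = "us_omic", us_text = "us_text"),
                    function(nm) project_stream(co$patients[[1]]$streams[[nm]],
                                                params[[paste0("proj_", nm, "_W")]],
                                                params[[paste0("proj_", nm, "_b")]]))
  got <- fuse_ultrasound(streams, fc, params)$fused
  expect_length(got, 8)
  # with zeroed output maps the result is the pooled text token (the query)
  p0 <- params
  for (nm in grep("_Wo$|_bo$", names(p0), value = TRUE)) p0[[nm]] <- p0[[nm]] * 0
  got0 <- fuse_ultrasound(streams, fc, p0)$fused
  expect_equal(got0, colMeans(streams$us_text), tolerance = 1e-10)
})

test_that("intermodal strategies follow their algebra", {
  E <- 4
  params <- list(align_path_W = diag(E), align_path_b = numeric(E),
                 align_us_W = diag(E), align_us_b = numeric(E))
  fp <- rnorm(E); fu <- rnorm(E)
  expect_equal(fuse_intermodal(fp, numeric(E), "add", params), fp)
  expect_equal(fuse_intermodal(fp, rep(1, E), "multiply", params), fp)
  expect_error(fuse_intermodal(fp, fu, "average", params), "average|arg")
})

test_that("concat intermodal fusion reproduces a hand-computed affine", {
  params <- list(align_path_W = diag(2), align_path_b = numeric(2),
                 align_us_W = diag(2), align_us_b = numeric(2),
                 inter_concat_W = matrix(c(1, 0, 2, 0,
                                           0, 3, 0, 4), 4, 2),
                 inter_concat_b = c(0.5, -0.5))
  fp <- c(1, 2); fu <- c(3, 4)
  got <- fuse_intermodal(fp, fu, "concat", params)
  expect_equal(got, as.numeric(c(fp, fu) %*% params$inter_concat_W +
                                 params$inter_concat_b))
})

test_that("clinical residual stage adds the attended clinical summary", {
  E <- 6
  p <- prefix_ca(rand_ca_params(E, seed = 9), "clin")
  fi <- rnorm(E)
  tok1 <- matrix(rnorm(E), 1, E)
  got <- fuse_clinical_residual(fi, tok1, p)
  expect_equal(sum(got$attention), 1, tolerance = 1e-10)
  raw <- setNames(p, sub("^ca_clin_", "", names(p)))
  expected <- fi + as.numeric(oracle_ca(matrix(fi, 1), tok1, raw))
  expect_equal(got$f_final, expected, tolerance = 1e-8)
  # zeroed output map leaves the residual untouched
  p0 <- p; p0$ca_clin_Wo <- p0$ca_clin_Wo * 0; p0$ca_clin_bo <- p0$ca_clin_bo * 0
  expect_equal(fuse_clinical_residual(fi, tok1, p0)$f_final, fi)
})

test_that("the full forward pass equals the composition of its stages", {
  co <- tiny_cohort(n = 3, seed = 11)
  fc <- tiny_fusion(E = 8)
  params <- small_net_params(co, fc, seed = 12)
  fwd <- fusion_forward(co, fc, params)
  for (i in 1:3) {
    pat <- co$patients[[i]]
    proj <- lapply(setNames(names(pat$streams), names(pat$streams)), function(nm)
      project_stream(pat$streams[[nm]], params[[paste0("proj_", nm, "_W")]],
                     params[[paste0("proj_", nm, "_b")]]))
    fp <- fuse_pathology(proj[c("wsi_deep", "wsi_morph", "wsi_top")], fc, params)$fused
    fu <- fuse_ultrasound(proj[c("us_deep", "us_omic", "us_text")], fc, params)$fused
    fi <- fuse_intermodal(fp, fu, fc$intermodal_strategy, params, config = fc)
    tok <- encode_clinical(pat$clinical, params, co$schema)
    ff <- fuse_clinical_residual(fi, tok, params)$f_final
    risk <- as.numeric(ff %*% params$head_W + params$head_b)
    expect_equal(unname(fwd$risk[i]), risk, tolerance = 1e-8)
    expect_equal(fwd$f_path[i, ], fp, tolerance = 1e-8)
    expect_equal(fwd$f_final[i, ], ff, tolerance = 1e-8)
  }
})

test_that("risks are deterministic and duplicated records agree", {
  co <- tiny_cohort(n = 4, seed = 13)
  co$patients[[2]] <- co$patients[[1]]
  co$patients[[2]]$patient_id <- "copy"
  fc <- tiny_fusion(E = 8)
  params <- small_net_params(co, fc)
  f1 <- fusion_forward(co, fc, params)
  f2 <- fusion_forward(co, fc, params)
  expect_identical(f1$risk, f2$risk)
  expect_equal(unname(f1$risk[1]), unname(f1$risk[2]), tolerance = 1e-12)
})

test_that("pathology-only configurations ignore ultrasound inputs", {
  co <- tiny_cohort(n = 3, seed = 14)
  fc <- tiny_fusion(E = 8, enabled_modalities = "pathology",
                    enabled_streams = c("wsi_deep", "wsi_morph", "wsi_top"))
  params <- small_net_params(co, fc)
  base <- fusion_forward(co, fc, params)$risk
  co$patients[[1]]$streams$us_deep[] <- 99
  co$patients[[2]]$streams$us_text[] <- -99
  expect_equal(fusion_forward(co, fc, params)$risk, base, tolerance = 1e-12)
})

test_that("all modalities disabled is a configuration error", {
  expect_error(fusion_config(enabled_modalities = character(0)), "one modality")
})

test_that("shuffling pathology patches leaves the risk unchanged (mean pooling)", {
  co <- tiny_cohort(n = 3, seed = 15)
  fc <- tiny_fusion(E = 8)
  params <- small_net_params(co, fc)
  base <- fusion_forward(co, fc, params)$risk
  for (i in seq_along(co$patients)) {
    perm <- sample(nrow(co$patients[[i]]$streams$wsi_deep))
    co$patients[[i]]$streams$wsi_deep <-
      co$patients[[i]]$streams$wsi_deep[perm, , drop = FALSE]
  }
  expect_equal(fusion_forward(co, fc, params)$risk, base, tolerance = 1e-6)
})

test_that("every recorded attention row sums to one", {
  co <- tiny_cohort(n = 5, seed = 16)
  fc <- tiny_fusion(E = 8, token_pooling = "attention",
                    intermodal_strategy = "cross_attention")
  params <- small_net_params(co, fc)
  fwd <- fusion_forward(co, fc, params, record_attention = TRUE)
  expect_gt(length(fwd$attention_records), 0)
  for (r in fwd$attention_records) {
    A <- r$weights
    if (length(dim(A)) == 3) {
      sums <- apply(A, c(1, 2), sum)
    } else {
      sums <- rowSums(A)
    }
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-6)
  }
  tab <- attention_table(fwd, variable_names = rownames(
    encode_clinical(co$patients[[1]]$clinical, params, co$schema)))
  expect_true(all(c("patient_id", "stage", "weight") %in% names(tab)))
  expect_true("age" %in% tab$key_token[tab$stage == "clinical"])
})

test_that("checkpoints round-trip exactly", {
  co <- tiny_cohort(n = 4, seed = 17)
  fc <- tiny_fusion(E = 8)
  params <- small_net_params(co, fc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, fc, path, schema = co$schema)
  ck <- load_checkpoint(path)
  expect_identical(ck$params, params)
  expect_identical(
    fusion_forward(co, fc, params)$risk,
    fusion_forward(co, ck$config, ck$params)$risk)
})
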