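# Reverse-mode autodiff tape over numeric arrays.
#
# The fusion network needs gradients of a scalar Cox loss with respect to a
# few dozen parameter arrays. Values on the tape are either matrices
# (n_patients x dim) or 3-d arrays (n_patients x n_tokens x dim); every op
# records a closure that maps the incoming gradient to gradients for its
# parents. Gradients are checked against central finite differences in the
# test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$backs <- list()    # backs[[id]]: NULL for leaves, else list(parents=ids, fn=function(g) list of grads)
  tp$n <- 0L
  tp
}

ad_push <- function(tape, value, parents = NULL, backfn = NULL) {
  id <- tape$n + 1L
  tape$n <- id
  tape$vals[[id]] <- value
  bk <- if (is.null(backfn)) NULL else list(parents = as.integer(parents), fn = backfn)
  tape$backs[id] <- list(bk)  # [<- keeps NULL slots instead of dropping them
  id
}

ad_leaf <- function(tape, value) ad_push(tape, value)

ad_value <- function(tape, id) tape$vals[[id]]

# Backpropagate from `seed_id` with gradient `seed_grad` (same shape as the
# node value). Returns a list of gradients indexed by node id (NULL where no
# gradient flowed).
ad_backward <- function(tape, seed_id, seed_grad) {
  grads <- vector("list", tape$n)
  grads[[seed_id]] <- seed_grad
  for (id in seq.int(tape$n, 1L)) {
    g <- grads[[id]]
    bk <- tape$backs[[id]]
    if (is.null(g) || is.null(bk)) next
    pg <- bk$fn(g)
    for (k in seq_along(bk$parents)) {
      if (is.null(pg[[k]])) next
      p <- bk$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# -- shape helpers ------------------------------------------------------------

# token slice of a 3-d array as an n x d matrix (robust to n == 1 / d == 1)
.tok <- function(x, i) {
  d <- dim(x)
  matrix(x[, i, ], d[1], d[3])
}

.flat2 <- function(x) {  # (n, t, d) -> (n*t, d), column-major collapse of dims 1:2
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

.unflat2 <- function(x, n, t) {
  d2 <- ncol(x)
  dim(x) <- c(n, t, d2)
  x
}

# -- primitive ops ------------------------------------------------------------

# y = x W + b with x either (n, d) or (n, t, d); W: (d, e), b: length e
ad_linear <- function(tape, x_id, W_id, b_id) {
  force(x_id); force(W_id); force(b_id)
  x <- tape$vals[[x_id]]; W <- tape$vals[[W_id]]; b <- tape$vals[[b_id]]
  is3 <- length(dim(x)) == 3L
  xm <- if (is3) .flat2(x) else x
  ym <- xm %*% W
  ym <- sweep(ym, 2L, b, "+")
  y <- if (is3) .unflat2(ym, dim(x)[1], dim(x)[2]) else ym
  ad_push(tape, y, parents = c(x_id, W_id, b_id), backfn = function(g) {
    gm <- if (is3) .flat2(g) else g
    dx <- gm %*% t(W)
    if (is3) dx <- .unflat2(dx, dim(x)[1], dim(x)[2])
    list(dx, crossprod(xm, gm), colSums(gm))
  })
}

ad_add <- function(tape, a_id, b_id) {
  force(a_id); force(b_id)
  a <- tape$vals[[a_id]]; b <- tape$vals[[b_id]]
  ad_push(tape, a + b, parents = c(a_id, b_id), backfn = function(g) list(g, g))
}

ad_mul <- function(tape, a_id, b_id) {
  force(a_id); force(b_id)
  a <- tape$vals[[a_id]]; b <- tape$vals[[b_id]]
  ad_push(tape, a * b, parents = c(a_id, b_id), backfn = function(g) list(g * b, g * a))
}

# elementwise product with a constant array (no gradient to the constant);
# `m` is recycled by R's rules, so it must be a full-shape array or scalar
ad_mul_const <- function(tape, x_id, m) {
  force(x_id)
  x <- tape$vals[[x_id]]
  ad_push(tape, x * m, parents = x_id, backfn = function(g) list(g * m))
}

ad_scale <- function(tape, x_id, s) ad_mul_const(tape, x_id, s)

# attention scores: Q (n, tq, e), K (n, tk, e) -> S (n, tq, tk),
# S[p, i, j] = scale * <Q[p, i, ], K[p, j, ]>
ad_scores <- function(tape, q_id, k_id, scale) {
  force(q_id); force(k_id)
  Q <- tape$vals[[q_id]]; K <- tape$vals[[k_id]]
  n <- dim(Q)[1]; tq <- dim(Q)[2]; tk <- dim(K)[2]
  S <- array(0, c(n, tq, tk))
  Ks <- lapply(seq_len(tk), function(j) .tok(K, j))
  Qs <- lapply(seq_len(tq), function(i) .tok(Q, i))
  for (i in seq_len(tq)) for (j in seq_len(tk))
    S[, i, j] <- rowSums(Qs[[i]] * Ks[[j]]) * scale
  ad_push(tape, S, parents = c(q_id, k_id), backfn = function(g) {
    dQ <- array(0, dim(Q)); dK <- array(0, dim(K))
    for (i in seq_len(tq)) {
      acc <- matrix(0, n, dim(Q)[3])
      for (j in seq_len(tk)) {
        gij <- g[, i, j] * scale
        acc <- acc + gij * Ks[[j]]
        dK[, j, ] <- .tok(dK, j) + gij * Qs[[i]]
      }
      dQ[, i, ] <- acc
    }
    list(dQ, dK)
  })
}

# softmax over the last (key) dimension of S (n, tq, tk)
ad_softmax_last <- function(tape, s_id) {
  force(s_id)
  S <- tape$vals[[s_id]]
  n <- dim(S)[1]; tq <- dim(S)[2]; tk <- dim(S)[3]
  A <- array(0, dim(S))
  for (i in seq_len(tq)) {
    m <- matrix(S[, i, ], n, tk)
    m <- exp(m - apply(m, 1L, max))
    A[, i, ] <- m / rowSums(m)
  }
  ad_push(tape, A, parents = s_id, backfn = function(g) {
    dS <- array(0, dim(S))
    for (i in seq_len(tq)) {
      Ai <- matrix(A[, i, ], n, tk); Gi <- matrix(g[, i, ], n, tk)
      dS[, i, ] <- Ai * (Gi - rowSums(Gi * Ai))
    }
    list(dS)
  })
}

# attention application: A (n, tq, tk), V (n, tk, e) -> O (n, tq, e)
ad_attn_apply <- function(tape, a_id, v_id) {
  force(a_id); force(v_id)
  A <- tape$vals[[a_id]]; V <- tape$vals[[v_id]]
  n <- dim(A)[1]; tq <- dim(A)[2]; tk <- dim(A)[3]; e <- dim(V)[3]
  Vs <- lapply(seq_len(tk), function(j) .tok(V, j))
  O <- array(0, c(n, tq, e))
  for (i in seq_len(tq)) {
    acc <- matrix(0, n, e)
    for (j in seq_len(tk)) acc <- acc + A[, i, j] * Vs[[j]]
    O[, i, ] <- acc
  }
  ad_push(tape, O, parents = c(a_id, v_id), backfn = function(g) {
    dA <- array(0, dim(A)); dV <- array(0, dim(V))
    for (i in seq_len(tq)) {
      Gi <- matrix(g[, i, ], n, e)
      for (j in seq_len(tk)) {
        dA[, i, j] <- rowSums(Gi * Vs[[j]])
        dV[, j, ] <- .tok(dV, j) + A[, i, j] * Gi
      }
    }
    list(dA, dV)
  })
}

# mean over the token axis: (n, t, e) -> (n, e)
ad_mean_tokens <- function(tape, x_id) {
  force(x_id)
  x <- tape$vals[[x_id]]
  n <- dim(x)[1]; t <- dim(x)[2]; e <- dim(x)[3]
  y <- matrix(0, n, e)
  for (j in seq_len(t)) y <- y + .tok(x, j)
  y <- y / t
  ad_push(tape, y, parents = x_id, backfn = function(g) {
    dx <- array(0, dim(x))
    for (j in seq_len(t)) dx[, j, ] <- g / t
    list(dx)
  })
}

# weighted token pool: A (n, t) row-stochastic, x (n, t, e) -> (n, e)
ad_weighted_pool <- function(tape, a_id, x_id) {
  force(a_id); force(x_id)
  A <- tape$vals[[a_id]]; x <- tape$vals[[x_id]]
  n <- dim(x)[1]; t <- dim(x)[2]; e <- dim(x)[3]
  xs <- lapply(seq_len(t), function(j) .tok(x, j))
  y <- matrix(0, n, e)
  for (j in seq_len(t)) y <- y + A[, j] * xs[[j]]
  ad_push(tape, y, parents = c(a_id, x_id), backfn = function(g) {
    dA <- matrix(0, n, t); dx <- array(0, dim(x))
    for (j in seq_len(t)) {
      dA[, j] <- rowSums(g * xs[[j]])
      dx[, j, ] <- A[, j] * g
    }
    list(dA, dx)
  })
}

# row-wise softmax of a matrix (n, t)
ad_softmax_rows <- function(tape, s_id) {
  force(s_id)
  S <- tape$vals[[s_id]]
  m <- exp(S - apply(S, 1L, max))
  A <- m / rowSums(m)
  ad_push(tape, A, parents = s_id, backfn = function(g) {
    list(A * (g - rowSums(g * A)))
  })
}

# token scores for attention pooling: x (n, t, e), w (e) -> (n, t)
ad_token_scores <- function(tape, x_id, w_id) {
  force(x_id); force(w_id)
  x <- tape$vals[[x_id]]; w <- tape$vals[[w_id]]
  n <- dim(x)[1]; t <- dim(x)[2]
  S <- matrix(0, n, t)
  for (j in seq_len(t)) S[, j] <- .tok(x, j) %*% w
  ad_push(tape, S, parents = c(x_id, w_id), backfn = function(g) {
    dx <- array(0, dim(x)); dw <- numeric(length(w))
    for (j in seq_len(t)) {
      dx[, j, ] <- outer(g[, j], as.numeric(w))
      dw <- dw + as.numeric(crossprod(.tok(x, j), g[, j]))
    }
    list(dx, dw)
  })
}

ad_concat_cols <- function(tape, a_id, b_id) {
  force(a_id); force(b_id)
  a <- tape$vals[[a_id]]; b <- tape$vals[[b_id]]
  ea <- ncol(a)
  ad_push(tape, cbind(a, b), parents = c(a_id, b_id), backfn = function(g) {
    list(g[, seq_len(ea), drop = FALSE], g[, -seq_len(ea), drop = FALSE])
  })
}

# stack matrices (n, e) into (n, T, e) along the token axis
ad_stack_tokens <- function(tape, ids) {
  force(ids)
  mats <- lapply(ids, function(i) tape$vals[[i]])
  n <- nrow(mats[[1]]); e <- ncol(mats[[1]]); t <- length(mats)
  x <- array(0, c(n, t, e))
  for (j in seq_len(t)) x[, j, ] <- mats[[j]]
  ad_push(tape, x, parents = as.integer(ids), backfn = function(g) {
    lapply(seq_len(t), function(j) matrix(g[, j, ], n, e))
  })
}

# single (n, e) matrix viewed as a one-token sequence (n, 1, e)
ad_as_token <- function(tape, x_id) {
  force(x_id)
  x <- tape$vals[[x_id]]
  n <- nrow(x); e <- ncol(x)
  ad_push(tape, array(x, c(n, 1L, e)), parents = x_id,
          backfn = function(g) list(matrix(g, n, e)))
}

ad_drop_token <- function(tape, x_id) {  # (n, 1, e) -> (n, e)
  force(x_id)
  x <- tape$vals[[x_id]]
  n <- dim(x)[1]; e <- dim(x)[3]
  ad_push(tape, matrix(x, n, e), parents = x_id,
          backfn = function(g) list(array(g, c(n, 1L, e))))
}

# continuous clinical token: values (const length n), w, b (length e) -> (n, e)
ad_outer_affine <- function(tape, values, w_id, b_id) {
  force(w_id); force(b_id)
  w <- tape$vals[[w_id]]; b <- tape$vals[[b_id]]
  y <- outer(values, as.numeric(w))
  y <- sweep(y, 2L, b, "+")
  ad_push(tape, y, parents = c(w_id, b_id), backfn = function(g) {
    list(as.numeric(crossprod(g, values)), colSums(g))
  })
}

# embedding lookup: table (L, e), integer codes (length n) -> (n, e)
ad_embed <- function(tape, table_id, codes) {
  force(table_id)
  Tb <- tape$vals[[table_id]]
  y <- Tb[codes, , drop = FALSE]
  ad_push(tape, y, parents = table_id, backfn = function(g) {
    dT <- matrix(0, nrow(Tb), ncol(Tb))
    acc <- rowsum(g, group = codes)
    dT[as.integer(rownames(acc)), ] <- acc
    list(dT)
  })
}

# per-patient replacement of unavailable rows: x (n, e); rows where
# `available` is FALSE are replaced by the learnable embedding (length e).
ad_mask_replace <- function(tape, x_id, emb_id, available) {
  force(x_id); force(emb_id)
  x <- tape$vals[[x_id]]; emb <- tape$vals[[emb_id]]
  y <- x
  if (any(!available)) y[!available, ] <- rep(as.numeric(emb), each = sum(!available))
  ad_push(tape, y, parents = c(x_id, emb_id), backfn = function(g) {
    dx <- g; dx[!available, ] <- 0
    demb <- if (any(!available)) colSums(g[!available, , drop = FALSE]) else numeric(length(emb))
    list(dx, demb)
  })
}

# feature-column slice of a 3-d array: (n, t, e) -> (n, t, length(cols))
ad_cols3 <- function(tape, x_id, cols) {
  force(x_id)
  x <- tape$vals[[x_id]]
  y <- x[, , cols, drop = FALSE]
  ad_push(tape, y, parents = x_id, backfn = function(g) {
    dx <- array(0, dim(x))
    dx[, , cols] <- g
    list(dx)
  })
}

# concatenate 3-d arrays along the feature dimension
ad_bind3 <- function(tape, ids) {
  force(ids)
  arrs <- lapply(ids, function(i) tape$vals[[i]])
  n <- dim(arrs[[1]])[1]; t <- dim(arrs[[1]])[2]
  es <- vapply(arrs, function(a) dim(a)[3], integer(1))
  y <- array(0, c(n, t, sum(es)))
  off <- 0L
  for (k in seq_along(arrs)) {
    y[, , off + seq_len(es[k])] <- arrs[[k]]
    off <- off + es[k]
  }
  ad_push(tape, y, parents = as.integer(ids), backfn = function(g) {
    out <- vector("list", length(arrs))
    off <- 0L
    for (k in seq_along(arrs)) {
      out[[k]] <- g[, , off + seq_len(es[k]), drop = FALSE]
      off <- off + es[k]
    }
    out
  })
}

# inverted dropout; draws from the session RNG so training is seed-reproducible
ad_dropout <- function(tape, x_id, p, training) {
  if (!training || p <= 0) return(x_id)
  x <- tape$vals[[x_id]]
  keep <- array(stats::runif(length(x)) >= p, dim = dim(x)) / (1 - p)
  ad_mul_const(tape, x_id, keep)
}
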