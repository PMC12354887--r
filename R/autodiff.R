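# Reverse-mode automatic differentiation on dense matrices.
#
# A minimal tape-based engine sized for the models in this package: dense
# layers, layer normalisation, multi-head attention and the fused losses the
# three neural components need. Values are base-R matrices; nodes are
# environments recorded on a tape in creation order and replayed in reverse
# by ad_backward(). Gradients of every primitive are checked against finite
# differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$tape <- list()
.ad$n <- 0L

#' Reset the autodiff tape
#'
#' Clears the record of intermediate nodes. Call once at the start of every
#' training step, before the forward pass.
#' @return Invisibly, NULL.
#' @keywords internal
ad_tape_reset <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_node <- function(value, parents = list(), bw = NULL, track = TRUE,
                    leaf = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$bw <- bw
  node$track <- track
  class(node) <- "adnode"
  if (!leaf && track) {
    .ad$n <- .ad$n + 1L
    if (.ad$n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    .ad$tape[[.ad$n]] <- node
  }
  node
}

#' Create a trainable parameter node
#' @param value Numeric matrix (or vector, coerced to 1-row matrix).
#' @return An `adnode` leaf whose gradient is accumulated by [ad_backward()].
#' @keywords internal
ad_param <- function(value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  ad_node(value, leaf = TRUE)
}

#' Wrap a constant (no gradient) value
#' @keywords internal
ad_const <- function(value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  ad_node(value, track = FALSE, leaf = TRUE)
}

ad_value <- function(x) if (inherits(x, "adnode")) x$value else x

ad_accum <- function(node, g) {
  if (!inherits(node, "adnode") || !node$track) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#' @param loss A 1x1 `adnode`.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "adnode"), length(loss$value) == 1L)
  if (!is.finite(loss$value)) stop("non-finite loss; aborting backward pass")
  loss$grad <- matrix(1, 1L, 1L)
  if (.ad$n < 1L) return(invisible(NULL))
  for (i in seq(.ad$n, 1L)) {
    node <- .ad$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$bw)) node$bw(node$grad)
  }
  invisible(NULL)
}

# ---- primitives -------------------------------------------------------------

ad_mm <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A %*% B, list(a, b), function(g) {
    ad_accum(a, g %*% t(B))
    ad_accum(b, t(A) %*% g)
  })
}

# Add; a 1-row right operand broadcasts over rows (bias add).
ad_add <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  if (is.matrix(B) && nrow(B) == 1L && nrow(A) > 1L) {
    val <- sweep(A, 2L, as.numeric(B), "+")
    ad_node(val, list(a, b), function(g) {
      ad_accum(a, g)
      ad_accum(b, matrix(colSums(g), 1L))
    })
  } else {
    ad_node(A + B, list(a, b), function(g) {
      ad_accum(a, g)
      ad_accum(b, g)
    })
  }
}

ad_sub <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A - B, list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  })
}

ad_mul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_node(A * B, list(a, b), function(g) {
    ad_accum(a, g * B)
    ad_accum(b, g * A)
  })
}

ad_scale <- function(a, s) {
  A <- ad_value(a)
  ad_node(A * s, list(a), function(g) ad_accum(a, g * s))
}

ad_relu <- function(a) {
  A <- ad_value(a)
  val <- A * (A > 0)
  ad_node(val, list(a), function(g) ad_accum(a, g * (A > 0)))
}

ad_tanh <- function(a) {
  val <- tanh(ad_value(a))
  ad_node(val, list(a), function(g) ad_accum(a, g * (1 - val^2)))
}

ad_sigmoid <- function(a) {
  val <- 1 / (1 + exp(-ad_value(a)))
  ad_node(val, list(a), function(g) ad_accum(a, g * val * (1 - val)))
}

ad_exp <- function(a) {
  val <- exp(ad_value(a))
  ad_node(val, list(a), function(g) ad_accum(a, g * val))
}

# Row gather from an embedding table; gradient scatters by rowsum.
ad_embed <- function(table, idx) {
  E <- ad_value(table)
  idx <- as.integer(idx)
  ad_node(E[idx, , drop = FALSE], list(table), function(g) {
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nrow(E), ncol(E))
    full[as.integer(rownames(acc)), ] <- acc
    ad_accum(table, full)
  })
}

ad_concat_cols <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  na <- ncol(A)
  ad_node(cbind(A, B), list(a, b), function(g) {
    ad_accum(a, g[, seq_len(na), drop = FALSE])
    ad_accum(b, g[, -seq_len(na), drop = FALSE])
  })
}

# Row-wise layer normalisation with learned gain/shift (1 x d parameters).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  X <- ad_value(x)
  gam <- as.numeric(ad_value(gamma)); bet <- as.numeric(ad_value(beta))
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- sweep(sweep(xhat, 2L, gam, "*"), 2L, bet, "+")
  ad_node(val, list(x, gamma, beta), function(g) {
    ad_accum(beta, matrix(colSums(g), 1L))
    ad_accum(gamma, matrix(colSums(g * xhat), 1L))
    dxh <- sweep(g, 2L, gam, "*")
    dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
    ad_accum(x, dx)
  })
}

#' Fused multi-head scaled-dot-product attention
#'
#' Operates on a ragged batch: rows of `q` belong to sentences indexed by
#' `seg_q`, rows of `k`/`v` to sentences indexed by `seg_k`. Only rows with
#' matching sentence index attend to each other. With `causal = TRUE`, query
#' position i within a sentence attends to key positions <= i (self-attention
#' in the decoder). No positional information enters the computation.
#'
#' @param q,k,v `adnode` matrices, N x d with d divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param seg_q,seg_k Integer sentence index per row of q and k/v.
#' @param causal Logical; restrict attention to earlier positions.
#' @return `adnode` of the same shape as `q`.
#' @keywords internal
ad_mha <- function(q, k, v, n_heads, seg_q, seg_k, causal = FALSE) {
  Q <- ad_value(q); K <- ad_value(k); V <- ad_value(v)
  d <- ncol(Q)
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  sc <- 1 / sqrt(dh)
  qs <- split(seq_len(nrow(Q)), seg_q)
  ks <- split(seq_len(nrow(K)), seg_k)
  sents <- names(qs)
  out <- matrix(0, nrow(Q), d)
  cache <- vector("list", length(sents) * n_heads)
  ci <- 0L
  for (b in sents) {
    qi <- qs[[b]]; ki <- ks[[b]]
    if (is.null(ki)) stop("attention: no keys for sentence ", b)
    cmask <- if (causal) outer(seq_along(qi), seq_along(ki), ">=") else NULL
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qb <- Q[qi, cols, drop = FALSE]
      Kb <- K[ki, cols, drop = FALSE]
      Vb <- V[ki, cols, drop = FALSE]
      S <- (Qb %*% t(Kb)) * sc
      if (!is.null(cmask)) S[!cmask] <- -Inf
      S <- S - apply(S, 1L, max)
      P <- exp(S)
      P <- P / rowSums(P)
      out[qi, cols] <- P %*% Vb
      ci <- ci + 1L
      cache[[ci]] <- list(qi = qi, ki = ki, cols = cols, P = P)
    }
  }
  ad_node(out, list(q, k, v), function(g) {
    dQ <- matrix(0, nrow(Q), d)
    dK <- matrix(0, nrow(K), d)
    dV <- matrix(0, nrow(K), d)
    for (cc in cache) {
      qi <- cc$qi; ki <- cc$ki; cols <- cc$cols; P <- cc$P
      gO <- g[qi, cols, drop = FALSE]
      Vb <- V[ki, cols, drop = FALSE]
      dV[ki, cols] <- dV[ki, cols] + t(P) %*% gO
      dP <- gO %*% t(Vb)
      dS <- P * (dP - rowSums(dP * P))
      dQ[qi, cols] <- dQ[qi, cols] + (dS %*% K[ki, cols, drop = FALSE]) * sc
      dK[ki, cols] <- dK[ki, cols] + (t(dS) %*% Q[qi, cols, drop = FALSE]) * sc
    }
    ad_accum(q, dQ)
    ad_accum(k, dK)
    ad_accum(v, dV)
  })
}

#' Fused softmax cross-entropy over vocabulary logits
#'
#' @param logits `adnode`, N x V.
#' @param target Integer vector of length N; `NA` rows are excluded.
#' @return 1x1 `adnode`: mean negative log-likelihood over non-NA rows.
#' @keywords internal
ad_softmax_xent <- function(logits, target) {
  L <- ad_value(logits)
  keep <- which(!is.na(target))
  if (length(keep) == 0L) stop("cross-entropy: no labelled positions")
  Lk <- L[keep, , drop = FALSE]
  Lk <- Lk - apply(Lk, 1L, max)
  P <- exp(Lk)
  P <- P / rowSums(P)
  tk <- target[keep]
  nll <- -log(pmax(P[cbind(seq_along(keep), tk)], 1e-12))
  val <- matrix(mean(nll), 1L, 1L)
  ad_node(val, list(logits), function(g) {
    gl <- matrix(0, nrow(L), ncol(L))
    Pk <- P
    Pk[cbind(seq_along(keep), tk)] <- Pk[cbind(seq_along(keep), tk)] - 1
    gl[keep, ] <- Pk * (as.numeric(g) / length(keep))
    ad_accum(logits, gl)
  })
}

# Mean squared error against a constant target matrix.
ad_mse <- function(x, target) {
  X <- ad_value(x); Tm <- ad_value(target)
  dif <- X - Tm
  val <- matrix(mean(dif^2), 1L, 1L)
  ad_node(val, list(x), function(g) {
    ad_accum(x, dif * (2 * as.numeric(g) / length(dif)))
  })
}

# Gaussian KL( q(mu, exp(logvar)) || N(0, I) ), mean over rows.
ad_kl_gauss <- function(mu, logvar) {
  M <- ad_value(mu); LV <- ad_value(logvar)
  n <- nrow(M)
  val <- matrix(-0.5 * sum(1 + LV - M^2 - exp(LV)) / n, 1L, 1L)
  ad_node(val, list(mu, logvar), function(g) {
    s <- as.numeric(g) / n
    ad_accum(mu, M * s)
    ad_accum(logvar, -0.5 * (1 - exp(LV)) * s)
  })
}

#' Cosine-structure matching loss
#'
#' Penalises squared differences between the pairwise cosine-similarity
#' matrix of the rows of `z` and a constant target similarity matrix
#' (off-diagonal entries only).
#' @keywords internal
ad_cosine_match <- function(z, target_sim) {
  Z <- ad_value(z)
  Cin <- ad_value(target_sim)
  n <- nrow(Z)
  nrm <- sqrt(rowSums(Z^2)) + 1e-12
  Zn <- Z / nrm
  C <- Zn %*% t(Zn)
  W <- matrix(1, n, n); diag(W) <- 0
  m <- max(sum(W), 1)
  dif <- (C - Cin) * W
  val <- matrix(sum(dif^2) / m, 1L, 1L)
  ad_node(val, list(z), function(g) {
    dC <- dif * (2 * as.numeric(g) / m)
    dZn <- (dC + t(dC)) %*% Zn
    proj <- rowSums(dZn * Zn)
    dZ <- (dZn - Zn * proj) / nrm
    ad_accum(z, dZ)
  })
}

#' Contrastive pair loss on row-aligned embeddings
#'
#' Squared distance for positive pairs; squared hinge on (margin - distance)
#' for negative pairs. Mean over all pairs.
#' @param a,b `adnode` matrices, n x d, row i of each forming pair i.
#' @param positive Logical vector of length n.
#' @param margin Separation margin for negative pairs.
#' @keywords internal
ad_contrastive <- function(a, b, positive, margin = 1) {
  A <- ad_value(a); B <- ad_value(b)
  dif <- A - B
  d2 <- rowSums(dif^2)
  s <- sqrt(pmax(d2, 1e-12))
  n <- nrow(A)
  hin <- pmax(margin - s, 0)
  li <- ifelse(positive, d2, hin^2)
  val <- matrix(mean(li), 1L, 1L)
  ad_node(val, list(a, b), function(g) {
    gs <- as.numeric(g) / n
    coefs <- ifelse(positive, 2, ifelse(hin > 0, -2 * hin / s, 0))
    dA <- dif * (coefs * gs)
    ad_accum(a, dA)
    ad_accum(b, -dA)
  })
}

# Binary cross-entropy with logits; y constant in {0,1}; mean over entries.
ad_bce <- function(logits, y) {
  L <- ad_value(logits)
  p <- 1 / (1 + exp(-L))
  n <- length(L)
  val <- matrix(-mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12))), 1L, 1L)
  ad_node(val, list(logits), function(g) {
    ad_accum(logits, (p - y) * (as.numeric(g) / n))
  })
}

# ---- layers and optimiser ---------------------------------------------------

# Glorot-uniform initialised dense layer.
ad_linear_new <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  list(
    W = ad_param(matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)),
    b = ad_param(matrix(0, 1L, fan_out))
  )
}

ad_linear <- function(layer, x) ad_add(ad_mm(x, layer$W), layer$b)

ad_layernorm_new <- function(d) {
  list(gamma = ad_param(matrix(1, 1L, d)), beta = ad_param(matrix(0, 1L, d)))
}

# Collect every ad_param leaf reachable in a nested list of layers.
ad_params <- function(x) {
  if (inherits(x, "adnode")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, ad_params)))
  list()
}

#' Adam optimiser state
#' @keywords internal
adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    params = params,
    m = lapply(params, function(p) p$value * 0),
    v = lapply(params, function(p) p$value * 0),
    beta1 = beta1, beta2 = beta2, eps = eps, t = 0L
  )
}

#' One Adam update; clears parameter gradients
#' @keywords internal
adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * p$grad
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * p$grad^2
    mhat <- opt$m[[i]] / corr1
    vhat <- opt$v[[i]] / corr2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
    p$grad <- NULL
  }
  opt
}
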