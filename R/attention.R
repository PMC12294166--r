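#' Bi-level routing attention (BRA) and the BCN-BiFormer block
#'
#' BRA restricts token-to-token attention to a routed subset of spatial
#' regions. The feature map is partitioned into an S x S grid of regions;
#' per-region average-pooled queries and keys give a region-to-region
#' affinity matrix, each query region keeps its `topk` most affine regions
#' (ties broken toward the lowest region index), and ordinary multi-head
#' scaled-dot-product attention then runs between each region's query
#' tokens and the keys/values gathered from its routed regions. With
#' `topk = S^2` every region attends to every token and BRA reduces exactly
#' to full attention.
#'
#' @name bra-attention
NULL

# token index matrix: row i = the (H/S)*(W/S) token ids of region i.
# Tokens are numbered column-major over (h, w); regions likewise over the
# S x S grid.
region_index <- function(H, W, S) {
  if (H %% S != 0L || W %% S != 0L) {
    stop(sprintf("spatial dims (H=%d, W=%d) not divisible by S=%d", H, W, S),
         call. = FALSE)
  }
  rh <- H %/% S
  rw <- W %/% S
  idx <- matrix(0L, S * S, rh * rw)
  for (gw in seq_len(S)) {
    for (gh in seq_len(S)) {
      reg <- gh + (gw - 1L) * S
      hs <- (gh - 1L) * rh + seq_len(rh)
      ws <- (gw - 1L) * rw + seq_len(rw)
      idx[reg, ] <- as.vector(outer(hs, (ws - 1L) * H, "+"))
    }
  }
  idx
}

#' Partition a feature map into S x S spatial regions of tokens
#'
#' @param x rank-4 feature map `(batch, channel, height, width)`.
#' @param S regions per spatial side; `H` and `W` must be divisible by `S`.
#' @return an object of class `region_tokens`: a list with `tokens`
#'   (array `(batch, S^2, tokens_per_region, channel)`), the token `index`
#'   matrix and the original dimensions. [unpartition_regions()] inverts it
#'   losslessly.
#' @examples
#' x <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
#' rt <- partition_regions(x, S = 2)
#' all.equal(unpartition_regions(rt), x)
#' @export
partition_regions <- function(x, S) {
  d <- check_nchw(x)
  S <- as.integer(S)
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  idx <- region_index(d[3], d[4], S)
  R <- nrow(idx); r <- ncol(idx)
  tokens <- array(0, c(d[1], R, r, d[2]))
  for (n in seq_len(d[1])) {
    xt <- t(matrix(x[n, , , ], d[2], d[3] * d[4]))  # T x C
    for (i in seq_len(R)) tokens[n, i, , ] <- xt[idx[i, ], ]
  }
  structure(list(tokens = tokens, index = idx, dims = d, S = S),
            class = "region_tokens")
}

#' @rdname partition_regions
#' @param rt a `region_tokens` object.
#' @export
unpartition_regions <- function(rt) {
  stopifnot(inherits(rt, "region_tokens"))
  d <- rt$dims
  x <- array(0, d)
  for (n in seq_len(d[1])) {
    xt <- matrix(0, d[3] * d[4], d[2])
    for (i in seq_len(nrow(rt$index))) {
      xt[rt$index[i, ], ] <- rt$tokens[n, i, , ]
    }
    x[n, , , ] <- t(xt)
  }
  x
}

#' Top-k region routing
#'
#' Given region-pooled queries and keys (rows = regions), computes the
#' region affinity matrix \eqn{A = Q_r K_r^T} and returns, for every query
#' region, the indices of the `k` regions with the largest affinity.
#' Ties are broken deterministically toward the lowest region index.
#'
#' @param region_q,region_k numeric matrices, `S^2 x channels`.
#' @param k number of regions to keep, in `[1, S^2]`.
#' @return integer matrix `S^2 x k`; row i lists the routed regions of
#'   query region i in decreasing affinity order.
#' @export
route_topk <- function(region_q, region_k, k) {
  region_q <- as.matrix(region_q)
  region_k <- as.matrix(region_k)
  R <- nrow(region_q)
  if (nrow(region_k) != R) {
    stop("region_q and region_k must have the same number of regions",
         call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > R) {
    stop(sprintf("topk k=%d out of range [1, %d]", k, R), call. = FALSE)
  }
  A <- tcrossprod(region_q, region_k)
  route_topk_core(A, k)
}

route_topk_core <- function(A, k) {
  R <- nrow(A)
  out <- matrix(0L, R, k)
  for (i in seq_len(R)) {
    # order() is stable, so equal affinities keep ascending index order
    out[i, ] <- order(A[i, ], decreasing = TRUE)[seq_len(k)]
  }
  out
}

## --- BRA layer -------------------------------------------------------------

new_bra <- function(channels, n_heads, S) {
  channels <- as.integer(channels)
  n_heads <- as.integer(n_heads)
  if (channels %% n_heads != 0L) {
    stop(sprintf("n_heads=%d must divide channels=%d", n_heads, channels),
         call. = FALSE)
  }
  sd <- sqrt(1 / channels)
  mk <- function() matrix(stats::rnorm(channels * channels, sd = sd),
                          channels, channels)
  new_module("bra",
             params = list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk(),
                           bo = numeric(channels)),
             channels = channels, n_heads = n_heads, S = as.integer(S))
}

#' @export
nn_forward.bra <- function(mod, x, training = FALSE, topk = NULL,
                           return_attn = FALSE, ...) {
  d <- check_nchw(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  if (C != mod$channels) {
    stop(sprintf("bra: expected %d channels, got %d", mod$channels, C),
         call. = FALSE)
  }
  S <- mod$S
  idx <- region_index(H, W, S)
  R <- nrow(idx); r <- ncol(idx)
  if (is.null(topk)) topk <- R
  topk <- as.integer(topk)
  if (topk < 1L || topk > R) {
    stop(sprintf("topk k=%d out of range [1, %d]", topk, R), call. = FALSE)
  }
  nh <- mod$n_heads
  dh <- C %/% nh
  scale <- 1 / sqrt(dh)
  p <- mod$params

  y <- array(0, d)
  caches <- vector("list", N)
  attn_out <- if (return_attn) vector("list", N) else NULL
  for (n in seq_len(N)) {
    Xt <- t(matrix(x[n, , , ], C, H * W))        # T x C tokens
    Q <- Xt %*% t(p$Wq)
    K <- Xt %*% t(p$Wk)
    V <- Xt %*% t(p$Wv)
    Qp <- matrix(0, R, C)
    Kp <- matrix(0, R, C)
    for (i in seq_len(R)) {
      Qp[i, ] <- colMeans(Q[idx[i, ], , drop = FALSE])
      Kp[i, ] <- colMeans(K[idx[i, ], , drop = FALSE])
    }
    route <- route_topk_core(tcrossprod(Qp, Kp), topk)

    O <- matrix(0, H * W, C)
    reg_cache <- vector("list", R)
    attn_n <- if (return_attn) vector("list", R) else NULL
    for (i in seq_len(R)) {
      gat <- as.vector(t(idx[route[i, ], , drop = FALSE]))
      qi <- Q[idx[i, ], , drop = FALSE]
      Kg <- K[gat, , drop = FALSE]
      Vg <- V[gat, , drop = FALSE]
      attn_h <- vector("list", nh)
      for (h in seq_len(nh)) {
        cl <- (h - 1L) * dh + seq_len(dh)
        logits <- tcrossprod(qi[, cl, drop = FALSE],
                             Kg[, cl, drop = FALSE]) * scale
        a <- softmax_rows(logits)
        attn_h[[h]] <- a
        O[idx[i, ], cl] <- a %*% Vg[, cl, drop = FALSE]
      }
      reg_cache[[i]] <- list(gat = gat, attn = attn_h)
      if (return_attn) attn_n[[i]] <- attn_h
    }
    Yt <- O %*% t(p$Wo) + rep(p$bo, each = H * W)
    y[n, , , ] <- array(t(Yt), c(C, H, W))
    caches[[n]] <- list(Xt = Xt, Q = Q, K = K, V = V, O = O,
                        regions = reg_cache)
    if (return_attn) attn_out[[n]] <- attn_n
  }
  out <- list(out = y,
              cache = list(per_sample = caches, idx = idx, dims = d,
                           topk = topk, nh = nh, dh = dh, scale = scale))
  if (return_attn) out$attn <- attn_out
  out
}

#' @export
nn_backward.bra <- function(mod, cache, dout) {
  d <- cache$dims
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  idx <- cache$idx
  R <- nrow(idx)
  nh <- cache$nh; dh <- cache$dh; scale <- cache$scale
  p <- mod$params

  dWq <- matrix(0, C, C); dWk <- matrix(0, C, C)
  dWv <- matrix(0, C, C); dWo <- matrix(0, C, C)
  dbo <- numeric(C)
  dx <- array(0, d)

  for (n in seq_len(N)) {
    cs <- cache$per_sample[[n]]
    dYt <- t(matrix(dout[n, , , ], C, H * W))    # T x C
    dbo <- dbo + colSums(dYt)
    dWo <- dWo + crossprod(dYt, cs$O)
    dO <- dYt %*% p$Wo

    dQ <- matrix(0, H * W, C)
    dK <- matrix(0, H * W, C)
    dV <- matrix(0, H * W, C)
    for (i in seq_len(R)) {
      rc <- cs$regions[[i]]
      gat <- rc$gat
      qi <- cs$Q[idx[i, ], , drop = FALSE]
      Kg <- cs$K[gat, , drop = FALSE]
      Vg <- cs$V[gat, , drop = FALSE]
      for (h in seq_len(nh)) {
        cl <- (h - 1L) * dh + seq_len(dh)
        a <- rc$attn[[h]]
        dOi <- dO[idx[i, ], cl, drop = FALSE]
        da <- tcrossprod(dOi, Vg[, cl, drop = FALSE])
        dV[gat, cl] <- dV[gat, cl] + crossprod(a, dOi)
        # softmax backward, row-wise
        ds <- a * (da - rowSums(da * a))
        dQ[idx[i, ], cl] <- dQ[idx[i, ], cl] +
          (ds %*% Kg[, cl, drop = FALSE]) * scale
        dK[gat, cl] <- dK[gat, cl] +
          crossprod(ds, qi[, cl, drop = FALSE]) * scale
      }
    }
    dWq <- dWq + crossprod(dQ, cs$Xt)
    dWk <- dWk + crossprod(dK, cs$Xt)
    dWv <- dWv + crossprod(dV, cs$Xt)
    dXt <- dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv
    dx[n, , , ] <- array(t(dXt), c(C, H, W))
  }
  list(dx = dx,
       grads = list(params = list(Wq = dWq, Wk = dWk, Wv = dWv,
                                  Wo = dWo, bo = dbo),
                    children = list()))
}

#' Apply bi-level routing attention to a feature map
#'
#' User-facing functional wrapper around the BRA layer: builds or reuses a
#' layer and runs the routed multi-head attention described in
#' [bra-attention].
#'
#' @param x rank-4 feature map `(batch, channel, height, width)`.
#' @param layer a layer created by `bra_layer()`; its channel count must
#'   match `x`.
#' @param topk number of routed regions per query region (default `S^2`,
#'   i.e. full attention).
#' @param return_attn if `TRUE`, also return the per-region attention
#'   matrices (rows sum to 1).
#' @return list with `out` (same shape as `x`) and optionally `attn`.
#' @export
bra_forward <- function(x, layer, topk = NULL, return_attn = FALSE) {
  res <- nn_forward(layer, x, training = FALSE, topk = topk,
                    return_attn = return_attn)
  res$cache <- NULL
  res
}

#' @rdname bra_forward
#' @param channels,n_heads,S layer dimensions: feature channels, attention
#'   heads (must divide `channels`) and regions per side.
#' @param seed integer seed for the projection weight draws.
#' @export
bra_layer <- function(channels, n_heads = 2, S = 7, seed = 1) {
  withr::with_seed(seed, new_bra(channels, n_heads, S))
}

## --- BCN-BiFormer block ----------------------------------------------------

# x -> x + DWConv(x) (positional term)
#   -> y + BRA(BCN(y))  (routed attention, pre-norm, residual)
#   -> z + MLP(BCN(z))  (expansion-e MLP, pre-norm, residual)
new_biformer <- function(channels, n_heads, S, topk, e = 3) {
  hidden <- as.integer(e * channels)
  new_module(
    "biformer",
    children = list(
      pos = new_dwconv2d(channels, k = 3L, stride = 1L, pad = 1L),
      norm1 = new_bcn(channels),
      attn = new_bra(channels, n_heads, S),
      norm2 = new_bcn(channels),
      fc1 = new_conv2d(channels, hidden, k = 1L),
      act = new_gelu(),
      fc2 = new_conv2d(hidden, channels, k = 1L)
    ),
    topk = as.integer(topk), channels = as.integer(channels)
  )
}

#' @export
nn_forward.biformer <- function(mod, x, training = FALSE, ...) {
  ch <- mod$children
  f_pos <- nn_forward(ch$pos, x, training)
  y <- x + f_pos$out
  f_n1 <- nn_forward(ch$norm1, y, training)
  f_at <- nn_forward(ch$attn, f_n1$out, training, topk = mod$topk)
  z <- y + f_at$out
  f_n2 <- nn_forward(ch$norm2, z, training)
  f_f1 <- nn_forward(ch$fc1, f_n2$out, training)
  f_ac <- nn_forward(ch$act, f_f1$out, training)
  f_f2 <- nn_forward(ch$fc2, f_ac$out, training)
  out <- z + f_f2$out
  list(out = out,
       cache = list(pos = f_pos$cache, n1 = f_n1$cache, at = f_at$cache,
                    n2 = f_n2$cache, f1 = f_f1$cache, ac = f_ac$cache,
                    f2 = f_f2$cache))
}

#' @export
nn_backward.biformer <- function(mod, cache, dout) {
  ch <- mod$children
  b_f2 <- nn_backward(ch$fc2, cache$f2, dout)
  b_ac <- nn_backward(ch$act, cache$ac, b_f2$dx)
  b_f1 <- nn_backward(ch$fc1, cache$f1, b_ac$dx)
  b_n2 <- nn_backward(ch$norm2, cache$n2, b_f1$dx)
  dz <- dout + b_n2$dx
  b_at <- nn_backward(ch$attn, cache$at, dz)
  b_n1 <- nn_backward(ch$norm1, cache$n1, b_at$dx)
  dy <- dz + b_n1$dx
  b_pos <- nn_backward(ch$pos, cache$pos, dy)
  dx <- dy + b_pos$dx
  list(dx = dx,
       grads = list(params = list(),
                    children = list(pos = b_pos$grads, norm1 = b_n1$grads,
                                    attn = b_at$grads, norm2 = b_n2$grads,
                                    fc1 = b_f1$grads, act = b_ac$grads,
                                    fc2 = b_f2$grads)))
}

#' Run one BCN-BiFormer block
#'
#' Composes the block used throughout the backbone: a depthwise 3x3
#' convolution as a positional term, batch channel normalization, bi-level
#' routing attention, a second BCN and an expansion-`e` MLP, with residual
#' connections around the attention and MLP paths. The routed region count
#' comes from `topk_per_stage[stage_index]`.
#'
#' @param x rank-4 feature map.
#' @param cfg a [bra_config()].
#' @param stage_index which backbone stage (1-4) the block sits in; selects
#'   the stage's top-k value.
#' @param block an existing block (from `biformer_layer()`); built fresh
#'   from `seed` when omitted.
#' @param seed integer seed used when `block` is omitted.
#' @param training logical; training-mode statistics for the BCN layers.
#' @return list with `out` (same shape as `x`).
#' @export
biformer_block <- function(x, cfg = bra_config(), stage_index = 1,
                           block = NULL, seed = 1, training = TRUE) {
  d <- check_nchw(x)
  if (is.null(block)) {
    block <- biformer_layer(d[2], cfg, stage_index, seed = seed)
  }
  res <- nn_forward(block, x, training = training)
  list(out = res$out, block = block)
}

#' @rdname biformer_block
#' @param channels feature channels of the block.
#' @export
biformer_layer <- function(channels, cfg = bra_config(), stage_index = 1,
                           seed = 1) {
  stage_index <- as.integer(stage_index)
  if (stage_index < 1L || stage_index > length(cfg$topk_per_stage)) {
    stop("stage_index out of range", call. = FALSE)
  }
  withr::with_seed(seed, {
    new_biformer(channels, cfg$n_heads, cfg$S,
                 topk = cfg$topk_per_stage[stage_index], e = cfg$e)
  })
}

#' Configuration of the bi-level routing attention blocks
#'
#' Defaults follow the grading network: `S = 7` regions per side, stage-wise
#' top-k `(7, 8, 16, 49)` and MLP expansion ratio `e = 3`. The default head
#' count is 2, the largest value dividing every channel width the default
#' backbone reaches (including the C/2-wide unit branches).
#'
#' @param S regions per spatial side.
#' @param topk_per_stage integer vector of routed-region counts, one per
#'   backbone stage; each must lie in `[1, S^2]`.
#' @param n_heads attention heads; must divide the channel width wherever a
#'   block is placed.
#' @param e MLP expansion ratio (hidden width = `e * channels`).
#' @return a list of class `bra_config`.
#' @export
bra_config <- function(S = 7, topk_per_stage = c(7, 8, 16, 49),
                       n_heads = 2, e = 3) {
  S <- as.integer(S)
  topk_per_stage <- as.integer(topk_per_stage)
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  if (any(topk_per_stage < 1L) || any(topk_per_stage > S * S)) {
    stop(sprintf("every top-k must lie in [1, S^2 = %d]", S * S),
         call. = FALSE)
  }
  if (e < 1) stop("MLP expansion ratio e must be >= 1", call. = FALSE)
  structure(list(S = S, topk_per_stage = topk_per_stage,
                 n_heads = as.integer(n_heads), e = e),
            class = "bra_config")
}
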