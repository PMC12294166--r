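# Basic differentiable layers (NCHW). Each forward caches what its backward
# needs; backwards were checked against central finite differences (see
# tests/testthat/test-layers.R).

## --- dense 2-D convolution -------------------------------------------------

new_conv2d <- function(in_ch, out_ch, k = 1L, stride = 1L, pad = 0L,
                       bias = TRUE) {
  fan_in <- in_ch * k * k
  W <- matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
              out_ch, fan_in)
  params <- list(W = W)
  if (bias) params$b <- numeric(out_ch)
  new_module("conv2d", params = params, in_ch = in_ch, out_ch = out_ch,
             k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad), bias = bias)
}

#' @export
nn_forward.conv2d <- function(mod, x, training = FALSE, ...) {
  d <- check_nchw(x)
  if (d[2] != mod$in_ch) {
    stop(sprintf("conv2d: expected %d input channels, got %d",
                 mod$in_ch, d[2]), call. = FALSE)
  }
  info <- im2col(x, mod$k, mod$stride, mod$pad)
  ym <- mod$params$W %*% info$cols
  if (mod$bias) ym <- ym + mod$params$b
  out <- aperm(array(ym, c(mod$out_ch, info$N, info$Ho, info$Wo)),
               c(2L, 1L, 3L, 4L))
  list(out = out, cache = list(info = info))
}

#' @export
nn_backward.conv2d <- function(mod, cache, dout) {
  info <- cache$info
  dym <- matrix(aperm(dout, c(2L, 1L, 3L, 4L)), mod$out_ch,
                info$N * info$Ho * info$Wo)
  grads <- list(W = tcrossprod(dym, info$cols))
  if (mod$bias) grads$b <- rowSums(dym)
  dcols <- crossprod(mod$params$W, dym)
  dx <- col2im(dcols, info)
  list(dx = dx, grads = list(params = grads, children = list()))
}

## --- depthwise 3x3 (or k x k) convolution ---------------------------------

new_dwconv2d <- function(ch, k = 3L, stride = 1L, pad = 1L, bias = TRUE) {
  K <- array(stats::rnorm(ch * k * k, sd = sqrt(2 / (k * k))), c(ch, k, k))
  params <- list(K = K)
  if (bias) params$b <- numeric(ch)
  new_module("dwconv2d", params = params, ch = as.integer(ch),
             k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad), bias = bias)
}

#' @export
nn_forward.dwconv2d <- function(mod, x, training = FALSE, ...) {
  d <- check_nchw(x)
  if (d[2] != mod$ch) {
    stop(sprintf("dwconv2d: expected %d channels, got %d", mod$ch, d[2]),
         call. = FALSE)
  }
  xp <- pad_nchw(x, mod$pad)
  dp <- dim(xp)
  Ho <- (dp[3] - mod$k) %/% mod$stride + 1L
  Wo <- (dp[4] - mod$k) %/% mod$stride + 1L
  N <- d[1]
  y <- array(0, c(N, mod$ch, Ho, Wo))
  for (j in seq_len(mod$k)) {
    for (i in seq_len(mod$k)) {
      hi <- i + mod$stride * (seq_len(Ho) - 1L)
      wi <- j + mod$stride * (seq_len(Wo) - 1L)
      y <- y + xp[, , hi, wi, drop = FALSE] *
        rep_ch(mod$params$K[, i, j], N)
    }
  }
  if (mod$bias) y <- y + rep_ch(mod$params$b, N)
  list(out = y, cache = list(xp = xp, N = N, Ho = Ho, Wo = Wo,
                             H = d[3], W = d[4]))
}

#' @export
nn_backward.dwconv2d <- function(mod, cache, dout) {
  N <- cache$N; Ho <- cache$Ho; Wo <- cache$Wo
  dK <- array(0, dim(mod$params$K))
  dxp <- array(0, dim(cache$xp))
  for (j in seq_len(mod$k)) {
    for (i in seq_len(mod$k)) {
      hi <- i + mod$stride * (seq_len(Ho) - 1L)
      wi <- j + mod$stride * (seq_len(Wo) - 1L)
      sl <- cache$xp[, , hi, wi, drop = FALSE]
      dK[, i, j] <- channel_sum(dout * sl)
      dxp[, , hi, wi] <- dxp[, , hi, wi, drop = FALSE] +
        dout * rep_ch(mod$params$K[, i, j], N)
    }
  }
  grads <- list(K = dK)
  if (mod$bias) grads$b <- channel_sum(dout)
  dx <- crop_nchw(dxp, mod$pad, cache$H, cache$W)
  list(dx = dx, grads = list(params = grads, children = list()))
}

## --- max pooling -----------------------------------------------------------

new_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  new_module("maxpool", k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad))
}

#' @export
nn_forward.maxpool <- function(mod, x, training = FALSE, ...) {
  d <- check_nchw(x)
  xp <- pad_nchw(x, mod$pad, value = -Inf)
  dp <- dim(xp)
  Ho <- (dp[3] - mod$k) %/% mod$stride + 1L
  Wo <- (dp[4] - mod$k) %/% mod$stride + 1L
  n_out <- d[1] * d[2] * Ho * Wo
  stack <- matrix(0, n_out, mod$k * mod$k)
  t <- 0L
  for (j in seq_len(mod$k)) {
    for (i in seq_len(mod$k)) {
      t <- t + 1L
      hi <- i + mod$stride * (seq_len(Ho) - 1L)
      wi <- j + mod$stride * (seq_len(Wo) - 1L)
      stack[, t] <- as.vector(xp[, , hi, wi, drop = FALSE])
    }
  }
  amax <- max.col(stack, ties.method = "first")
  y <- stack[cbind(seq_len(n_out), amax)]
  dim(y) <- c(d[1], d[2], Ho, Wo)
  list(out = y, cache = list(amax = amax, dims = d, Ho = Ho, Wo = Wo,
                             dp = dp))
}

#' @export
nn_backward.maxpool <- function(mod, cache, dout) {
  d <- cache$dims
  Ho <- cache$Ho; Wo <- cache$Wo
  dxp <- array(0, cache$dp)
  dvec <- as.vector(dout)
  t <- 0L
  for (j in seq_len(mod$k)) {
    for (i in seq_len(mod$k)) {
      t <- t + 1L
      sel <- cache$amax == t
      if (!any(sel)) next
      contr <- dvec * sel
      dim(contr) <- c(d[1], d[2], Ho, Wo)
      hi <- i + mod$stride * (seq_len(Ho) - 1L)
      wi <- j + mod$stride * (seq_len(Wo) - 1L)
      dxp[, , hi, wi] <- dxp[, , hi, wi, drop = FALSE] + contr
    }
  }
  dx <- crop_nchw(dxp, mod$pad, d[3], d[4])
  list(dx = dx, grads = list(params = list(), children = list()))
}

## --- activations -----------------------------------------------------------

new_relu <- function() new_module("relu")

#' @export
nn_forward.relu <- function(mod, x, training = FALSE, ...) {
  mask <- x > 0
  list(out = x * mask, cache = list(mask = mask))
}

#' @export
nn_backward.relu <- function(mod, cache, dout) {
  list(dx = dout * cache$mask,
       grads = list(params = list(), children = list()))
}

new_gelu <- function() new_module("gelu")

#' @export
nn_forward.gelu <- function(mod, x, training = FALSE, ...) {
  list(out = x * stats::pnorm(x), cache = list(x = x))
}

#' @export
nn_backward.gelu <- function(mod, cache, dout) {
  x <- cache$x
  list(dx = dout * (stats::pnorm(x) + x * stats::dnorm(x)),
       grads = list(params = list(), children = list()))
}

## --- global average pooling ------------------------------------------------

new_gap <- function() new_module("gap")

#' @export
nn_forward.gap <- function(mod, x, training = FALSE, ...) {
  d <- check_nchw(x)
  y <- rowMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  dim(y) <- c(d[1], d[2])
  list(out = y, cache = list(dims = d))
}

#' @export
nn_backward.gap <- function(mod, cache, dout) {
  d <- cache$dims
  hw <- d[3] * d[4]
  dx <- array(rep(as.vector(dout), hw) / hw, d)
  list(dx = dx, grads = list(params = list(), children = list()))
}

## --- dropout ---------------------------------------------------------------

new_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  new_module("dropout", rate = rate)
}

#' @export
nn_forward.dropout <- function(mod, x, training = FALSE, ...) {
  if (!training || mod$rate == 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  keep <- stats::runif(length(x)) >= mod$rate
  mask <- keep / (1 - mod$rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = list(mask = mask))
}

#' @export
nn_backward.dropout <- function(mod, cache, dout) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = list(params = list(), children = list()))
}

## --- fully connected -------------------------------------------------------

new_linear <- function(in_dim, out_dim, bias = TRUE) {
  W <- matrix(stats::rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
              out_dim, in_dim)
  params <- list(W = W)
  if (bias) params$b <- numeric(out_dim)
  new_module("linear", params = params, in_dim = in_dim, out_dim = out_dim,
             bias = bias)
}

#' @export
nn_forward.linear <- function(mod, x, training = FALSE, ...) {
  # x: N x in_dim matrix
  y <- tcrossprod(x, mod$params$W)
  if (mod$bias) y <- sweep(y, 2L, mod$params$b, "+")
  list(out = y, cache = list(x = x))
}

#' @export
nn_backward.linear <- function(mod, cache, dout) {
  grads <- list(W = crossprod(dout, cache$x))
  if (mod$bias) grads$b <- colSums(dout)
  list(dx = dout %*% mod$params$W,
       grads = list(params = grads, children = list()))
}

## --- softmax cross-entropy -------------------------------------------------

# logits: N x k, labels: 0-based integer vector. Returns mean loss and the
# gradient w.r.t. logits.
softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n
  list(loss = loss, dlogits = dlogits, probs = p)
}
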