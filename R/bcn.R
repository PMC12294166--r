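#' Batch channel normalization (BCN)
#'
#' BCN blends a batch-normalization branch with a layer-normalization branch
#' through a single learnable scalar mixing weight \eqn{\iota}:
#' \deqn{Y = \gamma\left[\iota\frac{x-\mu_1}{\sqrt{\sigma_1^2+\epsilon}}
#'   + (1-\iota)\frac{x-\mu_2}{\sqrt{\sigma_2^2+\epsilon}}\right] + \beta}
#' Branch 1 statistics (\eqn{\mu_1,\sigma_1^2}) are computed per channel over
#' the (batch, height, width) axes, exactly as in batch normalization; branch
#' 2 statistics (\eqn{\mu_2,\sigma_2^2}) are computed per sample over the
#' (channel, height, width) axes, as in layer normalization. \eqn{\gamma}
#' and \eqn{\beta} are per-channel affine parameters; \eqn{\iota} is a single
#' unconstrained scalar per layer (values outside \eqn{[0,1]} extrapolate
#' between the two branches rather than interpolating).
#'
#' In training mode branch-1 statistics come from the current batch and an
#' exponential moving average of them is stored for inference; in eval mode
#' branch 1 uses the stored running statistics while branch 2 is always
#' recomputed per sample (it needs no running state).
#'
#' @param channels number of feature channels the layer normalizes.
#' @param seed integer seed for the parameter draws.
#' @param eps small positive stabilizer added to both variances.
#' @param momentum exponential-moving-average weight for the running
#'   batch-branch statistics.
#' @return `init_bcn()` returns a `bcn_state` list with fields `iota`,
#'   `gamma`, `beta` (all drawn from N(0, 1)), `eps`, `momentum`,
#'   `running_mean`, `running_var` and `initialized`.
#' @examples
#' st <- init_bcn(4, seed = 1)
#' x <- array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3))
#' out <- bcn_forward(x, st, training = TRUE)
#' dim(out$out)
#' @export
init_bcn <- function(channels, seed, eps = 1e-5, momentum = 0.1) {
  channels <- as.integer(channels)
  if (is.na(channels) || channels < 1L) {
    stop("init_bcn: channels must be a positive integer", call. = FALSE)
  }
  if (eps <= 0) stop("init_bcn: eps must be positive", call. = FALSE)
  draws <- withr::with_seed(seed, stats::rnorm(2L * channels + 1L))
  structure(
    list(
      iota = draws[1L],
      gamma = draws[1L + seq_len(channels)],
      beta = draws[1L + channels + seq_len(channels)],
      eps = eps,
      momentum = momentum,
      running_mean = numeric(channels),
      running_var = rep(1, channels),
      initialized = FALSE
    ),
    class = "bcn_state"
  )
}

#' Apply batch channel normalization
#'
#' Functional forward pass of the BCN layer described in [init_bcn()].
#' Because R is copy-on-modify, the (possibly updated) state is returned
#' alongside the output.
#'
#' @param x rank-4 feature map, dim `(batch, channel, height, width)`.
#' @param state a `bcn_state` from [init_bcn()].
#' @param training logical; in training mode batch statistics are computed
#'   from `x` and the running statistics are updated. In eval mode the layer
#'   errors if the running statistics were never updated.
#' @return list with `out` (same shape as `x`) and `state` (updated).
#' @export
bcn_forward <- function(x, state, training = FALSE) {
  res <- bcn_core(x, state, training = training, need_cache = FALSE)
  list(out = res$out, state = res$state)
}

# shared core: forward with optional cache for the analytic backward
bcn_core <- function(x, st, training, need_cache = TRUE) {
  d <- check_nchw(x)
  N <- d[1]; C <- d[2]
  if (C != length(st$gamma)) {
    stop(sprintf("bcn: state has %d channels but input has %d",
                 length(st$gamma), C), call. = FALSE)
  }
  m1 <- N * d[3] * d[4]
  m2 <- C * d[3] * d[4]

  if (training) {
    mu1 <- channel_mean(x)
    v1 <- pmax(channel_mean(x * x) - mu1^2, 0)
    mom <- st$momentum
    if (st$initialized) {
      st$running_mean <- (1 - mom) * st$running_mean + mom * mu1
      st$running_var <- (1 - mom) * st$running_var + mom * v1
    } else {
      st$running_mean <- mu1
      st$running_var <- v1
      st$initialized <- TRUE
    }
  } else {
    if (!st$initialized) {
      stop("bcn: eval mode requested before any running-statistic update",
           call. = FALSE)
    }
    mu1 <- st$running_mean
    v1 <- st$running_var
  }
  mu2 <- sample_mean(x)
  v2 <- pmax(sample_mean(x * x) - mu2^2, 0)

  s1 <- sqrt(v1 + st$eps)
  s2 <- sqrt(v2 + st$eps)
  xhat1 <- (x - rep_ch(mu1, N)) * rep_ch(1 / s1, N)
  xhat2 <- (x - mu2) / s2                     # length-N vectors recycle per sample
  u <- st$iota * xhat1 + (1 - st$iota) * xhat2
  out <- rep_ch(st$gamma, N) * u + rep_ch(st$beta, N)

  cache <- NULL
  if (need_cache) {
    cache <- list(xhat1 = xhat1, xhat2 = xhat2, u = u, s1 = s1, s2 = s2,
                  N = N, m1 = m1, m2 = m2, training = training)
  }
  list(out = out, state = st, cache = cache)
}

# analytic backward (training-mode statistics). Returns dx and grads for
# iota, gamma, beta.
bcn_backward_core <- function(st, cache, dout) {
  if (!cache$training) {
    stop("bcn backward requires a training-mode forward cache", call. = FALSE)
  }
  N <- cache$N
  du <- dout * rep_ch(st$gamma, N)
  dgamma <- channel_sum(dout * cache$u)
  dbeta <- channel_sum(dout)
  diota <- sum(du * (cache$xhat1 - cache$xhat2))

  # batch branch: standard BN input gradient per channel
  dxh1 <- st$iota * du
  mc1 <- channel_sum(dxh1) / cache$m1
  mc2 <- channel_sum(dxh1 * cache$xhat1) / cache$m1
  dx1 <- (dxh1 - rep_ch(mc1, N) - cache$xhat1 * rep_ch(mc2, N)) *
    rep_ch(1 / cache$s1, N)

  # layer branch: same formula per sample
  dxh2 <- (1 - st$iota) * du
  mn1 <- sample_sum(dxh2) / cache$m2
  mn2 <- sample_sum(dxh2 * cache$xhat2) / cache$m2
  dx2 <- (dxh2 - mn1 - cache$xhat2 * mn2) / cache$s2

  list(dx = dx1 + dx2,
       grads = list(iota = diota, gamma = dgamma, beta = dbeta))
}

## --- module wrapper --------------------------------------------------------

new_bcn <- function(channels, eps = 1e-5, momentum = 0.1) {
  # parameter draws (N(0,1) for iota, gamma, beta) come from the ambient
  # RNG stream of the model builder, which is seeded once per build
  draws <- stats::rnorm(2L * channels + 1L)
  new_module(
    "bcn",
    params = list(iota = draws[1L],
                  gamma = draws[1L + seq_len(channels)],
                  beta = draws[1L + channels + seq_len(channels)]),
    buffers = list(running_mean = numeric(channels),
                   running_var = rep(1, channels),
                   initialized = FALSE),
    eps = eps, momentum = momentum, channels = as.integer(channels)
  )
}

bcn_module_state <- function(mod) {
  structure(
    list(iota = as.numeric(mod$params$iota),
         gamma = as.numeric(mod$params$gamma),
         beta = as.numeric(mod$params$beta),
         eps = mod$eps, momentum = mod$momentum,
         running_mean = mod$buffers$running_mean,
         running_var = mod$buffers$running_var,
         initialized = mod$buffers$initialized),
    class = "bcn_state"
  )
}

#' @export
nn_forward.bcn <- function(mod, x, training = FALSE, ...) {
  st <- bcn_module_state(mod)
  res <- bcn_core(x, st, training = training, need_cache = TRUE)
  if (training) {
    mod$buffers$running_mean <- res$state$running_mean
    mod$buffers$running_var <- res$state$running_var
    mod$buffers$initialized <- res$state$initialized
  }
  list(out = res$out, cache = res$cache)
}

#' @export
nn_backward.bcn <- function(mod, cache, dout) {
  st <- bcn_module_state(mod)
  res <- bcn_backward_core(st, cache, dout)
  list(dx = res$dx,
       grads = list(params = res$grads, children = list()))
}
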