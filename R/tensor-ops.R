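# Array plumbing for NCHW feature maps.
#
# Feature maps are rank-4 double arrays with dim = c(N, C, H, W). R arrays
# are column-major, so the batch index varies fastest; broadcasting a
# per-channel vector v over an (N,C,H,W) array is `x * rep(v, each = N)`
# (the recycling period N*C lines up with the first two dimensions), and a
# per-sample vector of length N recycles directly.

check_nchw <- function(x, arg = "x") {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(arg, " must be a rank-4 array with dim (batch, channel, height, width)",
         call. = FALSE)
  }
  invisible(dim(x))
}

# broadcast a per-channel vector over (N,C,H,W)
rep_ch <- function(v, n_batch) rep(v, each = n_batch)

# per-channel sum over (batch, height, width): returns length-C vector
channel_sum <- function(x) {
  d <- dim(x)
  rowSums(matrix(aperm(x, c(2L, 1L, 3L, 4L)), d[2], d[1] * d[3] * d[4]))
}

channel_mean <- function(x) {
  d <- dim(x)
  channel_sum(x) / (d[1] * d[3] * d[4])
}

# per-sample sum over (channel, height, width): returns length-N vector
sample_sum <- function(x) {
  d <- dim(x)
  rowSums(matrix(x, d[1], d[2] * d[3] * d[4]))
}

sample_mean <- function(x) {
  d <- dim(x)
  sample_sum(x) / (d[2] * d[3] * d[4])
}

pad_nchw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1], d[2], d[3] + 2L * p, d[4] + 2L * p))
  out[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  out
}

crop_nchw <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[, , p + seq_len(H), p + seq_len(W), drop = FALSE]
}

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# im2col: unfold k x k patches into a (C*k*k) x (N*Ho*Wo) matrix.
# Row blocks are ordered kernel-column-major (offset i = kernel row varies
# fastest), channel fastest within a block; this matches the layout of a
# weight array with dim (out, C, k, k) flattened to (out, C*k*k).
im2col <- function(x, k, stride, pad) {
  xp <- pad_nchw(x, pad)
  d <- dim(xp)
  N <- d[1]; C <- d[2]; Hp <- d[3]; Wp <- d[4]
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  cols <- matrix(0, C * k * k, N * Ho * Wo)
  blk <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      hi <- i + stride * (seq_len(Ho) - 1L)
      wi <- j + stride * (seq_len(Wo) - 1L)
      sl <- xp[, , hi, wi, drop = FALSE]
      cols[blk * C + seq_len(C), ] <-
        matrix(aperm(sl, c(2L, 1L, 3L, 4L)), C, N * Ho * Wo)
      blk <- blk + 1L
    }
  }
  list(cols = cols, N = N, C = C, Ho = Ho, Wo = Wo,
       k = k, stride = stride, pad = pad, Hp = Hp, Wp = Wp)
}

# adjoint of im2col: scatter-add column gradients back onto the padded input
col2im <- function(dcols, info) {
  N <- info$N; C <- info$C; Ho <- info$Ho; Wo <- info$Wo
  k <- info$k; stride <- info$stride
  dxp <- array(0, c(N, C, info$Hp, info$Wp))
  blk <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      m <- dcols[blk * C + seq_len(C), , drop = FALSE]
      sl <- aperm(array(m, c(C, N, Ho, Wo)), c(2L, 1L, 3L, 4L))
      hi <- i + stride * (seq_len(Ho) - 1L)
      wi <- j + stride * (seq_len(Wo) - 1L)
      dxp[, , hi, wi] <- dxp[, , hi, wi, drop = FALSE] + sl
      blk <- blk + 1L
    }
  }
  H <- info$Hp - 2L * info$pad
  W <- info$Wp - 2L * info$pad
  crop_nchw(dxp, info$pad, H, W)
}

# row-wise numerically stable softmax of a matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}
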