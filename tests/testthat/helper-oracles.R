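# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately written as direct, loop-heavy computations that
# never call the implementation paths they check.

# central finite difference of a scalar-valued function at selected entries
fd_grad <- function(fn, x, idx, h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

# per-channel batch standardization oracle (biased variance), BN-style axes
bn_standardize_oracle <- function(x, eps = 1e-5) {
  out <- array(0, dim(x))
  for (c in seq_len(dim(x)[2])) {
    v <- x[, c, , , drop = FALSE]
    m <- mean(v)
    s2 <- mean((v - m)^2)
    out[, c, , ] <- (v - m) / sqrt(s2 + eps)
  }
  out
}

# per-sample layer standardization oracle, LN-style axes
ln_standardize_oracle <- function(x, eps = 1e-5) {
  out <- array(0, dim(x))
  for (n in seq_len(dim(x)[1])) {
    v <- x[n, , , , drop = FALSE]
    m <- mean(v)
    s2 <- mean((v - m)^2)
    out[n, , , ] <- (v - m) / sqrt(s2 + eps)
  }
  out
}

# dense multi-head attention oracle over all tokens (no routing, no
# regions); mirrors the BRA projections given the same weights
dense_attention_oracle <- function(x, Wq, Wk, Wv, Wo, bo, n_heads) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  dh <- C %/% n_heads
  y <- array(0, d)
  for (n in seq_len(N)) {
    Xt <- t(matrix(x[n, , , ], C, H * W))
    Q <- Xt %*% t(Wq); K <- Xt %*% t(Wk); V <- Xt %*% t(Wv)
    O <- matrix(0, H * W, C)
    for (h in seq_len(n_heads)) {
      cl <- (h - 1) * dh + seq_len(dh)
      logits <- Q[, cl] %*% t(K[, cl]) / sqrt(dh)
      a <- exp(logits - apply(logits, 1, max))
      a <- a / rowSums(a)
      O[, cl] <- a %*% V[, cl]
    }
    Yt <- O %*% t(Wo) + rep(bo, each = H * W)
    y[n, , , ] <- array(t(Yt), c(C, H, W))
  }
  y
}

# brute-force episodic prediction: explicit loops over queries, classes and
# cosine similarities, then a softmax
episodic_oracle <- function(support_x, support_y, query_x) {
  classes <- sort(unique(support_y))
  protos <- t(vapply(classes, function(cl) {
    mu <- colMeans(support_x[support_y == cl, , drop = FALSE])
    mu / sqrt(sum(mu^2))
  }, numeric(ncol(support_x))))
  probs <- matrix(0, nrow(query_x), length(classes))
  pred <- integer(nrow(query_x))
  for (i in seq_len(nrow(query_x))) {
    q <- query_x[i, ]
    sims <- vapply(seq_along(classes), function(c) {
      sum(protos[c, ] * q) / (sqrt(sum(protos[c, ]^2)) * sqrt(sum(q^2)))
    }, numeric(1))
    e <- exp(sims - max(sims))
    probs[i, ] <- e / sum(e)
    pred[i] <- classes[which.max(sims)]
  }
  list(probs = probs, pred = pred)
}

# one-vs-rest confusion counting oracle: nested loops
confusion_oracle <- function(y_true, y_pred, l) {
  out <- data.frame(class = 0:(l - 1), TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_len(l)) {
    cls <- i - 1
    for (j in seq_along(y_true)) {
      t_pos <- y_true[j] == cls
      p_pos <- y_pred[j] == cls
      if (t_pos && p_pos) out$TP[i] <- out$TP[i] + 1L
      else if (!t_pos && !p_pos) out$TN[i] <- out$TN[i] + 1L
      else if (!t_pos && p_pos) out$FP[i] <- out$FP[i] + 1L
      else out$FN[i] <- out$FN[i] + 1L
    }
  }
  out
}

# small backbone variants used across tests
tiny_backbone_config <- function(input_size = 32, dropout = 0) {
  backbone_config(stage_channels = c(4, 8, 8, 8),
                  units_per_stage = c(1, 1, 1, 1),
                  embed_dim = 8, dropout_rate = dropout,
                  input_size = input_size,
                  bra = bra_config(S = 1, topk_per_stage = c(1, 1, 1, 1),
                                   n_heads = 2))
}

rand_map <- function(n, c, h, w, seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(n * c * h * w), c(n, c, h, w)))
}
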