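# Region partitioning, top-k routing and the routed attention block.

test_that("partition_regions tiles losslessly and counts regions correctly", {
  x <- rand_map(2, 3, 14, 14, seed = 1)
  rt <- partition_regions(x, S = 7)
  expect_identical(dim(rt$tokens), c(2L, 49L, 4L, 3L))   # 49 regions of 2x2
  expect_equal(unpartition_regions(rt), x)
  # S = 1: one region holding all tokens
  rt1 <- partition_regions(x, S = 1)
  expect_identical(dim(rt1$tokens)[2:3], c(1L, 196L))
  expect_equal(unpartition_regions(rt1), x)
  expect_error(partition_regions(x, S = 3), "not divisible")
})

test_that("route_topk ranks by inner-product affinity with stable ties", {
  # identity-ish case: one pooled key equals the query, others orthogonal
  q <- diag(4)
  k <- diag(4)
  idx <- route_topk(q, k, 1)
  expect_identical(idx[, 1], 1:4)
  # exhaustive selection at k = S^2
  qa <- withr::with_seed(2, matrix(stats::rnorm(16), 4))
  ka <- withr::with_seed(3, matrix(stats::rnorm(16), 4))
  full <- route_topk(qa, ka, 4)
  expect_identical(sort(full[1, ]), 1:4)
  # against a brute-force full sort on a random 4x4 affinity
  A <- qa %*% t(ka)
  got <- route_topk(qa, ka, 2)
  for (i in 1:4) {
    expect_identical(got[i, ], order(A[i, ], decreasing = TRUE)[1:2])
  }
  # deterministic tie-break toward the lowest index
  tied <- bbsnet:::route_topk_core(matrix(1, 3, 3), 2)
  expect_identical(tied, matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 3))
  expect_error(route_topk(qa, ka, 5), "out of range")
})

test_that("full routing reproduces dense attention; rows are stochastic", {
  for (S in c(2, 7)) {
    layer <- bra_layer(channels = 6, n_heads = 2, S = S, seed = 4)
    x <- rand_map(2, 6, 14, 14, seed = 5)
    res <- bra_forward(x, layer, topk = S * S, return_attn = TRUE)
    p <- layer$params
    oracle <- dense_attention_oracle(x, p$Wq, p$Wk, p$Wv, p$Wo, p$bo, 2)
    expect_equal(res$out, oracle, tolerance = 1e-5,
                 label = paste("dense equivalence S =", S))
    rows_ok <- vapply(res$attn, function(per_region) {
      all(vapply(per_region, function(heads) {
        all(vapply(heads, function(a) max(abs(rowSums(a) - 1)), numeric(1)) < 1e-6)
      }, logical(1)))
    }, logical(1))
    expect_true(all(rows_ok))
  }
})

test_that("routed attention output keeps input shape and zero values null it", {
  layer <- bra_layer(channels = 8, n_heads = 2, S = 2, seed = 6)
  x <- rand_map(3, 8, 8, 8, seed = 7)
  out <- bra_forward(x, layer, topk = 2)$out
  expect_identical(dim(out), dim(x))
  layer$params$Wv <- layer$params$Wv * 0
  layer$params$bo <- layer$params$bo * 0
  out0 <- bra_forward(x, layer, topk = 2)$out
  expect_equal(max(abs(out0)), 0)
})

test_that("permuting input regions permutes routed output regions identically", {
  layer <- bra_layer(channels = 4, n_heads = 2, S = 2, seed = 8)
  x <- rand_map(1, 4, 8, 8, seed = 9)
  perm <- c(3L, 1L, 4L, 2L)
  rt <- partition_regions(x, 2)
  rt$tokens <- rt$tokens[, perm, , , drop = FALSE]
  xp <- unpartition_regions(rt)
  y <- bra_forward(x, layer, topk = 2)$out
  yp <- bra_forward(xp, layer, topk = 2)$out
  ry <- partition_regions(y, 2)
  ryp <- partition_regions(yp, 2)
  expect_equal(ryp$tokens, ry$tokens[, perm, , , drop = FALSE],
               tolerance = 1e-10)
})

test_that("the BiFormer block is residual-correct and differentiable", {
  cfg <- bra_config(S = 2, topk_per_stage = c(2, 2, 4, 4), n_heads = 2, e = 3)
  block <- biformer_layer(8, cfg, stage_index = 1, seed = 10)
  x <- rand_map(2, 8, 4, 4, seed = 11)
  res <- biformer_block(x, cfg, stage_index = 1, block = block)
  expect_identical(dim(res$out), dim(x))
  # e = 3, C = 8 -> MLP hidden width 24 (e * C by construction)
  expect_identical(nrow(block$children$fc1$params$W), 24L)
  b32 <- biformer_layer(32, bra_config(S = 2, topk_per_stage = c(2, 2, 4, 4),
                                       n_heads = 2, e = 3), 1, seed = 1)
  expect_identical(nrow(b32$children$fc1$params$W), 96L)

  # all residual-branch weights zero -> identity map
  idb <- biformer_layer(8, cfg, stage_index = 1, seed = 12)
  for (r in bbsnet:::param_refs(idb)) {
    r$env$params[[r$name]] <- r$env$params[[r$name]] * 0
  }
  # zero BCN gamma nullifies both pre-norm branches; zero dwconv kernel
  # nullifies the positional term
  expect_equal(bbsnet:::nn_forward(idb, x, training = TRUE)$out, x,
               tolerance = 1e-12)

  # finite-difference gradient w.r.t. single input pixels matches autodiff
  fwd <- bbsnet:::nn_forward(block, x, training = TRUE)
  co <- withr::with_seed(13, array(stats::rnorm(length(fwd$out)), dim(fwd$out)))
  bwd <- bbsnet:::nn_backward(block, fwd$cache, co)
  loss <- function(xx) sum(bbsnet:::nn_forward(block, xx, training = TRUE)$out * co)
  idx <- withr::with_seed(14, sample(length(x), 5))
  num <- fd_grad(loss, x, idx)
  expect_equal(bwd$dx[idx], num, tolerance = 1e-4)
})
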