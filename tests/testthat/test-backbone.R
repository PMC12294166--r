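# Channel plumbing, unit contracts and the assembled feature extractor.

test_that("channel split/concat are lossless and validate parity", {
  x <- rand_map(2, 4, 3, 3, seed = 1)
  halves <- channel_split(x)
  expect_equal(halves[[1]], x[, 1:2, , , drop = FALSE])
  expect_equal(halves[[2]], x[, 3:4, , , drop = FALSE])
  expect_equal(channel_concat(halves[[1]], halves[[2]]), x)
  expect_error(channel_split(rand_map(1, 3, 2, 2)), "odd channel")
})

test_that("channel shuffle is the reshape-transpose permutation with inverse", {
  x <- rand_map(1, 6, 2, 2, seed = 2)
  got <- channel_shuffle(x, 2)
  # oracle: reshape channels to 2 x 3, transpose, flatten
  perm_oracle <- as.vector(matrix(1:6, nrow = 2, byrow = TRUE))
  expect_identical(perm_oracle, c(1L, 4L, 2L, 5L, 3L, 6L))
  ref <- x[, c(1, 4, 2, 5, 3, 6), , , drop = FALSE]
  expect_equal(got, ref)
  # shuffle with groups g then C/g is the identity; groups = 1 degenerate
  expect_equal(channel_shuffle(channel_shuffle(x, 2), 3), x)
  expect_equal(channel_shuffle(x, 1), x)
  expect_error(channel_shuffle(x, 4), "divisible")
})

test_that("basic unit preserves shape and carries the identity half", {
  cfg <- bra_config(S = 2, topk_per_stage = c(2, 2, 4, 4), n_heads = 2)
  unit <- basic_unit_layer(8, cfg, stage_index = 1, seed = 3)
  x <- rand_map(2, 8, 4, 4, seed = 4)
  out <- basic_unit(x, params = unit)$out
  expect_identical(dim(out), dim(x))

  # zero the whole transform branch (recursively, including the BiFormer
  # block's sub-layers): the untouched half must reappear, permuted by the
  # channel shuffle
  for (r in bbsnet:::param_refs(unit)) {
    r$env$params[[r$name]] <- r$env$params[[r$name]] * 0
  }
  out0 <- basic_unit(x, params = unit)$out
  inv <- order(bbsnet:::shuffle_perm(8L, 2L))
  uns <- out0[, inv, , , drop = FALSE]
  expect_equal(uns[, 1:4, , , drop = FALSE], x[, 1:4, , , drop = FALSE],
               tolerance = 1e-12)
  expect_equal(max(abs(uns[, 5:8, , ])), 0)
})

test_that("basic unit routes gradient into both branches", {
  cfg <- bra_config(S = 2, topk_per_stage = c(2, 2, 4, 4), n_heads = 2)
  unit <- basic_unit_layer(4, cfg, stage_index = 1, seed = 5)
  x <- rand_map(2, 4, 4, 4, seed = 6)
  fwd <- bbsnet:::nn_forward(unit, x, training = TRUE)
  co <- withr::with_seed(7, array(stats::rnorm(length(fwd$out)), dim(fwd$out)))
  bwd <- bbsnet:::nn_backward(unit, fwd$cache, co)
  loss <- function(xx) sum(bbsnet:::nn_forward(unit, xx, training = TRUE)$out * co)
  # probe pixels in the identity half (channels 1-2) and transform half (3-4)
  idx <- c(1L, 2L, length(x) - 1L, 35L)
  num <- fd_grad(loss, x, idx)
  expect_equal(bwd$dx[idx], num, tolerance = 1e-4)
  expect_gt(max(abs(bwd$dx[, 1:2, , ])), 0)
  expect_gt(max(abs(bwd$dx[, 3:4, , ])), 0)
})

test_that("downsample unit halves space, retargets channels, and composes", {
  cfg <- bra_config(S = 2, topk_per_stage = c(2, 2, 4, 4), n_heads = 2)
  unit <- downsample_unit_layer(6, 12, cfg, stage_index = 2, seed = 8)
  x <- rand_map(2, 6, 8, 8, seed = 9)
  out <- downsample_unit(x, 12, params = unit)$out
  expect_identical(dim(out), c(2L, 12L, 4L, 4L))
  expect_true(all(is.finite(out)))
  unit2 <- downsample_unit_layer(12, 24, cfg, stage_index = 3, seed = 10)
  out2 <- downsample_unit(out, 24, params = unit2)$out
  expect_identical(dim(out2), c(2L, 24L, 2L, 2L))
  expect_error(downsample_unit(rand_map(1, 6, 7, 7), 12, params = unit),
               "odd spatial")
})

test_that("feature extraction follows the stride law and is deterministic in eval", {
  # stage maps at 1/4, 1/8, 1/16, 1/32 of the input side
  expect_identical(feature_map_sizes(backbone_config()), c(56L, 28L, 14L, 7L))
  cfg <- tiny_backbone_config(input_size = 32)
  model <- build_backbone(cfg, seed = 11)
  x <- withr::with_seed(12, array(stats::runif(2 * 3 * 32 * 32), c(2, 3, 32, 32)))
  fwd <- bbsnet:::model_forward(model, x, training = TRUE)
  expect_identical(vapply(fwd$stage_dims, function(d) d[3], integer(1)),
                   c(8L, 4L, 2L, 1L))
  expect_identical(dim(fwd$features), c(2L, 8L))

  calibrate_bcn(model, x)
  f1 <- extract_features(x, model)
  f2 <- extract_features(x, model)
  expect_identical(f1, f2)
  # embed length independent of batch size
  f3 <- extract_features(x[1, , , , drop = FALSE], model)
  expect_identical(ncol(f3), 8L)
  expect_equal(f3[1, ], f1[1, ], tolerance = 1e-10)
  expect_error(bbsnet:::model_forward(model, rand_map(1, 3, 16, 16)),
               "expected 32x32")
})

test_that("one optimization step on a 2-image batch reduces the probe loss", {
  cfg <- tiny_backbone_config(input_size = 32)
  model <- build_backbone(cfg, seed = 13)
  head <- withr::with_seed(14, bbsnet:::new_linear(8, 2))
  x <- withr::with_seed(15, array(stats::runif(2 * 3 * 32 * 32), c(2, 3, 32, 32)))
  y <- c(0L, 1L)
  refs <- c(bbsnet:::param_refs(model), bbsnet:::param_refs(head, "head."))
  opt <- bbsnet:::adam_init(refs)
  step_loss <- function() {
    fwd <- bbsnet:::model_forward(model, x, training = TRUE)
    hd <- bbsnet:::nn_forward(head, fwd$features, TRUE)
    ce <- bbsnet:::softmax_ce(hd$out, y)
    bh <- bbsnet:::nn_backward(head, hd$cache, ce$dlogits)
    bm <- bbsnet:::model_backward(model, fwd$caches, bh$dx)
    grads <- c(bbsnet:::flatten_grads(bm$grads),
               bbsnet:::flatten_grads(bh$grads, "head."))
    opt <<- bbsnet:::adam_step(refs, grads, opt, 0.001)
    ce$loss
  }
  l1 <- step_loss()
  l2 <- step_loss()
  expect_lt(l2, l1)
})

test_that("backbone rejects region grids that do not divide the stage maps", {
  expect_error(
    build_backbone(backbone_config(stage_channels = c(4, 8, 8, 8),
                                   units_per_stage = c(1, 1, 1, 1),
                                   embed_dim = 8, input_size = 64,
                                   bra = bra_config(S = 7))),
    "divisible by S")
  expect_error(backbone_config(input_size = 100), "divisible by 32")
  expect_error(backbone_config(stage_channels = c(3, 8, 8, 8)), "even")
})
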