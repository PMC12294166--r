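# Grade labeling, the synthetic image generator and feature-space episodes.

test_that("colony counts map to grades by the tabulated bins", {
  tab <- freshness_grade_table()
  expect_identical(nrow(tab), 5L)
  expect_true(all(diff(tab$concentration_kcfu) > 0))
  # tabulated representative concentrations recover their own grade
  expect_identical(grade_from_colony_count(4.168e3), tab$grade[1])
  expect_identical(grade_from_colony_count(13.182e3), tab$grade[2])
  expect_identical(grade_from_colony_count(301.995e3), tab$grade[3])
  expect_identical(grade_from_colony_count(1778.279e3), tab$grade[4])
  expect_identical(grade_from_colony_count(5370.317e3), tab$grade[5])
  # the measured 72-hour count exceeds the fresh limit -> a spoiled grade
  expect_match(grade_from_colony_count(1.778279e6), "spoiled")
  # the limit itself is still fresh ("should not exceed")
  expect_match(grade_from_colony_count(1e6), "fresh")
  expect_match(grade_from_colony_count(1e6 + 1), "spoiled")
  expect_error(grade_from_colony_count(0), "positive")
  expect_error(grade_from_colony_count(-5), "positive")
  # vectorized and monotone in the count
  counts <- c(1e2, 1e4, 1e5, 2e6, 1e7)
  grades <- grade_from_colony_count(counts)
  expect_identical(grades, tab$grade[c(1, 2, 3, 4, 5)])
})

test_that("image generation is deterministic, balanced and hue-graded", {
  cfg <- synth_config(n_classes = 5, images_per_class = 8, image_size = 32,
                      seed = 5)
  b1 <- generate_images(cfg)
  b2 <- generate_images(cfg)
  expect_identical(b1$pixels, b2$pixels)
  expect_identical(as.vector(table(b1$labels)), rep(8L, 5))
  expect_identical(dim(b1$pixels), c(40L, 3L, 32L, 32L))
  expect_true(all(b1$pixels >= 0 & b1$pixels <= 1))

  # degenerate noise: all images of a class identical
  cfg0 <- synth_config(images_per_class = 3, image_size = 32,
                       luster_jitter_sd = 0, texture_grain = 0, seed = 1)
  b0 <- generate_images(cfg0)
  expect_identical(b0$pixels[1, , , ], b0$pixels[2, , , ])
  expect_identical(b0$pixels[1, , , ], b0$pixels[3, , , ])
  expect_false(identical(b0$pixels[1, , , ], b0$pixels[4, , , ]))

  expect_error(synth_config(image_size = 100), "divisible by 32")
  expect_error(synth_config(n_classes = 1), "n_classes")
  expect_error(synth_config(luster_jitter_sd = -1), "luster")
})

test_that("mean hue drifts monotonically with grade (independent RGB->HSV)", {
  cfg <- synth_config(n_classes = 5, images_per_class = 100, image_size = 32,
                      seed = 7)
  b <- generate_images(cfg)
  mean_hue <- function(cls) {
    sel <- which(b$labels == cls)
    hs <- vapply(sel, function(i) {
      img <- b$pixels[i, , , ]
      # grDevices oracle on the mean RGB of the image
      hsv <- grDevices::rgb2hsv(mean(img[1, , ]), mean(img[2, , ]),
                                mean(img[3, , ]), maxColorValue = 1)
      hsv["h", 1] * 360
    }, numeric(1))
    mean(hs)
  }
  hues <- vapply(0:4, mean_hue, numeric(1))
  expect_lt(hues[1], hues[5])
  expect_true(all(diff(hues) > 0))
})

test_that("feature episodes have directional class structure", {
  # degenerate noise: samples collinear with their class direction, and
  # same-class cosine is exactly 1 regardless of magnitude jitter
  ep <- generate_feature_episode(k = 3, n = 4, q = 2, dim = 8,
                                 angle_sep = pi / 2, mag_jitter_sd = 2,
                                 noise_sd = 0, seed = 1)
  for (c in 0:2) {
    rows <- ep$support$x[ep$support$labels == c, ]
    for (i in 2:nrow(rows)) {
      expect_equal(cosine_similarity(rows[1, ], rows[i, ]), 1,
                   tolerance = 1e-9)
    }
    expect_equal(abs(cosine_similarity(rows[1, ], ep$directions[c + 1, ])), 1,
                 tolerance = 1e-9)
  }
  # pairwise direction separation honors angle_sep
  ep2 <- generate_feature_episode(k = 4, n = 1, q = 1, dim = 6,
                                  angle_sep = 0.8, seed = 2)
  D <- ep2$directions
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(acos(max(-1, min(1, sum(D[i, ] * D[j, ])))), 0.8,
                 tolerance = 1e-8)
  }
  # reproducibility and config errors
  expect_identical(generate_feature_episode(3, 2, 2, 8, pi / 2, 0.1, 0.1, seed = 3),
                   generate_feature_episode(3, 2, 2, 8, pi / 2, 0.1, 0.1, seed = 3))
  expect_error(generate_feature_episode(3, 2, 2, 2, pi / 2), "dim")
  expect_error(generate_feature_episode(3, 2, 2, 8, 2.0), "infeasible")
  expect_error(generate_feature_episode(3, 2, 2, 3, 0.5), "k \\+ 1")
})

test_that("large magnitude jitter hurts Euclidean centroids more than cosine", {
  cos_correct <- 0; euc_correct <- 0; total <- 0
  for (s in 1:50) {
    ep <- generate_feature_episode(k = 4, n = 5, q = 5, dim = 16,
                                   angle_sep = pi / 2, mag_jitter_sd = 1.2,
                                   noise_sd = 0, seed = s)
    res <- evaluate_episode(ep)
    cos_correct <- cos_correct + sum(res$predicted == ep$query$labels)
    # brute-force Euclidean nearest-centroid on the raw features
    cls <- sort(unique(ep$support$labels))
    cent <- t(vapply(cls, function(cl) {
      colMeans(ep$support$x[ep$support$labels == cl, , drop = FALSE])
    }, numeric(16)))
    for (i in seq_len(nrow(ep$query$x))) {
      d2 <- rowSums((cent - matrix(ep$query$x[i, ], nrow(cent), 16,
                                   byrow = TRUE))^2)
      euc_correct <- euc_correct + (cls[which.min(d2)] == ep$query$labels[i])
    }
    total <- total + nrow(ep$query$x)
  }
  expect_equal(cos_correct / total, 1)      # noise-free: cosine is perfect
  expect_lt(euc_correct / total, cos_correct / total)
})
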