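# Config loading, checkpoint round-trips, dataset/episode I/O and the CLI.

test_that("YAML config merges over defaults and rejects unknown keys", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", tmp)
  cfg <- load_config(tmp)
  expect_identical(cfg$protocol$k, 5L)
  expect_identical(cfg$backbone$dropout_rate, 0.4)
  expect_identical(cfg$bra$S, 7L)
  expect_identical(cfg$bra$topk_per_stage, c(7L, 8L, 16L, 49L))
  expect_identical(cfg$train$batch_size, 2L)
  expect_identical(cfg$train$lr, 0.001)
  expect_identical(cfg$train$pretrain_lr, 1e-4)

  writeLines("protocol:\n  n: 0\n", tmp)
  expect_error(load_config(tmp), "protocol.n")
  writeLines("protocol:\n  banana: 1\n", tmp)
  expect_error(load_config(tmp), "unknown key: protocol.banana")
  writeLines("frobnicate:\n  x: 1\n", tmp)
  expect_error(load_config(tmp), "unknown section")

  writeLines("protocol:\n  n: 3\nbackbone:\n  embed_dim: 16\n", tmp)
  cfg2 <- load_config(tmp)
  expect_identical(cfg2$protocol$n, 3L)
  expect_identical(cfg2$backbone$embed_dim, 16L)
  # roundtrip through save_config
  out <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg2, out)
  expect_equal(unclass(load_config(out)), unclass(cfg2))
})

test_that("checkpoints round-trip parameters and features bit-exactly", {
  cfg <- tiny_backbone_config(input_size = 32)
  model <- build_backbone(cfg, seed = 21)
  x <- withr::with_seed(22, array(stats::runif(2 * 3 * 32 * 32), c(2, 3, 32, 32)))
  calibrate_bcn(model, x)
  f_before <- extract_features(x, model)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, config = list(note = "test"))
  ck <- load_checkpoint(path)
  expect_identical(bbsnet:::collect_params(ck$model),
                   bbsnet:::collect_params(model))
  expect_identical(extract_features(x, ck$model), f_before)
  expect_identical(ck$config$note, "test")
  # truncated file -> integrity error
  bad <- withr::local_tempfile(fileext = ".rds")
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:50], bad)
  expect_error(load_checkpoint(bad), "integrity")
  # arbitrary RDS content -> integrity error
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_checkpoint(other), "integrity")
})

test_that("image datasets round-trip through the PNG directory layout", {
  cfg <- synth_config(n_classes = 3, images_per_class = 2, image_size = 32,
                      seed = 31)
  batch <- generate_images(cfg)
  dir <- withr::local_tempdir()
  labels_df <- write_image_dataset(batch, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(dir.exists(file.path(dir, "class_0")))
  expect_identical(labels_df$grade_name[1], "First-grade fresh pork")
  back <- read_image_dataset(dir)
  expect_identical(back$labels, batch$labels)
  # PNG stores 8-bit samples; tolerance is one quantization step
  expect_equal(back$pixels, batch$pixels, tolerance = 1 / 255)
})

test_that("feature episodes round-trip through the JSON+binary container", {
  ep <- generate_feature_episode(3, 2, 4, 8, pi / 2, 0.2, 0.1, seed = 41)
  prefix <- file.path(withr::local_tempdir(), "ep")
  episode_save(ep, prefix)
  back <- episode_load(prefix)
  expect_equal(back$support$x, ep$support$x, tolerance = 1e-15)
  expect_equal(back$query$x, ep$query$x, tolerance = 1e-15)
  expect_identical(back$support$labels, ep$support$labels)
  expect_identical(back$k, 3L)
})

test_that("the CLI pipeline runs end-to-end at miniature scale", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "data")
  ck_path <- file.path(root, "model.rds")
  out_dir <- file.path(root, "eval")
  tiny_yaml <- file.path(root, "tiny.yaml")
  writeLines(paste(
    "backbone:",
    "  stage_channels: [4, 8, 8, 8]",
    "  embed_dim: 8",
    "  input_size: 32",
    "  dropout_rate: 0.4",
    "bra:",
    "  S: 1",
    "  topk_per_stage: [1, 1, 1, 1]",
    "  n_heads: 2",
    "train:",
    "  batch_size: 4",
    "  pretrain_epochs: 1",
    "synth:",
    "  n_classes: 5",
    "  images_per_class: 6",
    "  image_size: 32",
    sep = "\n"), tiny_yaml)

  bbs_cli(c("generate-data", "--config", tiny_yaml, "--seed", "5",
            "--out", data_dir))
  expect_true(file.exists(file.path(data_dir, "labels.csv")))
  expect_true(file.exists(file.path(data_dir, "generate-data_run_log.json")))

  bbs_cli(c("pretrain", "--config", tiny_yaml, "--seed", "5",
            "--data", data_dir, "--out", ck_path))
  expect_true(file.exists(ck_path))
  expect_true(file.exists(paste0(ck_path, "_trace.csv")))

  bbs_cli(c("episode-eval", "--config", tiny_yaml, "--seed", "5",
            "--data", data_dir, "--checkpoint", ck_path,
            "--n", "2", "--q", "3", "--episodes", "2",
            "--out", out_dir))
  summ <- jsonlite::read_json(file.path(out_dir, "episode-eval_summary.json"))
  expect_true(summ$mean_accuracy >= 0 && summ$mean_accuracy <= 1)
  expect_false(summ$finetune)

  bbs_cli(c("finetune-eval", "--config", tiny_yaml, "--seed", "5",
            "--data", data_dir, "--checkpoint", ck_path,
            "--n", "2", "--q", "3", "--episodes", "2",
            "--out", out_dir))
  summ2 <- jsonlite::read_json(file.path(out_dir, "finetune-eval_summary.json"))
  expect_true(summ2$finetune)
  expect_true(file.exists(file.path(out_dir, "finetune-eval_predictions.csv")))

  # run log carries seed and config hash for reproducibility
  log <- jsonlite::read_json(file.path(out_dir, "finetune-eval_run_log.json"))
  expect_identical(log$seed, 5L)
  expect_true(nzchar(log$config_hash))
})

test_that("pretrain decreases the training loss on a small 2-class task", {
  cfg <- synth_config(n_classes = 2, images_per_class = 16, image_size = 32,
                      hue_start = 0, hue_end = 120, seed = 51)
  batch <- generate_images(cfg)
  bc <- tiny_backbone_config(input_size = 32, dropout = 0.4)
  res <- pretrain(batch, bc, epochs = 3, batch_size = 4, lr = 1e-3, seed = 52)
  expect_identical(nrow(res$trace), 3L)
  expect_lt(res$trace$loss[3], res$trace$loss[1])
  # head output width equals the class count
  expect_identical(nrow(res$head$params$W), 2L)
  expect_error(pretrain(list(pixels = batch$pixels,
                             labels = rep(0L, length(batch$labels))),
                        bc), "2 classes")
})
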