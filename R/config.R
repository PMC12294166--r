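#' Default run configuration
#'
#' All knobs of the pipeline with their defaults: 5-way episodes, query set
#' five times the support set, dropout 0.4, S = 7 with stage top-k
#' (7, 8, 16, 49), MLP expansion 3, batch size 2, Adam learning rates
#' 0.001 (backbone / head) and 0.0001 (pre-training).
#'
#' @param ... named overrides of the default fields (nested lists merge
#'   shallowly per section).
#' @return a list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    protocol = list(k = 5L, n = 5L, q = 25L, episodes = 20L, seed = 1L),
    backbone = list(stage_channels = c(24L, 116L, 232L, 464L),
                    units_per_stage = c(1L, 1L, 1L, 1L),
                    embed_dim = 1024L, dropout_rate = 0.4,
                    input_size = 224L),
    bra = list(S = 7L, topk_per_stage = c(7L, 8L, 16L, 49L),
               n_heads = 2L, e = 3),
    train = list(batch_size = 2L, lr = 0.001, pretrain_lr = 1e-4,
                 pretrain_epochs = 5L),
    finetune = list(epochs = 50L, lr = 0.001, mode = "joint", lambda = 1),
    synth = list(n_classes = 5L, images_per_class = 20L, image_size = 224L,
                 hue_start = 10, hue_end = 50, luster_jitter_sd = 0.15,
                 texture_grain = 4)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm,
                                  call. = FALSE)
    for (f in names(overrides[[nm]])) cfg[[nm]][[f]] <- overrides[[nm]][[f]]
  }
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  offenders <- character(0)
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) offenders <- c(offenders, paste("unknown section:", extra))
  ref <- default_config()
  for (nm in intersect(names(cfg), known)) {
    bad <- setdiff(names(cfg[[nm]]), names(ref[[nm]]))
    if (length(bad)) {
      offenders <- c(offenders, paste0("unknown key: ", nm, ".", bad))
    }
  }
  p <- cfg$protocol
  if (!is.null(p)) {
    for (f in c("k", "n", "q", "episodes")) {
      if (!is.null(p[[f]]) && (!is.numeric(p[[f]]) || p[[f]] < 1)) {
        offenders <- c(offenders, paste0("protocol.", f, " must be >= 1"))
      }
    }
  }
  if (!is.null(cfg$backbone$dropout_rate) &&
      (cfg$backbone$dropout_rate < 0 || cfg$backbone$dropout_rate >= 1)) {
    offenders <- c(offenders, "backbone.dropout_rate must lie in [0, 1)")
  }
  if (!is.null(cfg$backbone$input_size) &&
      cfg$backbone$input_size %% 32 != 0) {
    offenders <- c(offenders, "backbone.input_size must be divisible by 32")
  }
  if (length(offenders)) {
    stop("invalid configuration:\n  ", paste(offenders, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial) YAML file and merges it over
#' [default_config()]; an empty file yields the full defaults. Unknown
#' sections or keys, and out-of-range values, raise a config error listing
#' every offender.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  # YAML 1.1 resolves a bare `n:` key to a boolean; map it back (the
  # schema has no boolean-valued fields or keys besides these letters)
  raw <- yaml::yaml.load(
    paste(readLines(path, warn = FALSE), collapse = "\n"),
    handlers = list("bool#no" = function(x) "n", "bool#yes" = function(x) "y"))
  if (is.null(raw)) raw <- list()
  validate_config(raw)
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

backbone_config_from_run <- function(cfg) {
  backbone_config(
    stage_channels = cfg$backbone$stage_channels,
    units_per_stage = cfg$backbone$units_per_stage,
    embed_dim = cfg$backbone$embed_dim,
    dropout_rate = cfg$backbone$dropout_rate,
    input_size = cfg$backbone$input_size,
    bra = bra_config(S = cfg$bra$S,
                     topk_per_stage = cfg$bra$topk_per_stage,
                     n_heads = cfg$bra$n_heads, e = cfg$bra$e)
  )
}

#' Desk-scale run configuration
#'
#' A reduced configuration sized for CPU-only experimentation and the test
#' suite: 64-pixel images, narrow stages (16/32/64/128 channels), a
#' 128-dimensional embedding and a 2x2 region grid with stage top-k
#' (1, 1, 2, 4) (the stage maps at 64 px are 16/8/4/2 pixels, so the
#' full-scale 7x7 grid is not applicable). Pre-training uses minibatches
#' of 8 — at batch size 2 the batch-branch statistics of BCN are so noisy
#' that the classification head cannot learn within a desk-scale epoch
#' budget — and the feature-extractor learning rate 0.001. The synthetic
#' section is the generator's easy separation setting: a 120-degree hue
#' span (24 degrees between adjacent grades) with the default luster
#' jitter and texture. Desk-scale fine-tuning runs 5 epochs: the episodic
#' features here are far weaker than fully pre-trained ones, and longer
#' entropy regularization on weakly separated classes erodes weak
#' boundaries.
#'
#' @param ... overrides forwarded to [default_config()].
#' @return a `run_config`.
#' @export
desk_config <- function(...) {
  cfg <- default_config(
    backbone = list(stage_channels = c(16L, 32L, 64L, 128L),
                    units_per_stage = c(1L, 1L, 1L, 1L),
                    embed_dim = 128L, dropout_rate = 0.4,
                    input_size = 64L),
    bra = list(S = 2L, topk_per_stage = c(1L, 1L, 2L, 4L), n_heads = 2L,
               e = 3),
    train = list(batch_size = 8L, lr = 0.001, pretrain_lr = 0.001,
                 pretrain_epochs = 5L),
    finetune = list(epochs = 5L, lr = 0.001, mode = "joint", lambda = 1),
    synth = list(n_classes = 5L, images_per_class = 60L, image_size = 64L,
                 hue_start = 0, hue_end = 120, luster_jitter_sd = 0.15,
                 texture_grain = 4)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    for (f in names(overrides[[nm]])) cfg[[nm]][[f]] <- overrides[[nm]][[f]]
  }
  validate_config(cfg)
  cfg
}
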