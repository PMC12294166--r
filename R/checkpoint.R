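CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file container (R serialization, version 3)
#' holding the checkpoint format version, the backbone configuration, every
#' learnable parameter, every BCN running statistic, the optional
#' classifier head and the generating run configuration. Save then load
#' reproduces all parameters bit-exactly, so eval-mode features are
#' identical before and after a round trip. Corrupt or truncated files and
#' version mismatches raise an integrity error.
#'
#' @param model a model from [build_backbone()] / [pretrain()].
#' @param path file path.
#' @param head optional `classifier_head` (or the linear pre-training
#'   head's parameters).
#' @param config optional run configuration to embed for provenance.
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` a
#'   list with `model`, `head`, `config`.
#' @export
save_checkpoint <- function(model, path, head = NULL, config = NULL) {
  obj <- list(
    version = CHECKPOINT_VERSION,
    magic = "bbsnet-checkpoint",
    backbone_config = model$config,
    params = collect_params(model),
    buffers = collect_buffers(model),
    head = head,
    config = config
  )
  saveRDS(obj, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("checkpoint integrity error: cannot read ", path, " (",
         conditionMessage(e), ")", call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$magic, "bbsnet-checkpoint")) {
    stop("checkpoint integrity error: ", path,
         " is not a model checkpoint", call. = FALSE)
  }
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    stop(sprintf("checkpoint version mismatch: file has %s, expected %d",
                 obj$version, CHECKPOINT_VERSION), call. = FALSE)
  }
  model <- build_backbone(obj$backbone_config, seed = 0L)
  set_params(model, obj$params)
  set_buffers(model, obj$buffers)
  list(model = model, head = obj$head, config = obj$config)
}
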