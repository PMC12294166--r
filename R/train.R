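#' Recalibrate BCN running statistics
#'
#' The batch branch of every BCN layer keeps exponential-moving-average
#' statistics for inference. When training uses very small minibatches
#' (batch size 2), per-batch variances systematically underestimate the
#' population variance, and near-constant channels end up with running
#' variances close to zero; at eval time the mismatch is amplified by
#' \eqn{1/\sqrt{\sigma^2+\epsilon}} and compounds across layers. After
#' training, this routine replays the data through the network in training
#' mode with large batches (so batch statistics approximate population
#' statistics) for a few passes, letting the EMAs settle at values
#' consistent with what each layer sees at inference. No parameter is
#' touched.
#'
#' @param model a backbone model.
#' @param x image array or `image_batch` (the calibration set).
#' @return the model, invisibly (statistics updated in place).
#' @details Calibration replays the whole calibration set in a single
#'   forward pass with every BCN momentum temporarily set to 1, so each
#'   layer's running statistics become exactly the statistics of the
#'   inputs it receives during that pass. Because branch-1 output then
#'   uses those same statistics, the calibration pass and subsequent
#'   eval-mode passes on the same distribution are mutually consistent,
#'   layer by layer.
#' @export
calibrate_bcn <- function(model, x) {
  if (inherits(x, "image_batch")) x <- x$pixels
  bcns <- find_modules(model, "bcn")
  old <- lapply(bcns, function(m) m$momentum)
  for (m in bcns) m$momentum <- 1
  # momentum 1 requires the 'initialized' EMA path, not the first-fill path
  for (m in bcns) m$buffers$initialized <- TRUE
  on.exit(for (i in seq_along(bcns)) bcns[[i]]$momentum <- old[[i]])
  model_forward(model, x, training = TRUE)
  invisible(model)
}

# depth-first collection of sub-modules of a given class
find_modules <- function(mod, cls) {
  out <- if (inherits(mod, cls)) list(mod) else list()
  for (child in mod$children) out <- c(out, find_modules(child, cls))
  out
}

#' Train the backbone with a temporary softmax classification head
#'
#' Standard supervised pre-training of the feature extractor: the backbone
#' plus a fully connected head (one output neuron per class) is trained
#' with softmax cross-entropy and Adam. The head is kept in the returned
#' object for inspection but the product of this step is the trained
#' backbone; downstream episodic evaluation discards the head.
#'
#' @param data an `image_batch` (from [generate_images()] /
#'   [read_image_dataset()]) or a list with `pixels` and `labels`.
#' @param config a [backbone_config()]; its `input_size` must match the
#'   images.
#' @param epochs training epochs.
#' @param batch_size minibatch size (default 2).
#' @param lr Adam learning rate (default 1e-4, the pre-training rate).
#' @param seed integer seed covering parameter initialization, shuffling
#'   and dropout.
#' @param verbose print per-epoch losses.
#' @return list with the trained `model`, the classification `head`, a
#'   per-epoch `trace` data frame (epoch, loss, accuracy) and the config.
#' @export
pretrain <- function(data, config = backbone_config(), epochs = 5,
                     batch_size = 2L, lr = 1e-4, seed = 1,
                     verbose = FALSE) {
  x <- if (inherits(data, "image_batch")) data$pixels else data$pixels
  labels <- data$labels
  n_classes <- length(unique(labels))
  if (n_classes < 2L) {
    stop("pretrain: need at least 2 classes", call. = FALSE)
  }
  d <- check_nchw(x)
  n <- d[1]
  model <- build_backbone(config, seed = seed)
  head <- withr::with_seed(seed + 1L,
                           new_linear(config$embed_dim, n_classes))
  refs <- c(param_refs(model), param_refs(head, "head."))
  opt <- adam_init(refs)
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      accuracy = numeric(0))
  withr::with_seed(seed + 2L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      losses <- numeric(0)
      correct <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[sel, , , , drop = FALSE]
        yb <- labels[sel]
        fwd <- model_forward(model, xb, training = TRUE)
        hd <- nn_forward(head, fwd$features, training = TRUE)
        ce <- softmax_ce(hd$out, yb)
        losses <- c(losses, ce$loss)
        correct <- correct +
          sum(max.col(ce$probs, ties.method = "first") - 1L == yb)
        bh <- nn_backward(head, hd$cache, ce$dlogits)
        bm <- model_backward(model, fwd$caches, bh$dx)
        grads <- c(flatten_grads(bm$grads),
                   flatten_grads(bh$grads, "head."))
        opt <- adam_step(refs, grads, opt, lr)
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses),
                                       accuracy = correct / n))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f acc %.3f", ep,
                        mean(losses), correct / n))
      }
    }
  })
  calibrate_bcn(model, x)
  list(model = model, head = head, trace = trace, config = config,
       n_classes = n_classes, seed = seed)
}
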