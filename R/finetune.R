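#' Initialize the fine-tuning classifier head from prototypes
#'
#' The transductive fine-tuning stage trains a k-way softmax head
#' \eqn{p = \mathrm{softmax}(W \hat f(x) + b)} on top of the frozen feature
#' extractor, where \eqn{\hat f(x)} is the unit-normalized feature vector.
#' The head is initialized with `W = M` (the prototype matrix) and `b = 0`,
#' so before any update its predictions coincide exactly with the episodic
#' cosine-prototype classifier.
#'
#' Because cosine logits are confined to `[-1, 1]`, the head multiplies the
#' normalized features by a fixed `logit_scale` before the affine map
#' (`logits = s W \hat f(x) + b`); the scale is monotone, so it never
#' changes which class is predicted, but it controls how peaked the
#' softmax is — without it the entropy regularizer acts on near-uniform
#' distributions, whose minimization provably drifts toward a single-class
#' collapse instead of sharpening the prototype structure.
#'
#' @param M a [compute_prototypes()] matrix.
#' @param logit_scale fixed multiplier applied to the normalized features
#'   (default 1: pure cosine logits, exactly the episodic classifier).
#' @return a `classifier_head`: list with `W` (k x dim), `b` (k) and
#'   `logit_scale`.
#' @export
init_head <- function(M, logit_scale = 1) {
  M <- as.matrix(M)
  structure(list(W = unclass(M), b = numeric(nrow(M)),
                 logit_scale = logit_scale),
            class = "classifier_head")
}

head_scale <- function(head) head$logit_scale %||% 1

head_logits <- function(head, features) {
  f <- unit_rows(as.matrix(features)) * head_scale(head)
  sweep(tcrossprod(f, head$W), 2L, head$b, "+")
}

#' @rdname init_head
#' @param head a `classifier_head`.
#' @param features feature matrix (rows are unit-normalized internally).
#' @return `predict_head()`: an `n x k` probability matrix.
#' @export
predict_head <- function(head, features) {
  softmax_rows(head_logits(head, features))
}

#' Support-set cross-entropy loss of a classifier head
#'
#' \eqn{-\sum_j y_j \log p_j}, summed (not averaged) over the support
#' samples, with \eqn{p_j = \mathrm{softmax}(W \hat f(x_j) + b)}.
#'
#' @param head a `classifier_head`.
#' @param support_features feature matrix of the support set.
#' @param support_labels 0-based class labels.
#' @return nonnegative scalar.
#' @export
support_ce_loss <- function(head, support_features, support_labels) {
  support_features <- as.matrix(support_features)
  if (nrow(support_features) == 0L) {
    stop("support_ce_loss: empty support set", call. = FALSE)
  }
  p <- predict_head(head, support_features)
  idx <- cbind(seq_len(nrow(p)), support_labels + 1L)
  -sum(log(pmax(p[idx], 1e-300)))
}

#' Entropy regularizer over the query set
#'
#' \eqn{H(p) = -\sum_{i=1}^{m}\sum_c p_{ic}\log p_{ic}}: the sum of the
#' Shannon entropies of the head's predicted distributions over the m
#' (unlabeled) query samples. Bounded by \eqn{0 \le H \le m \ln k}.
#'
#' @param head a `classifier_head`.
#' @param query_features feature matrix of the query set.
#' @return nonnegative scalar.
#' @export
query_entropy <- function(head, query_features) {
  query_features <- as.matrix(query_features)
  if (nrow(query_features) == 0L) {
    stop("query_entropy: empty query set", call. = FALSE)
  }
  p <- predict_head(head, query_features)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Fine-tuning configuration
#'
#' @param epochs number of fine-tuning epochs (>= 0; 0 returns the
#'   prototype-initialized head unchanged).
#' @param lr Adam learning rate for the head.
#' @param mode `"joint"` minimizes support cross-entropy plus
#'   `lambda * H(query)` in one step per epoch; `"two_stage"` alternates a
#'   cross-entropy step on the support set and an entropy step on the query
#'   set within each epoch.
#' @param lambda signed weight of the entropy regularizer; the default `+1`
#'   adds the query entropy to the loss (entropy minimization, i.e.
#'   confidence encouragement on the unlabeled queries).
#' @param logit_scale fixed cosine-logit multiplier of the head (see
#'   [init_head()]).
#' @param seed integer seed (Adam is deterministic; the seed is recorded
#'   for provenance).
#' @return list of class `finetune_config`.
#' @export
finetune_config <- function(epochs = 50, lr = 0.001, mode = c("joint", "two_stage"),
                            lambda = 1, logit_scale = 10, seed = 1) {
  mode <- match.arg(mode)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 0L) {
    stop("finetune_config: epochs must be >= 0", call. = FALSE)
  }
  if (lr <= 0) stop("finetune_config: lr must be positive", call. = FALSE)
  structure(list(epochs = epochs, lr = lr, mode = mode, lambda = lambda,
                 logit_scale = logit_scale, seed = as.integer(seed)),
            class = "finetune_config")
}

# gradient of (sum CE over support) + lambda * H(query) w.r.t. (W, b).
# Closed form: dCE/dlogit = p - y per support sample;
# dH/dlogit_k = -p_k (log p_k - sum_c p_c log p_c) per query sample.
finetune_grads <- function(head, Fs, ys, Fq, lambda, use_ce = TRUE,
                           use_ent = TRUE) {
  s <- head_scale(head)
  dW <- matrix(0, nrow(head$W), ncol(head$W))
  db <- numeric(nrow(head$W))
  if (use_ce && !is.null(Fs)) {
    fs <- unit_rows(Fs) * s
    p <- softmax_rows(sweep(tcrossprod(fs, head$W), 2L, head$b, "+"))
    idx <- cbind(seq_len(nrow(p)), ys + 1L)
    dlog <- p
    dlog[idx] <- dlog[idx] - 1
    dW <- dW + crossprod(dlog, fs)
    db <- db + colSums(dlog)
  }
  if (use_ent && !is.null(Fq) && lambda != 0) {
    fq <- unit_rows(Fq) * s
    p <- softmax_rows(sweep(tcrossprod(fq, head$W), 2L, head$b, "+"))
    lp <- ifelse(p > 0, log(p), 0)
    dlog <- -p * (lp - rowSums(p * lp))
    dW <- dW + lambda * crossprod(dlog, fq)
    db <- db + lambda * colSums(dlog)
  }
  list(W = dW, b = db)
}

#' Fine-tune the softmax head on one episode
#'
#' Minimizes the transductive objective: support cross-entropy plus
#' `lambda` times the query-prediction entropy, by Adam steps on `(W, b)`
#' only. The feature extractor is frozen: features are computed once before
#' the loop (or supplied precomputed) and never touched again; query labels
#' are never read. In `"two_stage"` mode each epoch performs a
#' cross-entropy step on the support set followed by an entropy step on the
#' query set, mirroring the two-stage optimization schedule.
#'
#' @param episode an [sample_episode()] result. If `backbone` is `NULL`,
#'   `episode$support$x` / `episode$query$x` must already be feature
#'   matrices.
#' @param backbone optional frozen feature extractor (eval mode) used to
#'   encode the episode's images.
#' @param cfg a [finetune_config()].
#' @return list with the fine-tuned `head`, the initial head (`head0`),
#'   a `trace` data frame (epoch, ce, entropy, total; row `epoch = e` is
#'   the loss after `e` epochs) and the query probability matrix.
#' @export
finetune <- function(episode, backbone = NULL, cfg = finetune_config()) {
  if (is.null(backbone)) {
    Fs <- as.matrix(episode$support$x)
    Fq <- as.matrix(episode$query$x)
  } else {
    Fs <- extract_features(episode$support$x, backbone, training = FALSE)
    Fq <- extract_features(episode$query$x, backbone, training = FALSE)
  }
  ys <- episode$support$labels
  M <- compute_prototypes(Fs, ys)
  head <- init_head(M, logit_scale = cfg$logit_scale %||% 1)
  head0 <- head

  eval_losses <- function(h) {
    ce <- support_ce_loss(h, Fs, ys)
    ent <- query_entropy(h, Fq)
    c(ce = ce, entropy = ent, total = ce + cfg$lambda * ent)
  }
  trace <- matrix(0, cfg$epochs + 1L, 3L,
                  dimnames = list(NULL, c("ce", "entropy", "total")))
  trace[1L, ] <- eval_losses(head)

  if (cfg$epochs > 0L) {
    st <- list(t = 0L,
               mW = matrix(0, nrow(head$W), ncol(head$W)),
               vW = matrix(0, nrow(head$W), ncol(head$W)),
               mb = numeric(length(head$b)),
               vb = numeric(length(head$b)))
    step <- function(head, g, st, lr) {
      st$t <- st$t + 1L
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      st$mW <- b1 * st$mW + (1 - b1) * g$W
      st$vW <- b2 * st$vW + (1 - b2) * g$W^2
      st$mb <- b1 * st$mb + (1 - b1) * g$b
      st$vb <- b2 * st$vb + (1 - b2) * g$b^2
      head$W <- head$W - lr * (st$mW / (1 - b1^st$t)) /
        (sqrt(st$vW / (1 - b2^st$t)) + eps)
      head$b <- head$b - lr * (st$mb / (1 - b1^st$t)) /
        (sqrt(st$vb / (1 - b2^st$t)) + eps)
      list(head = head, st = st)
    }
    for (e in seq_len(cfg$epochs)) {
      if (cfg$mode == "joint") {
        g <- finetune_grads(head, Fs, ys, Fq, cfg$lambda)
        r <- step(head, g, st, cfg$lr); head <- r$head; st <- r$st
      } else {
        g <- finetune_grads(head, Fs, ys, NULL, cfg$lambda,
                            use_ent = FALSE)
        r <- step(head, g, st, cfg$lr); head <- r$head; st <- r$st
        g <- finetune_grads(head, NULL, NULL, Fq, cfg$lambda,
                            use_ce = FALSE)
        r <- step(head, g, st, cfg$lr); head <- r$head; st <- r$st
      }
      trace[e + 1L, ] <- eval_losses(head)
    }
  }
  probs <- predict_head(head, Fq)
  pred <- max.col(probs, ties.method = "first") - 1L
  list(head = head, head0 = head0,
       trace = data.frame(epoch = 0:cfg$epochs, trace),
       probs = probs, predicted = pred,
       accuracy = mean(pred == episode$query$labels))
}
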