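#' Cosine similarity between two vectors
#'
#' \deqn{sim(u, v) = \frac{u \cdot v}{\|u\|_2 \|v\|_2} = \cos\theta}
#' Scale-invariant in both arguments; errors on a zero vector.
#'
#' @param u,v numeric vectors of equal length, both nonzero.
#' @return a scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("cosine_similarity: vectors differ in length", call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine_similarity: zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

unit_rows <- function(m) {
  nr <- sqrt(rowSums(m^2))
  if (any(nr == 0)) stop("zero feature vector cannot be normalized",
                         call. = FALSE)
  m / nr
}

#' Class prototypes from support features
#'
#' The prototype of class c is the mean of its support feature vectors,
#' rescaled to unit 2-norm. The rows of the returned matrix `M` are the
#' prototypes \eqn{\mu_1 \ldots \mu_k} (ordered by class id).
#'
#' @param features numeric matrix, one support feature vector per row.
#' @param labels 0-based integer class labels, one per row.
#' @return a `prototype_set`: the `k x dim` matrix `M` with unit-norm rows
#'   and a `classes` attribute giving the class ids.
#' @export
compute_prototypes <- function(features, labels) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stop("compute_prototypes: one label per feature row required",
         call. = FALSE)
  }
  classes <- sort(unique(labels))
  M <- matrix(0, length(classes), ncol(features))
  for (i in seq_along(classes)) {
    rows <- features[labels == classes[i], , drop = FALSE]
    mu <- colMeans(rows)
    nn <- sqrt(sum(mu^2))
    if (nn == 0) {
      stop(sprintf("degenerate prototype: class %s has zero mean vector",
                   classes[i]), call. = FALSE)
    }
    M[i, ] <- mu / nn
  }
  structure(M, classes = classes, class = c("prototype_set", "matrix", "array"))
}

#' Classify a query feature vector against class prototypes
#'
#' The query is unit-normalized, so the logits \eqn{M\hat q} are exactly the
#' cosine similarities to the prototypes; a softmax converts them to class
#' probabilities. Ties in the argmax resolve to the lowest class index.
#'
#' @param q a nonzero feature vector (or, for `classify_queries`, a matrix
#'   of such rows).
#' @param M a [compute_prototypes()] result (any matrix with unit-norm rows
#'   works).
#' @return `classify_query`: a probability vector over the k classes
#'   (sums to 1). `classify_queries`: an `n x k` probability matrix.
#' @export
classify_query <- function(q, M) {
  if (length(q) != ncol(M)) {
    stop(sprintf("classify_query: query length %d != prototype dim %d",
                 length(q), ncol(M)), call. = FALSE)
  }
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("classify_query: zero query vector", call. = FALSE)
  logits <- as.vector(M %*% (q / nq))
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' @rdname classify_query
#' @export
classify_queries <- function(q, M) {
  q <- as.matrix(q)
  probs <- softmax_rows(tcrossprod(unit_rows(q), unclass(M)))
  colnames(probs) <- attr(M, "classes")
  probs
}

#' Sample a k-way n-shot episode
#'
#' Draws `n` support and `q` query items per class, uniformly without
#' replacement and index-disjoint, from a labeled dataset. If the dataset
#' has more than `k` classes, `k` of them are sampled first. By default the
#' query set is five times the support set (`q = 5 * n`).
#'
#' @param dataset a list with `x` (feature matrix or rank-4 image array;
#'   rows/first axis are items) and `labels` (0-based integers).
#' @param k number of ways (classes).
#' @param n support shots per class.
#' @param q query items per class (default `5 * n`).
#' @param seed integer seed; the same seed reproduces the episode exactly.
#' @return an `episode`: list with `support` and `query` (each `x`,
#'   `labels`, `index`), and `k`, `n`, `q`. Labels are re-coded 0..k-1 in
#'   the order of the sampled class ids (stored as `classes`).
#' @export
sample_episode <- function(dataset, k, n, q = 5L * n, seed = 1) {
  labels <- dataset$labels
  classes <- sort(unique(labels))
  if (length(classes) < k) {
    stop(sprintf("dataset has %d classes, need k=%d", length(classes), k),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    chosen <- sort(sample(classes, k))
    sup_idx <- integer(0)
    qry_idx <- integer(0)
    for (cls in chosen) {
      pool <- which(labels == cls)
      if (length(pool) < n + q) {
        stop(sprintf(
          "class %s has only %d items; need n+q = %d", cls, length(pool),
          n + q), call. = FALSE)
      }
      pick <- sample(pool, n + q)
      sup_idx <- c(sup_idx, pick[seq_len(n)])
      qry_idx <- c(qry_idx, pick[n + seq_len(q)])
    }
  })
  recode <- function(l) match(l, chosen) - 1L
  take <- function(idx) {
    x <- if (length(dim(dataset$x)) == 4L) {
      dataset$x[idx, , , , drop = FALSE]
    } else {
      dataset$x[idx, , drop = FALSE]
    }
    list(x = x, labels = recode(labels[idx]), index = idx)
  }
  structure(list(support = take(sup_idx), query = take(qry_idx),
                 k = as.integer(k), n = as.integer(n), q = as.integer(q),
                 classes = chosen),
            class = "episode")
}

#' Evaluate the episodic cosine-prototype classifier on one episode
#'
#' Pipeline: extract features (optional `feature_fn`), build unit-norm
#' prototypes from the support set, classify every query by softmax over
#' cosine similarities.
#'
#' @param episode an [sample_episode()] result (or any list with matching
#'   `support`/`query` fields holding feature matrices).
#' @param feature_fn function mapping the episode's `x` to a feature
#'   matrix; defaults to the identity (features already computed).
#' @return list with `accuracy`, predicted labels, the probability matrix
#'   and the prototypes.
#' @export
evaluate_episode <- function(episode, feature_fn = identity) {
  fs <- feature_fn(episode$support$x)
  fq <- feature_fn(episode$query$x)
  M <- compute_prototypes(fs, episode$support$labels)
  probs <- classify_queries(fq, M)
  pred <- max.col(probs, ties.method = "first") - 1L
  list(accuracy = mean(pred == episode$query$labels),
       predicted = pred, probs = probs, prototypes = M)
}
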