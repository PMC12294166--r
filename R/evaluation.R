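#' One-vs-rest confusion counts
#'
#' For each class i, counts of true positives, true negatives, false
#' positives and false negatives when class i is taken as the positive
#' class and all others as negative.
#'
#' @param y_true,y_pred equal-length 0-based integer label vectors.
#' @param l number of classes; labels must lie in `[0, l)`.
#' @return a `confusion_counts` data frame with columns `class`, `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, l) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion_counts: label vectors differ in length", call. = FALSE)
  }
  l <- as.integer(l)
  bad <- c(y_true, y_pred)
  if (any(bad < 0L | bad >= l)) {
    stop(sprintf("confusion_counts: labels must lie in [0, %d)", l),
         call. = FALSE)
  }
  n <- length(y_true)
  out <- data.frame(class = 0:(l - 1L), TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_len(l)) {
    cls <- i - 1L
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    out$TP[i] <- tp
    out$FP[i] <- fp
    out$FN[i] <- fn
    out$TN[i] <- n - tp - fp - fn
  }
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Macro-averaged accuracy, sensitivity, specificity and precision
#'
#' Each metric is the unweighted mean over classes of the per-class
#' one-vs-rest ratio:
#' \deqn{Acc_i = \frac{TP_i + TN_i}{TP_i+TN_i+FP_i+FN_i},\quad
#'       Sen_i = \frac{TP_i}{TP_i+FN_i},\quad
#'       Spe_i = \frac{TN_i}{FP_i+TN_i},\quad
#'       Pre_i = \frac{TP_i}{TP_i+FP_i}}
#' A per-class ratio with a zero denominator is undefined; it contributes 0
#' to the average and the class is recorded in `undefined`. Note that with
#' more than two classes the macro-averaged accuracy exceeds the overall
#' (item-level) accuracy, which is reported separately as
#' `overall_accuracy`.
#'
#' @param counts a [confusion_counts()] result.
#' @return a `metrics_report` list: `average_acc`, `average_sen`,
#'   `average_spe`, `average_pre`, `overall_accuracy`, the `per_class`
#'   table and `undefined` flags.
#' @export
macro_metrics <- function(counts) {
  if (nrow(counts) == 0L) {
    stop("macro_metrics: no classes", call. = FALSE)
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, 0)
  acc <- ratio(counts$TP + counts$TN,
               counts$TP + counts$TN + counts$FP + counts$FN)
  sen <- ratio(counts$TP, counts$TP + counts$FN)
  spe <- ratio(counts$TN, counts$FP + counts$TN)
  pre <- ratio(counts$TP, counts$TP + counts$FP)
  undef <- data.frame(
    class = counts$class,
    sen = (counts$TP + counts$FN) == 0L,
    spe = (counts$FP + counts$TN) == 0L,
    pre = (counts$TP + counts$FP) == 0L
  )
  total <- counts$TP[1] + counts$TN[1] + counts$FP[1] + counts$FN[1]
  structure(list(
    average_acc = mean(acc),
    average_sen = mean(sen),
    average_spe = mean(spe),
    average_pre = mean(pre),
    overall_accuracy = if (total > 0) sum(counts$TP) / total else 0,
    per_class = data.frame(class = counts$class, acc = acc, sen = sen,
                           spe = spe, pre = pre),
    undefined = undef
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "macro Acc %.4f | Sen %.4f | Spe %.4f | Pre %.4f (overall %.4f)\n",
    x$average_acc, x$average_sen, x$average_spe, x$average_pre,
    x$overall_accuracy))
  invisible(x)
}

#' Stratified k-fold partition
#'
#' Shuffles each class separately and deals its items round-robin across
#' the folds, so per-fold class counts differ by at most one from
#' proportional and the folds partition the index set exactly.
#'
#' @param labels class labels (any atomic type).
#' @param folds number of folds (default 5).
#' @param seed integer seed; identical seeds give identical folds.
#' @return list of `folds` elements, each `list(train, test)` index
#'   vectors.
#' @export
stratified_kfold <- function(labels, folds = 5L, seed = 1) {
  folds <- as.integer(folds)
  n <- length(labels)
  assign_fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < folds) {
        stop(sprintf("class %s has %d items, fewer than %d folds",
                     cls, length(idx), folds), call. = FALSE)
      }
      idx <- sample(idx)
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  lapply(seq_len(folds), function(f) {
    list(train = which(assign_fold != f), test = which(assign_fold == f))
  })
}

#' Two-sample equal-variance t-test
#'
#' Pooled-variance t statistic with `n_a + n_b - 2` degrees of freedom and
#' a two-sided p-value (doubled tail of the t distribution). Used to
#' compare mean accuracies across repeated runs.
#'
#' @param a,b numeric vectors of at least 2 values each.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop("two_sample_ttest: each sample needs >= 2 values", call. = FALSE)
  }
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    stop("two_sample_ttest: zero pooled variance (degenerate samples)",
         call. = FALSE)
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' @rdname two_sample_ttest
#' @description `paired_ttest()` is the paired companion: a one-sample t
#'   test on the elementwise differences `a - b` (df = n - 1), for
#'   comparing two methods evaluated on the same episodes.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired_ttest: samples must have equal length", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("paired_ttest: need >= 2 pairs", call. = FALSE)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) != 0) {
      stop("paired_ttest: zero variance with nonzero mean difference",
           call. = FALSE)
    }
    return(list(t = 0, df = n - 1L, p = 1))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L))
}

#' Episodic evaluation under stratified cross-validation
#'
#' Splits the dataset with [stratified_kfold()]; per fold, a model is built
#' on the training folds (via `model_builder`) and episodes are sampled
#' from the held-out fold only, so support and query items never leak from
#' the training side.
#'
#' @param dataset list with `x` (feature matrix or image array) and
#'   `labels`.
#' @param model_builder `function(x_train, labels_train, seed)` returning a
#'   feature-extraction function `function(x) -> matrix`. Use
#'   `function(...) identity` when `dataset$x` already holds features.
#' @param protocol list with `k`, `n`, `q`, `episodes_per_fold`, optional
#'   `folds` (default 5) and `finetune` (logical or a [finetune_config()]).
#' @param seed master seed; fold assignment, episode sampling and model
#'   building all derive from it.
#' @return list with the pooled `report` ([macro_metrics()]), per-fold mean
#'   accuracies, per-episode accuracies, and `mean`/`sd` across folds.
#' @export
run_crossval <- function(dataset, model_builder, protocol, seed = 1) {
  folds <- protocol$folds %||% 5L
  ft <- protocol$finetune %||% FALSE
  ft_cfg <- if (isTRUE(ft)) finetune_config() else if (inherits(ft, "finetune_config")) ft else NULL
  splits <- stratified_kfold(dataset$labels, folds, seed)
  sub_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max %/% 2L,
                      folds * (protocol$episodes_per_fold + 1L)),
           folds)
  })
  take_items <- function(idx) {
    x <- if (length(dim(dataset$x)) == 4L) {
      dataset$x[idx, , , , drop = FALSE]
    } else {
      dataset$x[idx, , drop = FALSE]
    }
    list(x = x, labels = dataset$labels[idx])
  }
  fold_acc <- numeric(folds)
  episode_acc <- matrix(0, folds, protocol$episodes_per_fold)
  yt <- integer(0); yp <- integer(0)
  for (f in seq_len(folds)) {
    tr <- take_items(splits[[f]]$train)
    te <- take_items(splits[[f]]$test)
    feature_fn <- model_builder(tr$x, tr$labels, sub_seeds[f, 1L])
    te_feat <- list(x = feature_fn(te$x), labels = te$labels)
    for (e in seq_len(protocol$episodes_per_fold)) {
      ep <- sample_episode(te_feat, protocol$k, protocol$n, protocol$q,
                           seed = sub_seeds[f, e + 1L])
      if (is.null(ft_cfg)) {
        res <- evaluate_episode(ep)
      } else {
        res <- finetune(ep, backbone = NULL, cfg = ft_cfg)
      }
      episode_acc[f, e] <- res$accuracy
      pred <- if (is.null(ft_cfg)) res$predicted else res$predicted
      yt <- c(yt, ep$query$labels)
      yp <- c(yp, pred)
    }
    fold_acc[f] <- mean(episode_acc[f, ])
  }
  report <- macro_metrics(confusion_counts(yt, yp, protocol$k))
  list(report = report, fold_accuracy = fold_acc,
       episode_accuracy = episode_acc,
       mean = mean(fold_acc), sd = stats::sd(fold_acc))
}
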