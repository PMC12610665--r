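#' Confusion matrix from label vectors
#'
#' `counts[a, p]` is the number of samples with actual class `a` predicted
#' as class `p`.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param label_set Ordered class names; every label must belong to it.
#' @return Integer matrix of class `confusion_matrix` with dimnames
#'   `(actual, predicted)`.
#' @export
confusion_matrix <- function(actual, predicted, label_set = NULL) {
  stopifnot(length(actual) == length(predicted))
  if (is.null(label_set)) label_set <- sort(unique(c(actual, predicted)))
  bad <- setdiff(unique(c(actual, predicted)), label_set)
  if (length(bad)) stop("labels outside label_set: ", paste(bad, collapse = ", "))
  cm <- table(factor(actual, label_set), factor(predicted, label_set))
  m <- matrix(as.integer(cm), length(label_set), length(label_set),
              dimnames = list(actual = label_set, predicted = label_set))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

safe_ratio <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0))
    warning("zero denominator in per-class ", what, "; reporting 0 for that class")
  out
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall, F1, and Cohen's kappa. Binary problems use
#' the declared positive class; multiclass problems compute one-vs-rest
#' per-class metrics and macro-average them (weighted averaging optional).
#' Kappa is `(po - pe) / (1 - pe)` with `po` the observed agreement and
#' `pe` the agreement expected from the marginals. Per-class recall (the
#' per-category accuracy of cross-validation summaries) is the diagonal
#' over the row sum. Zero-denominator per-class ratios are reported as 0
#' with a warning so degenerate folds never abort a cross-validation.
#'
#' @param cm A [confusion_matrix].
#' @param positive_class Positive class name (binary; default: the last
#'   label, conventionally the abnormal one).
#' @param averaging `"macro"` (default) or `"weighted"`.
#' @return An `eval_report` list: `accuracy`, `precision`, `recall`, `f1`,
#'   `kappa`, `per_class_precision`, `per_class_recall`, `per_class_f1`,
#'   `confusion`, plus `auc_roc` / `ap` slots filled by the caller when
#'   scores are available.
#' @export
classification_metrics <- function(cm, positive_class = NULL,
                                   averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(cm, "confusion_matrix"))
  labels <- rownames(cm)
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0

  tp <- diag(cm)
  prec_k <- safe_ratio(tp, colSums(cm), "precision")
  rec_k <- safe_ratio(tp, rowSums(cm), "recall")
  f1_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)

  if (length(labels) == 2L) {
    if (is.null(positive_class)) positive_class <- labels[length(labels)]
    i <- match(positive_class, labels)
    if (is.na(i)) stop("positive_class not in label set")
    precision <- prec_k[i]; recall <- rec_k[i]; f1 <- f1_k[i]
  } else {
    wts <- if (averaging == "macro") rep(1 / length(labels), length(labels))
           else rowSums(cm) / total
    precision <- sum(wts * prec_k); recall <- sum(wts * rec_k); f1 <- sum(wts * f1_k)
  }

  structure(list(accuracy = po, precision = unname(precision),
                 recall = unname(recall), f1 = unname(f1), kappa = kappa,
                 per_class_precision = stats::setNames(prec_k, labels),
                 per_class_recall = stats::setNames(rec_k, labels),
                 per_class_f1 = stats::setNames(f1_k, labels),
                 positive_class = if (length(labels) == 2L) positive_class,
                 averaging = averaging, n = total, confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d\naccuracy %.4f | precision %.4f | recall %.4f | f1 %.4f | kappa %.4f\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$kappa))
  if (!is.null(x$auc_roc)) cat(sprintf("auc_roc %.4f | ap/mAP %.4f\n", x$auc_roc, x$ap))
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' TPR/FPR are swept over all distinct score thresholds (ties grouped at a
#' single threshold) and the area is accumulated with the trapezoidal rule
#' `sum (FPR_{i+1} - FPR_i) * (TPR_{i+1} + TPR_i) / 2`.
#'
#' @param scores Positive-class probabilities in `[0, 1]`.
#' @param actual Actual labels.
#' @param positive_class Which label is positive (default: the label with
#'   the greater mean score would be ambiguous, so the last sorted label).
#' @return Numeric AUC in `[0, 1]`. `roc_points()` returns the swept
#'   `(fpr, tpr, threshold)` tibble.
#' @export
roc_auc <- function(scores, actual, positive_class = NULL) {
  pts <- roc_points(scores, actual, positive_class)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' @rdname roc_auc
#' @export
roc_points <- function(scores, actual, positive_class = NULL) {
  if (is.null(positive_class)) positive_class <- sort(unique(actual))[length(unique(actual))]
  pos <- actual == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: need both positive and negative samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))                  # tie group per distinct score
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)      # state after each tie group
  tibble::tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / n_pos),
    fpr = c(0, fp[last] / n_neg)
  )
}

#' Average precision (area under the precision-recall steps)
#'
#' `AP = sum_k P(k) * dR(k)`: precision at each recall increment, i.e. the
#' precision at every positive sample in the score-ranked list, weighted by
#' the recall step it contributes.
#'
#' @inheritParams roc_auc
#' @return Numeric AP in `[0, 1]`.
#' @export
average_precision <- function(scores, actual, positive_class = NULL) {
  if (is.null(positive_class)) positive_class <- sort(unique(actual))[length(unique(actual))]
  pos <- actual == positive_class
  n_pos <- sum(pos)
  if (n_pos == 0L) stop("AP undefined: no positive samples")
  ord <- order(scores, decreasing = TRUE)
  p <- pos[ord]
  precision_at_k <- cumsum(p) / seq_along(p)
  sum(precision_at_k[p]) / n_pos
}

#' Mean average precision over classes (one-vs-rest)
#'
#' @param score_matrix `N x n_classes` matrix of per-class probabilities
#'   with class names as column names.
#' @param actual Actual labels.
#' @return Unweighted mean of per-class APs.
#' @export
map_multiclass <- function(score_matrix, actual) {
  classes <- colnames(score_matrix)
  stopifnot(!is.null(classes))
  mean(vapply(classes, function(cl) {
    average_precision(score_matrix[, cl], ifelse(actual == cl, cl, "rest"),
                      positive_class = cl)
  }, numeric(1)))
}

#' Multiclass one-vs-rest macro AUC
#'
#' @inheritParams map_multiclass
#' @return Unweighted mean of per-class one-vs-rest AUCs.
#' @export
auc_multiclass <- function(score_matrix, actual) {
  classes <- colnames(score_matrix)
  stopifnot(!is.null(classes))
  mean(vapply(classes, function(cl) {
    roc_auc(score_matrix[, cl], ifelse(actual == cl, cl, "rest"),
            positive_class = cl)
  }, numeric(1)))
}

#' Full evaluation report from scores and labels
#'
#' Hard labels by argmax, confusion matrix, threshold metrics, and the
#' ranking metrics (AUC-ROC and AP, or their one-vs-rest means for
#' multiclass).
#'
#' @param score_matrix `N x n_classes` probability matrix with class-name
#'   columns.
#' @param actual Actual labels.
#' @param positive_class Binary positive class (default last column).
#' @param averaging Multiclass averaging for threshold metrics.
#' @return An `eval_report` with `auc_roc` and `ap` filled in.
#' @export
evaluate_scores <- function(score_matrix, actual, positive_class = NULL,
                            averaging = "macro") {
  classes <- colnames(score_matrix)
  predicted <- classes[max.col(score_matrix, ties.method = "first")]
  rep <- classification_metrics(confusion_matrix(actual, predicted, classes),
                                positive_class = positive_class,
                                averaging = averaging)
  if (length(classes) == 2L) {
    pc <- positive_class %||% classes[length(classes)]
    rep$auc_roc <- roc_auc(score_matrix[, pc], actual, pc)
    rep$ap <- average_precision(score_matrix[, pc], actual, pc)
  } else {
    rep$auc_roc <- auc_multiclass(score_matrix, actual)
    rep$ap <- map_multiclass(score_matrix, actual)
  }
  rep
}
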