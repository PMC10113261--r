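# Evaluation metrics and protocols: ROC/PR AUC, MCC, accuracy, precision,
# top-ranked recovery rate, and the channel confusion matrix.

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, with ties counted one half.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1) of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  npos <- sum(pos)
  nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L) {
    stop("ROC AUC undefined: only one class present")
  }
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Precision-recall area under the curve
#'
#' Trapezoidal integration over the precision-recall points obtained at
#' every distinct score threshold (descending), with the curve anchored at
#' recall 0 with the precision of the first point.
#'
#' @inheritParams roc_auc
#' @return PR AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0L || npos == length(labels)) {
    stop("PR AUC undefined: only one class present")
  }
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab)
  k <- seq_along(lab)
  last_of_thresh <- c(sc[-1] != sc[-length(sc)], TRUE)
  prec <- (tp / k)[last_of_thresh]
  rec <- (tp / npos)[last_of_thresh]
  rec0 <- c(0, rec)
  prec0 <- c(prec[1], prec)
  sum(diff(rec0) * (prec0[-1] + prec0[-length(prec0)]) / 2)
}

#' Matthews correlation coefficient
#'
#' Closed-form MCC from the confusion counts of binarized predictions; by
#' convention 0 when any denominator term vanishes.
#'
#' @param pred_binary binary predictions (0/1).
#' @param labels binary labels (0/1).
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(pred_binary, labels) {
  stopifnot(length(pred_binary) == length(labels))
  tp <- sum(pred_binary == 1 & labels == 1)
  tn <- sum(pred_binary == 0 & labels == 0)
  fp <- sum(pred_binary == 1 & labels == 0)
  fn <- sum(pred_binary == 0 & labels == 1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Accuracy and precision of binarized predictions
#'
#' Precision is 0 by convention when nothing is predicted positive.
#'
#' @inheritParams mcc_score
#' @return scalar.
#' @export
accuracy_score <- function(pred_binary, labels) {
  if (length(labels) == 0L) stop("empty input")
  mean(pred_binary == labels)
}

#' @rdname accuracy_score
#' @export
precision_score <- function(pred_binary, labels) {
  if (length(labels) == 0L) stop("empty input")
  np <- sum(pred_binary == 1)
  if (np == 0L) return(0)
  sum(pred_binary == 1 & labels == 1) / np
}

#' Per-structure metric report
#'
#' Computes ROC AUC, PR AUC, MCC, accuracy and precision (binarized at
#' `threshold`) for each structure and their medians.
#'
#' @param scores_list list of per-structure score vectors.
#' @param labels_list list of matching binary label vectors.
#' @param threshold binarization threshold (default 0.5).
#' @return data.frame with one row per structure; medians in attribute
#'   `"medians"`.
#' @export
metric_report <- function(scores_list, labels_list, threshold = 0.5) {
  stopifnot(length(scores_list) == length(labels_list))
  rows <- Map(function(s, y) {
    b <- as.integer(s > threshold)
    data.frame(roc_auc = roc_auc(s, y), pr_auc = pr_auc(s, y),
               mcc = mcc_score(b, y), accuracy = accuracy_score(b, y),
               precision = precision_score(b, y))
  }, scores_list, labels_list)
  out <- do.call(rbind, rows)
  attr(out, "medians") <- vapply(out, stats::median, 0)
  out
}

#' Interface recovery rate
#'
#' Ranks residues by score and asks whether the top fraction (10 percent by
#' default; `k = max(1, round(fraction * n))`, round half up) are all true
#' interface residues.  Ties at the k-th score are broken by ascending
#' residue index.
#'
#' @param scores per-residue scores.
#' @param labels per-residue binary interface truth.
#' @param fraction top fraction to consider (default 0.10).
#' @return list with `k`, `rate` (fraction of the top k that are true) and
#'   `recovered` (`rate == 1`).
#' @export
recovery_rate <- function(scores, labels, fraction = 0.10) {
  n <- length(scores)
  stopifnot(n >= 1L, length(labels) == n)
  k <- max(1L, as.integer(floor(fraction * n + 0.5)))
  top <- order(-scores, seq_len(n))[seq_len(k)]
  rate <- mean(labels[top] == 1)
  list(k = k, rate = rate, recovered = rate == 1)
}

#' Channel confusion matrix
#'
#' For residues with at least one true channel and a maximal predicted
#' confidence above `threshold`: rows are true channels, columns the argmax
#' predicted channel.  A residue with several true channels contributes one
#' count per true channel.
#'
#' @param pred residues x channels confidence matrix (or
#'   [prediction_result()]).
#' @param labels residues x channels binary matrix (or `interface_labels`).
#' @param threshold gating threshold on the maximal confidence.
#' @param normalize row-normalize to fractions.
#' @return channels x channels matrix.
#' @export
confusion_by_type <- function(pred, labels, threshold = 0.5,
                              normalize = FALSE) {
  if (inherits(pred, "prediction_result")) {
    pred <- as.matrix(as.data.frame(pred)[attr(pred, "channels")])
  }
  if (inherits(labels, "interface_labels")) labels <- labels$labels
  stopifnot(all(dim(pred) == dim(labels)))
  ch <- colnames(pred)
  if (is.null(ch)) ch <- colnames(labels)
  m <- matrix(0, ncol(pred), ncol(pred), dimnames = list(ch, ch))
  for (r in seq_len(nrow(pred))) {
    true_ch <- which(labels[r, ] == 1)
    if (length(true_ch) == 0L) next
    if (max(pred[r, ]) <= threshold) next
    pc <- which.max(pred[r, ])
    for (tc in true_ch) m[tc, pc] <- m[tc, pc] + 1
  }
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
  }
  m
}
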