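#' Area under the receiver operating characteristic curve
#'
#' The probability that a randomly chosen case (label 1) is scored above a
#' randomly chosen control (label 0), with ties counted one half
#' (midrank / Mann-Whitney estimator).
#'
#' @param labels Binary labels (0/1), both classes present.
#' @param scores Numeric scores, higher = more case-like.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) estimator: thresholds sweep the distinct
#' score values in decreasing order, and the area is the sum over
#' thresholds of precision times the recall increment.
#'
#' @param labels Binary labels (at least one case).
#' @param scores Numeric scores.
#' @return AUPRC in \[0, 1\]; equals prevalence for constant scores.
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("at least one case required")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # keep only the last index of each distinct score (threshold boundaries)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Matthews correlation coefficient at a fixed score cutoff
#'
#' Thresholds the scores at `cutoff` (predicted case iff score > cutoff)
#' and computes the Matthews correlation from the resulting 2x2 table.
#' Returns 0 when any marginal of the table is zero (degenerate table).
#'
#' @param labels Binary labels.
#' @param scores Numeric scores (probabilities).
#' @param cutoff Classification cutoff (default 0.5).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(labels, scores, cutoff = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > cutoff)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}
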