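#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (or coercible) positive indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: precision is evaluated at each distinct score
#' threshold and summed against the recall increments (no interpolation).
#' Tied scores enter as a single threshold step.
#'
#' @inheritParams auc_roc
#' @return AUC-PRC in `[0, 1]`.
#' @export
auc_prc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0 || sum(!labels) == 0) abort("Both classes must be present.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie block
  tp <- tp[last]
  fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' F1-optimal score threshold
#'
#' Scans the midpoints of all adjacent distinct score values; at each
#' threshold genes scoring at or above it are predicted positive, and the
#' threshold maximizing F1 = 2PR/(P+R) is returned (ties resolved to the
#' lowest threshold). F1 is defined as 0 when no positives are predicted.
#'
#' @param scores numeric scores.
#' @param labels logical positive indicator.
#' @return A list with `threshold` and `f1`.
#' @export
select_threshold_f1 <- function(scores, labels) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) {
    abort("Threshold selection needs both classes.")
  }
  u <- sort(unique(scores))
  if (length(u) < 2) {
    abort("All scores identical; no threshold separates anything.")
  }
  thresholds <- (u[-length(u)] + u[-1]) / 2
  f1 <- vapply(thresholds, function(t) f1_at(scores >= t, labels), 0)
  best <- which.max(f1)  # which.max takes the first, i.e. lowest threshold
  list(threshold = thresholds[best], f1 = f1[best])
}

f1_at <- function(pred, labels) {
  tp <- sum(pred & labels)
  if (tp == 0) return(0)
  precision <- tp / sum(pred)
  recall <- tp / sum(labels)
  2 * precision * recall / (precision + recall)
}
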