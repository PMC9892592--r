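#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the probability that
#' a random positive scores higher than a random negative, with ties counted
#' as 1/2 (midrank formula).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels.
#' @return AUC in [0, 1].
#' @export
kd_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_config("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grouped percentile bootstrap confidence interval for the AUC
#'
#' Resamples groups (subjects) with replacement `B` times, recomputing the
#' AUC on the concatenated rows of the drawn groups; resamples containing a
#' single class are discarded and redrawn. Returns the percentile interval.
#'
#' @param scores,labels as in [kd_auc()].
#' @param groups group (subject) id per row; rows of a group are kept
#'   together. Defaults to one group per row.
#' @param B number of bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `auc`, `low`, `high`, `B`.
#' @export
kd_bootstrap_auc_ci <- function(scores, labels, groups = seq_along(scores),
                                B = 1000L, conf = 0.95, seed = 1L) {
  if (B < 100L) stop_config("B must be at least 100")
  labels <- as.integer(labels)
  groups <- as.character(groups)
  ug <- unique(groups)
  cls_by_group <- vapply(split(labels, groups)[ug],
                         function(y) mean(y == 1L) > 0, logical(1))
  if (sum(cls_by_group) < 2L || sum(!cls_by_group) < 2L) {
    stop_config("need at least 2 groups per class for a grouped bootstrap")
  }
  idx_by_group <- split(seq_along(scores), groups)[ug]
  auc_hat <- kd_auc(scores, labels)
  with_seed(seed, {
    stat <- numeric(B)
    b <- 1L
    attempts <- 0L
    while (b <= B) {
      take <- sample.int(length(ug), replace = TRUE)
      idx <- unlist(idx_by_group[take], use.names = FALSE)
      y <- labels[idx]
      if (any(y == 1L) && any(y == 0L)) {
        stat[b] <- kd_auc(scores[idx], y)
        b <- b + 1L
      } else {
        attempts <- attempts + 1L
        if (attempts > 50L * B) stop_config("bootstrap cannot find two-class resamples")
      }
    }
    alpha <- (1 - conf) / 2
    q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE)
    list(auc = auc_hat, low = q[1], high = q[2], B = B)
  })
}

#' Sensitivity, specificity, accuracy and prevalence at a threshold
#'
#' Standard definitions from the 2x2 confusion table obtained by calling a
#' prediction positive when its probability reaches `threshold`.
#'
#' @param prob predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `prevalence`,
#'   and the counts `tp`, `fp`, `tn`, `fn`.
#' @export
kd_confusion_metrics <- function(prob, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  ok <- !is.na(prob) & !is.na(labels)
  prob <- prob[ok]; labels <- labels[ok]
  if (!length(prob)) stop_config("no predictions to evaluate")
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop_config("both classes must be present")
  }
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels),
       prevalence = mean(labels == 1L),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve points
#'
#' @param scores,labels as in [kd_auc()].
#' @return `data.table` of (`fpr`, `tpr`) sorted so both coordinates are
#'   non-decreasing.
#' @export
kd_roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop_config("both classes must be present")
  tpr <- cumsum(y == 1L) / n1
  fpr <- cumsum(y == 0L) / n0
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.table(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}
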