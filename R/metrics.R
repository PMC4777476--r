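#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (presence, absence) pairs in
#' which the presence cell scores strictly higher, with ties counted one
#' half. Equivalent to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (probability, favourability, or any monotone
#'   transform thereof).
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  if (anyNA(scores)) stop("missing scores")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity, specificity and correct classification rate at a threshold
#'
#' A cell is classified as a predicted presence when its score is greater
#' than or equal to the threshold (so a score exactly at the neutral
#' favourability value 0.5 counts as a predicted presence).
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels binary labels (0/1), both classes present.
#' @param threshold classification cut-off in \[0, 1\]; default 0.5, the
#'   neutral favourability value.
#' @return list with `sensitivity` (presences correctly classified),
#'   `specificity` (absences correctly classified) and `ccr` (all cells
#'   correctly classified).
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  list(sensitivity = tp / n1,
       specificity = tn / n0,
       ccr = (tp + tn) / length(labels))
}
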