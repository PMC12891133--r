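# Binary-classification evaluation: confusion counts and the eight-metric
# suite (SE, SP, ACC, MCC, P, F1, BA, AUC).

#' Confusion counts from true and predicted binary labels
#'
#' @param y_true,y_pred Vectors of 0/1 (or logical) labels, equal length.
#' @return List of class \code{confusion_counts}: TP, FP, TN, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    ls_stop("length_mismatch", "y_true (%d) and y_pred (%d) differ in length",
            length(y_true), length(y_pred))
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    ls_stop("non_binary", "labels must be binary 0/1")
  }
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0)
  ), class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with midranks for tied scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels aligned with scores.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    ls_stop("empty_class", "AUC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Compute the eight-metric report from confusion counts
#'
#' SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/n, P = TP/(TP+FP),
#' F1 = 2 P SE/(P+SE), BA = (SE+SP)/2, MCC by the standard product formula,
#' AUC by midrank statistic when scores are supplied. Ratios with a zero
#' denominator are reported as 0 (flagged in the \code{undefined} element);
#' MCC is 0 when any marginal is zero.
#'
#' @param counts A \code{\link{confusion_counts}} object.
#' @param scores Optional numeric scores (for AUC).
#' @param labels Optional binary labels aligned with \code{scores}.
#' @return List of class \code{metric_report} with elements SE, SP, ACC,
#'   MCC, P, F1, BA, AUC (NA if no scores), counts and undefined flags.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  if (n == 0) ls_stop("empty_input", "confusion counts sum to zero")
  undefined <- character(0)
  if (TP + FN == 0) undefined <- c(undefined, "SE")
  if (TN + FP == 0) undefined <- c(undefined, "SP")
  if (TP + FP == 0) undefined <- c(undefined, "P")
  SE <- safe_ratio(TP, TP + FN)
  SP <- safe_ratio(TN, TN + FP)
  ACC <- (TP + TN) / n
  P <- safe_ratio(TP, TP + FP)
  F1 <- safe_ratio(2 * P * SE, P + SE)
  BA <- (SE + SP) / 2
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (denom2 == 0) 0 else (TP * TN - FP * FN) / sqrt(denom2)
  AUC <- if (!is.null(scores)) auc_rank(scores, labels) else NA_real_
  structure(list(SE = SE, SP = SP, ACC = ACC, MCC = MCC, P = P, F1 = F1,
                 BA = BA, AUC = AUC, counts = counts, undefined = undefined),
            class = "metric_report")
}

metric_report_row <- function(report) {
  data.frame(SE = report$SE, SP = report$SP, ACC = report$ACC, MCC = report$MCC,
             P = report$P, F1 = report$F1, BA = report$BA, AUC = report$AUC,
             TP = report$counts$TP, FP = report$counts$FP,
             TN = report$counts$TN, FN = report$counts$FN)
}
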