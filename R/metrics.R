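#' Confusion-table classification metrics
#'
#' Accuracy, sensitivity and specificity from predicted vs true binary
#' labels: `acc = (TP + TN) / n`, `sen = TP / (TP + FN)`,
#' `spe = TN / (TN + FP)`. An undefined ratio (no positives, or no
#' negatives, among the true labels) is returned as `NA` with a warning,
#' never silently as 0.
#'
#' @param yTrue,yPred equal-length vectors of binary class labels.
#' @param positive the label counted as positive (sensitivity numerator).
#' @return named numeric vector `c(acc, sen, spe)`.
#' @export
confusionMetrics <- function(yTrue, yPred, positive) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  n <- length(yTrue)
  if (n < 1L || length(yPred) != n)
    stop("yTrue and yPred must be equal-length, nonempty", call. = FALSE)
  isPos <- yTrue == positive
  tp <- sum(isPos & yPred == positive)
  fn <- sum(isPos & yPred != positive)
  tn <- sum(!isPos & yPred != positive)
  fp <- sum(!isPos & yPred == positive)
  sen <- if (tp + fn == 0) {
    warning("no positive samples: sensitivity undefined"); NA_real_
  } else tp / (tp + fn)
  spe <- if (tn + fp == 0) {
    warning("no negative samples: specificity undefined"); NA_real_
  } else tn / (tn + fp)
  c(acc = (tp + tn) / n, sen = sen, spe = spe)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted as 1/2.
#'
#' @param yTrue binary class labels.
#' @param scores classifier scores, larger = more positive-like.
#' @param positive the positive label.
#' @return AUC in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
aucScore <- function(yTrue, scores, positive) {
  yTrue <- as.character(yTrue)
  if (length(scores) != length(yTrue))
    stop("scores and labels must be equal length", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  isPos <- yTrue == positive
  np <- sum(isPos); nn <- sum(!isPos)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)                  # midranks handle ties as 1/2
  (sum(r[isPos]) - np * (np + 1) / 2) / (np * nn)
}

#' Paired t-test on per-repeat accuracies
#'
#' Two-sided paired t-test on the per-repeat accuracy differences of two
#' methods evaluated with identical fold assignments. Zero-variance
#' differences are handled by convention: p = 1 when the mean difference is
#' 0 (no difference), otherwise p = 0 (below machine precision) with
#' attribute `zeroVariance = TRUE` and a warning, rather than a fabricated
#' finite number.
#'
#' @param accA,accB equal-length (>= 2) accuracy vectors paired by repeat.
#' @return the p-value.
#' @export
pairedAccuracyTTest <- function(accA, accB) {
  if (length(accA) != length(accB) || length(accA) < 2L)
    stop("need two equal-length vectors of >= 2 paired accuracies",
         call. = FALSE)
  d <- accA - accB
  if (sd(d) == 0) {
    if (mean(d) == 0) return(1)
    warning("zero-variance nonzero differences: p below machine precision")
    return(structure(0, zeroVariance = TRUE))
  }
  t.test(accA, accB, paired = TRUE)$p.value
}
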