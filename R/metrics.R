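#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes, \eqn{\frac{1}{N}\sum_i (p_i - y_i)^2}: a strictly proper
#' scoring rule, robust to predicted probabilities of exactly 0 or 1, and
#' the primary comparison metric between models here. Over constant
#' predictors it is minimized at `p = prevalence` with minimum
#' `prevalence * (1 - prevalence)`.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels in `{0, 1}`, same length.
#' @return Brier score in `[0, 1]`; smaller is better.
#' @examples
#' brier(c(0.8, 0.4, 0.1), c(1, 0, 0))  # 0.07
#' @export
brier <- function(probs, labels) {
  check_scored(probs, labels)
  mean((probs - labels)^2)
}

#' ROC-AUC (Mann-Whitney rank statistic)
#'
#' The probability that a randomly chosen positive case is scored above a
#' randomly chosen negative case, with ties counted one half — the rank-sum
#' formulation of the area under the ROC curve. Requires both classes.
#'
#' @inheritParams brier
#' @return AUC in `[0, 1]`; 0.5 is chance level.
#' @examples
#' roc_auc(c(0.9, 0.7, 0.7, 0.2), c(1, 1, 0, 0))  # 0.875
#' @export
roc_auc <- function(probs, labels) {
  check_scored(probs, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("ROC-AUC is undefined when only one class is present")
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a probability threshold
#'
#' Fraction of cases where `probs >= threshold` matches the label; ties at
#' the threshold classify as positive.
#'
#' @inheritParams brier
#' @param threshold Classification threshold (default 0.5).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(probs, labels, threshold = 0.5) {
  check_scored(probs, labels)
  mean(as.integer(probs >= threshold) == labels)
}

check_scored <- function(probs, labels) {
  if (length(probs) < 1L || length(probs) != length(labels))
    stop("probs and labels must be non-empty and of equal length")
  if (anyNA(probs) || anyNA(labels))
    stop("probs and labels must not contain missing values")
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  invisible(TRUE)
}
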