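# ROC/AUC machinery: Mann-Whitney AUC, DeLong confidence intervals, Youden
# cut-off, diagnostic metrics.

check_two_class <- function(labels) {
  y <- as_binary_outcome(labels)
  if (length(unique(y)) < 2)
    abort("both outcome classes must be present", class = "raprout_domain_error")
  y
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance probability (ties counted 1/2),
#' computed from midranks; the curve contains one (FPR, TPR) point per unique
#' threshold under the rule "score >= threshold predicts positive".
#'
#' @param scores Numeric scores; higher scores favour the positive class.
#' @param labels Binary labels (0/1, logical, or dRL factor).
#'
#' @return A list of class `rap_roc` with `auc`, `n_pos`, `n_neg` and
#'   `curve` (tibble `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
roc_auc <- function(scores, labels) {
  y <- check_two_class(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) mean(scores[y == 1] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[y == 0] >= th), numeric(1))
  curve <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr))
  structure(list(auc = auc, n_pos = n1, n_neg = n0, curve = curve),
            class = "rap_roc")
}

#' @export
print.rap_roc <- function(x, ...) {
  cat(sprintf("<rap_roc> AUC = %.4f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.rap_roc <- function(x, ...) x$curve

#' @export
glance.rap_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' DeLong confidence interval and test for the AUC
#'
#' Nonparametric (DeLong) variance of the Mann-Whitney AUC from the
#' placement values of each class, normal-approximation confidence interval
#' truncated to \[0, 1\], and a two-sided test against AUC = 0.5.
#'
#' @param scores,labels As in [roc_auc()].
#' @param level Confidence level.
#'
#' @return A one-row tibble: `auc`, `ci_low`, `ci_high`, `se`, `p_value`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  y <- check_two_class(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (min(n1, n0) < 10)
    warn("fewer than 10 observations in one class; interval will be wide")
  xs <- scores[y == 1]; ys <- scores[y == 0]
  # placement values: V10_i = P(score_neg < x_i) + .5 P(=), per positive i
  v10 <- vapply(xs, function(v) (sum(ys < v) + 0.5 * sum(ys == v)) / n0,
                numeric(1))
  v01 <- vapply(ys, function(v) (sum(xs > v) + 0.5 * sum(xs == v)) / n1,
                numeric(1))
  auc <- mean(v10)
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  se <- sqrt(s10 / n1 + s01 / n0)
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  tibble::tibble(auc = auc, ci_low = ci[1], ci_high = ci[2], se = se,
                 p_value = p)
}

#' Youden-index optimal cut-off
#'
#' Maximises sensitivity + specificity - 1 over the observed thresholds for
#' the rule "score >= cut-off predicts positive".  Ties are broken toward the
#' higher sensitivity, then the lower threshold.
#'
#' @param scores,labels As in [roc_auc()].
#'
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity` (%),
#'   `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- check_two_class(labels)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(th) mean(scores[y == 1] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(scores[y == 0] < th), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[order(-sens[best], thr[best])][1]
  tibble::tibble(cutoff = thr[best], sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best], youden = j[best])
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive values (in
#' percent) from the four confusion-matrix counts.  Fields with a zero
#' denominator are returned as `NA` with a flag.
#'
#' @param tp,fn,fp,tn Nonnegative counts.
#' @return A one-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percent), `flag`.
#' @examples
#' confusion_metrics(34, 4, 14, 18)
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0))
    abort("counts must be nonnegative", class = "raprout_domain_error")
  if (tp + fn + fp + tn == 0)
    abort("all-zero confusion matrix", class = "raprout_domain_error")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- tibble::tibble(sensitivity = rate(tp, tp + fn),
                        specificity = rate(tn, tn + fp),
                        ppv = rate(tp, tp + fp),
                        npv = rate(tn, tn + fn))
  out$flag <- if (anyNA(out[1, ])) "zero_denominator" else NA_character_
  out
}

#' Predictive values from rates and prevalence
#'
#' Bayes' identity linking sensitivity, specificity and prevalence to the
#' positive and negative predictive values:
#' \deqn{PPV = \frac{se \cdot \pi}{se \cdot \pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp (1-\pi)}{sp (1-\pi) + (1-se) \pi}}
#'
#' @param sens,spec,prevalence Proportions in (0, 1) ranges.
#' @return A one-row tibble: `ppv`, `npv` (proportions), `flag`.
#' @examples
#' metrics_from_rates(0.8947, 0.5625, 38 / 70)
#' @export
metrics_from_rates <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence >= 0, prevalence <= 1)
  den_p <- sens * prevalence + (1 - spec) * (1 - prevalence)
  den_n <- spec * (1 - prevalence) + (1 - sens) * prevalence
  tibble::tibble(ppv = if (den_p > 0) sens * prevalence / den_p else NA_real_,
                 npv = if (den_n > 0) spec * (1 - prevalence) / den_n else NA_real_,
                 flag = if (den_p == 0 || den_n == 0) "degenerate_denominator"
                        else NA_character_)
}
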