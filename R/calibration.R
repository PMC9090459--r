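# Calibration (Hosmer-Lemeshow) and distribution-adaptive correlation.

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into `g` risk strata by quantiles of the predicted
#' probability (boundary ties go to the lower group), then computes
#' \deqn{H = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / n_g)}}
#' with \eqn{O_g} observed events, \eqn{E_g} expected events and
#' \eqn{n_g} the group size, referred to a chi-square with `g - 2` degrees of
#' freedom.  Groups emptied by tie collapse are merged with their neighbour
#' and the degrees of freedom reduced (flagged).
#'
#' @param predicted_probs Predicted event probabilities.
#' @param labels Binary outcomes.
#' @param g Number of risk groups (default 10; requires `n >= 2 g`).
#'
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `groups`, `flag`.
#' @export
hosmer_lemeshow <- function(predicted_probs, labels, g = 10) {
  y <- as_binary_outcome(labels)
  n <- length(y)
  stopifnot(length(predicted_probs) == n)
  if (n < 2 * g)
    abort("need n >= 2 g observations", class = "raprout_data_error")
  qs <- unique(quantile(predicted_probs, probs = seq_len(g - 1) / g, type = 7))
  grp <- cut(predicted_probs, breaks = c(-Inf, qs, Inf), labels = FALSE,
             right = TRUE)   # boundary ties fall into the lower group
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(grp = grp, y = y, p = predicted_probs), grp),
    n = dplyr::n(), o = sum(.data$y), e = sum(.data$p), .groups = "drop")
  collapsed <- nrow(tab) < g
  terms <- (tab$o - tab$e)^2 / (tab$e * (1 - tab$e / tab$n))
  stat <- sum(terms)
  df <- nrow(tab) - 2
  if (df < 1)
    abort("too few risk groups after tie collapse", class = "raprout_data_error")
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 groups = nrow(tab),
                 flag = if (collapsed) "groups_merged" else NA_character_)
}

#' Distribution-adaptive correlation
#'
#' Pearson correlation when both variables pass a Shapiro-Wilk normality
#' check (p >= 0.05 each), Spearman rank correlation otherwise; the choice is
#' reported.  For n > 5000 the Shapiro-Wilk check uses evenly spaced order
#' statistics (the test is defined for at most 5000 observations).
#'
#' @param x,y Paired numeric vectors (>= 5 complete pairs).
#' @return A one-row tibble: `estimate`, `p_value`, `method`.
#' @export
correlate <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5)
    abort("need at least 5 complete pairs", class = "raprout_data_error")
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    abort("zero variance", class = "raprout_domain_error")
  swp <- function(v) {
    if (length(v) > 5000)
      v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
    if (length(unique(v)) < 3) return(0)  # degenerate: force Spearman
    shapiro.test(v)$p.value
  }
  normal <- swp(x) >= 0.05 && swp(y) >= 0.05
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 method = method)
}
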