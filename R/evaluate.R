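# The five predictive model specifications and their evaluation.

#' The five predictive model specifications
#'
#' Named predictor sets for the models compared in the analysis: Rout alone,
#' each relative RAPmax decline alone, both declines together, and the total
#' index (both declines plus Rout).
#'
#' @return A named list mapping model name to predictor columns.
#' @export
model_specs <- function() {
  list(rout_only = "rout",
       drap1 = "drap1max_pct",
       drap2 = "drap2max_pct",
       drap1_plus_drap2 = c("drap1max_pct", "drap2max_pct"),
       total_index = c("drap1max_pct", "drap2max_pct", "rout"))
}

#' Evaluate the predictive models on a cohort
#'
#' For each model specification: single predictors are scored by the raw
#' predictor value (monotone-equivalent to the univariate logistic
#' probability, so the AUC is identical and the cut-off is reported in
#' predictor units); multivariate models are scored by the fitted logistic
#' probability.  Each model gets the Mann-Whitney AUC with DeLong confidence
#' interval and test against 0.5, the Youden-index cut-off with sensitivity
#' and specificity, predictive values at that cut-off, and the
#' Hosmer-Lemeshow calibration test on the fitted probabilities.
#'
#' @param cohort Cohort data frame (needs `rout`, `drap1max_pct`,
#'   `drap2max_pct` and either a binary `drl` column or `mrs`).
#' @param specs Model list as from [model_specs()].
#' @param hl_groups Hosmer-Lemeshow risk groups.
#' @param conf_level Confidence level for the AUC interval.
#'
#' @return A tibble of class `shunt_model_eval`, one row per model in
#'   specification order: `model`, `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `p_value`, `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `hl_stat`, `hl_p`, plus list-columns `coefficients` and `roc`.
#'   Failed models yield a row with `NA` values and the failure in `note`.
#' @export
evaluate_models <- function(cohort, specs = model_specs(), hl_groups = 10,
                            conf_level = 0.95) {
  if (!"drl" %in% names(cohort)) {
    if (!"mrs" %in% names(cohort))
      abort("cohort needs a `drl` or `mrs` column", class = "raprout_data_error")
    cohort$drl <- dichotomize_mrs(cohort$mrs)
  }
  y <- as_binary_outcome(cohort$drl)

  rows <- purrr::imap(specs, function(preds, name) {
    tryCatch({
      keep <- complete.cases(cohort[, preds, drop = FALSE])
      dat <- cohort[keep, , drop = FALSE]
      yk <- y[keep]
      fitobj <- fit_logistic(dat, "drl", preds)
      score <- if (length(preds) == 1) dat[[preds]] else fitobj$fitted
      roc <- roc_auc(score, yk)
      ci <- auc_ci(score, yk, level = conf_level)
      yd <- youden_cutoff(score, yk)
      pred_pos <- score >= yd$cutoff
      cm <- confusion_metrics(tp = sum(pred_pos & yk == 1),
                              fn = sum(!pred_pos & yk == 1),
                              fp = sum(pred_pos & yk == 0),
                              tn = sum(!pred_pos & yk == 0))
      hl <- hosmer_lemeshow(fitobj$fitted, yk, g = hl_groups)
      tibble::tibble(model = name, auc = roc$auc,
                     auc_ci_low = ci$ci_low, auc_ci_high = ci$ci_high,
                     p_value = ci$p_value,
                     cutoff = yd$cutoff,
                     sensitivity = cm$sensitivity, specificity = cm$specificity,
                     ppv = cm$ppv, npv = cm$npv,
                     hl_stat = hl$statistic, hl_p = hl$p_value,
                     n = length(yk), note = NA_character_,
                     coefficients = list(tidy(fitobj)),
                     roc = list(roc$curve))
    }, error = function(e) {
      tibble::tibble(model = name, auc = NA_real_, auc_ci_low = NA_real_,
                     auc_ci_high = NA_real_, p_value = NA_real_,
                     cutoff = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                     hl_stat = NA_real_, hl_p = NA_real_, n = NA_integer_,
                     note = conditionMessage(e),
                     coefficients = list(NULL), roc = list(NULL))
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shunt_model_eval", class(out))
  out
}

#' Evaluate a single predictor against an outcome direction
#'
#' Scores the raw predictor for either outcome direction (`"dRL"`: higher
#' values predict a desirable recovery; `"non_dRL"`: higher values predict a
#' poor recovery, as used for the segment RAPmax predictors).
#'
#' @param cohort Cohort data frame with `mrs` or `drl`.
#' @param predictor Predictor column name.
#' @param direction `"dRL"` or `"non_dRL"`.
#' @param conf_level Confidence level.
#' @return A one-row tibble: AUC with CI/p, Youden cut-off, sensitivity,
#'   specificity, ppv, npv.
#' @export
evaluate_predictor <- function(cohort, predictor,
                               direction = c("dRL", "non_dRL"),
                               conf_level = 0.95) {
  direction <- match.arg(direction)
  if (!"drl" %in% names(cohort)) cohort$drl <- dichotomize_mrs(cohort$mrs)
  y <- as_binary_outcome(cohort$drl)
  if (direction == "non_dRL") y <- 1L - y
  score <- cohort[[predictor]]
  keep <- complete.cases(score)
  score <- score[keep]; y <- y[keep]
  ci <- auc_ci(score, y, level = conf_level)
  yd <- youden_cutoff(score, y)
  pred_pos <- score >= yd$cutoff
  cm <- confusion_metrics(sum(pred_pos & y == 1), sum(!pred_pos & y == 1),
                          sum(pred_pos & y == 0), sum(!pred_pos & y == 0))
  dplyr::bind_cols(tibble::tibble(predictor = predictor, direction = direction),
                   ci, yd[, c("cutoff", "sensitivity", "specificity")],
                   cm[, c("ppv", "npv")])
}

#' @export
print.shunt_model_eval <- function(x, ...) {
  cat("<shunt_model_eval> predictive models for desirable recovery (dRL)\n")
  cols <- c("model", "auc", "auc_ci_low", "auc_ci_high", "sensitivity",
            "specificity", "hl_p")
  print(tibble::as_tibble(x)[, cols])
  invisible(x)
}

#' @export
tidy.shunt_model_eval <- function(x, ...) {
  tibble::as_tibble(tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "model", "coefficients"),
    "coefficients"))
}

#' @export
glance.shunt_model_eval <- function(x, ...) {
  tibble::as_tibble(x)[, c("model", "auc", "auc_ci_low", "auc_ci_high",
                           "p_value", "hl_stat", "hl_p", "n")]
}
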