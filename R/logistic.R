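# Logistic regression by IRLS, with the internals (deviance trace,
# separation flag) exposed; cross-checked against stats::glm in the tests.

#' Dichotomise the modified Rankin Scale
#'
#' mRS 0-2 is the desirable recovery level (dRL), mRS 3-6 is non-dRL.
#'
#' @param mrs Integer vector with values in 0-6.
#' @return A factor with levels `non_dRL`, `dRL`.
#' @examples
#' dichotomize_mrs(c(0, 2, 3, 6))
#' @export
dichotomize_mrs <- function(mrs) {
  if (any(is.na(mrs)) || any(mrs < 0 | mrs > 6) || any(mrs != round(mrs)))
    abort("`mrs` must contain integers in 0..6", class = "raprout_domain_error")
  factor(ifelse(mrs <= 2, "dRL", "non_dRL"), levels = c("non_dRL", "dRL"))
}

as_binary_outcome <- function(y) {
  if (is.factor(y)) {
    if (!"dRL" %in% levels(y)) return(as.integer(y) - 1L)
    return(as.integer(y == "dRL"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (all(y %in% c(0, 1))) return(as.integer(y))
  abort("outcome must be binary (0/1, logical, or dRL factor)",
        class = "raprout_domain_error")
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an explicit IRLS loop: convergence
#' when the largest coefficient step falls below `tol` (default 1e-8) or
#' after `max_iter` iterations.  Complete separation is detected (fitted
#' probabilities pinned at 0/1 with perfect classification) and reported as a
#' warning, with the coefficients returned as-is.  A rank-deficient design is
#' an error.
#'
#' @param data A data frame.
#' @param outcome Column name of the binary outcome (0/1, logical, or the
#'   `dRL` factor from [dichotomize_mrs()]).
#' @param predictors Character vector of predictor column names.
#' @param tol,max_iter IRLS stopping rule.
#'
#' @return An object of class `rap_logit`: coefficients, standard errors,
#'   covariance, fitted probabilities, deviance trace, convergence and
#'   separation flags.
#' @export
fit_logistic <- function(data, outcome, predictors,
                         tol = 1e-8, max_iter = 100) {
  keep <- complete.cases(data[, c(outcome, predictors), drop = FALSE])
  if (!all(keep))
    inform(sprintf("listwise deletion: dropped %d of %d rows with missing values",
                   sum(!keep), length(keep)))
  data <- data[keep, , drop = FALSE]
  y <- as_binary_outcome(data[[outcome]])
  n <- length(y)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  if (qr(X)$rank < ncol(X))
    abort("singular design matrix", class = "raprout_singular_error")

  beta <- rep(0, ncol(X))
  dev_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (it in seq_len(max_iter)) {
    iter <- it
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    dev <- -2 * sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
    dev_trace <- c(dev_trace, dev)
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(XtWX), error = function(e) matrix(NA, ncol(X), ncol(X)))
  se <- sqrt(diag(vcov))
  names(se) <- colnames(X)

  pinned <- p < 1e-8 | p > 1 - 1e-8
  separation <- all(pinned) && all((p > 0.5) == (y == 1))
  if (separation)
    warn("complete separation detected; coefficients are unbounded",
         class = "raprout_separation_warning")

  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 se = se, vcov = vcov, fitted = p, y = y,
                 deviance = tail(dev_trace, 1), deviance_trace = dev_trace,
                 converged = converged, iter = iter,
                 separation = separation, n = n,
                 outcome = outcome, predictors = predictors),
            class = "rap_logit")
}

#' @export
print.rap_logit <- function(x, ...) {
  cat(sprintf("<rap_logit> %s ~ %s  (n = %d, %d IRLS iterations%s)\n",
              x$outcome, paste(x$predictors, collapse = " + "), x$n, x$iter,
              if (x$separation) ", SEPARATION" else ""))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.rap_logit <- function(x, ...) {
  est <- x$coefficients
  z <- est / x$se
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(x$se), statistic = unname(z),
                 p.value = 2 * pnorm(-abs(unname(z))))
}

#' @export
glance.rap_logit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, AIC = x$deviance + 2 * length(x$coefficients),
                 nobs = x$n, iter = x$iter, converged = x$converged,
                 separation = x$separation)
}

#' Univariate predictor screen
#'
#' Fits one single-covariate logistic model per candidate predictor and
#' retains those with a Wald p-value below `alpha` (default 0.10, the
#' conventional relaxed threshold for entry into a multivariate model).
#' Zero-variance predictors are excluded with a flag.  A warning is issued
#' when either outcome arm has fewer than 10 events.
#'
#' @param data Cohort data frame.
#' @param predictors Character vector of candidate predictor columns.
#' @param outcome Outcome column (default `"drl"`; created from `mrs` via
#'   [dichotomize_mrs()] when absent).
#' @param alpha Retention threshold on the Wald p-value.
#'
#' @return A tibble: `predictor`, `estimate`, `p_value`, `retained`, `flag`.
#' @export
univariate_screen <- function(data, predictors, outcome = "drl", alpha = 0.10) {
  if (!outcome %in% names(data)) {
    if (!"mrs" %in% names(data))
      abort("need an outcome column or `mrs`", class = "raprout_data_error")
    data[[outcome]] <- dichotomize_mrs(data$mrs)
  }
  y <- as_binary_outcome(data[[outcome]])
  if (min(table(y)) < 10)
    warn("fewer than 10 events in one outcome arm; screen is underpowered")
  rows <- purrr::map(predictors, function(v) {
    x <- data[[v]]
    if (sd(x, na.rm = TRUE) < 1e-12)
      return(tibble::tibble(predictor = v, estimate = NA_real_,
                            p_value = NA_real_, retained = FALSE,
                            flag = "zero_variance"))
    f <- fit_logistic(data, outcome, v)
    td <- tidy(f)
    tibble::tibble(predictor = v, estimate = td$estimate[2],
                   p_value = td$p.value[2],
                   retained = td$p.value[2] < alpha, flag = NA_character_)
  })
  dplyr::bind_rows(rows)
}
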