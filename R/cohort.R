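# Synthetic pre-shunting cohort generator.

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF sampling; exact for the truncated normal
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic pre-shunting cohort
#'
#' Draws `n` patients with the statistical structure the prognosis analysis
#' assumes: Rout from a truncated normal on \[6, 25\] mmHg·min/ml, a latent
#' reserve-recovery fraction \eqn{\rho} from a Beta distribution, baseline
#' RAPmax correlated with Rout, relative RAPmax declines after drainage days 1
#' and 2 driven by \eqn{\rho} plus independent noise, and a dichotomised
#' modified-Rankin outcome drawn from the logistic model
#' \eqn{P(dRL) = logit^{-1}(\beta_0 + \beta_1 \Delta RAP1max\% + \beta_2
#' \Delta RAP2max\% + \beta_3 Rout)}.  Demographic covariates (age, GCS
#' severity, decompressive-craniectomy history, injury-to-test interval, shunt
#' type, baseline ICP, follow-up time) are sampled from the reported
#' validation-set marginals and are prognostically inert.
#'
#' In `mode = "fast"` the RAP summary parameters are sampled directly (no
#' waveforms), which is what cohort-scale experiments use.  In
#' `mode = "waveform"` each patient's infusion test and 48-h drainage are
#' actually simulated (time-compressed) and pushed through the full signal
#' pipeline; this is slow and intended for small-n end-to-end checks.
#'
#' @param config A [cohort_sim_config()].
#' @param mode `"fast"` or `"waveform"`.
#' @param sim_config Base [sim_config()] used per patient in waveform mode.
#' @param compress Time-compression factor for waveform mode.
#'
#' @return A tibble of class `rap_cohort` with one `PatientRecord` row per
#'   patient; the generative ground truth (rho, true Rout, generative dRL
#'   probability) is attached as attribute `ground_truth` and accessible via
#'   [cohort_truth()].
#' @examples
#' coh <- generate_cohort(cohort_sim_config(n = 50, seed = 1))
#' nrow(coh)
#' @export
generate_cohort <- function(config, mode = c("fast", "waveform"),
                            sim_config = NULL, compress = 60) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n

  rout <- rtruncnorm1(n, config$rout_mean, config$rout_sd,
                      config$rout_range[1], config$rout_range[2])
  rho <- stats::rbeta(n, config$rho_shape1, config$rho_shape2)

  # baseline RAPmax correlated with Rout (higher resistance, poorer reserve)
  r <- config$rout_rapb_cor
  z <- rnorm(n)
  rap1max <- config$rap1max_mean +
    config$rap1max_sd * (r * (rout - config$rout_mean) / config$rout_sd +
                           sqrt(max(0, 1 - r^2)) * z)
  rap1max <- pmin(pmax(rap1max, 0.2), 0.99)

  rho_mean <- config$rho_shape1 / (config$rho_shape1 + config$rho_shape2)

  if (mode == "fast") {
    drap1 <- config$drap1_mean / rho_mean * rho + rnorm(n, 0, config$drap1_noise_sd)
    drap2 <- config$drap2_mean / rho_mean * rho + rnorm(n, 0, config$drap2_noise_sd)
    drap1 <- pmin(drap1, 98); drap2 <- pmin(drap2, 98)
    rap2max <- pmax(rap1max * (1 - drap1 / 100), 0.01)
    rap3max <- pmax(rap1max * (1 - drap2 / 100), 0.01)
    # declines recomputed from the stored maxima so the invariant
    # drap = 100 (rap1max - rapKmax)/rap1max holds exactly after clipping
    drap1 <- 100 * (rap1max - rap2max) / rap1max
    drap2 <- 100 * (rap1max - rap3max) / rap1max
    rout_est <- rout
  } else {
    base_cfg <- if (is.null(sim_config)) sim_config() else sim_config
    res <- purrr::map(seq_len(n), function(i) {
      cfg <- base_cfg
      cfg$seed <- NULL
      cfg$r_out <- rout[i]
      cfg$p_bp <- cfg$p0 + rout[i] * cfg$i_f - 1.5  # reserve exhausted at baseline
      inf_rec <- simulate_infusion_test(cfg, rout_terminate = Inf)
      inf <- analyze_infusion(inf_rec)
      dra <- simulate_drainage(cfg, rho = rho[i], compress = compress,
                               patient_id = sprintf("P%03d", i))
      win <- window_stats(dra, window_s = 10)
      rap <- compute_rap(win, span_n = 40)
      smry <- summarize_drainage(rap, rec_events(dra), dra)
      list(rout_est = inf$rout, smry = smry)
    })
    smry <- dplyr::bind_rows(purrr::map(res, "smry"))
    rout_est <- purrr::map_dbl(res, "rout_est")
    rap1max <- smry$rap1max; rap2max <- smry$rap2max; rap3max <- smry$rap3max
    drap1 <- smry$drap1max_pct; drap2 <- smry$drap2max_pct
  }

  b <- config$beta
  p_drl <- plogis(b[1] + b[2] * drap1 + b[3] * drap2 + b[4] * rout_est)
  drl <- rbinom(n, 1, p_drl)
  mrs <- ifelse(drl == 1,
                sample(0:2, n, replace = TRUE, prob = c(0.20, 0.45, 0.35)),
                sample(3:6, n, replace = TRUE, prob = c(0.50, 0.25, 0.15, 0.10)))

  cohort <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = round(rtruncnorm1(n, 48.5, 6.9, 16, 72)),
    gcs_severe = rbinom(n, 1, 0.343),
    dc_history = rbinom(n, 1, 0.157),
    interval_tbi_weeks = round(rtruncnorm1(n, 7.4, 2.8, 2, 18), 1),
    shunt_type = sample(c("VP", "LP"), n, replace = TRUE, prob = c(0.729, 0.271)),
    icp_b_mmhg = round(rtruncnorm1(n, 11.3, 3.3, 4, 14.9), 1),
    rout = rout_est,
    rap_b = rap1max,
    rap_dra = pmin(pmax(0.57 + 0.5 * (rap1max - 0.70) + rnorm(n, 0, 0.10), 0.05), 0.99),
    rap1max = rap1max, rap2max = rap2max, rap3max = rap3max,
    drap1max_pct = drap1, drap2max_pct = drap2,
    mrs = as.integer(mrs),
    followup_months = sample(c(3L, 4L, 5L), n, replace = TRUE,
                             prob = c(0.843, 0.086, 0.071)))

  truth <- tibble::tibble(patient_id = cohort$patient_id,
                          rho = rho, rout_true = rout, p_drl = p_drl)
  attr(cohort, "ground_truth") <- truth
  class(cohort) <- c("rap_cohort", class(cohort))
  cohort
}

#' @rdname generate_cohort
#' @param cohort A cohort generated by [generate_cohort()].
#' @export
cohort_truth <- function(cohort) attr(cohort, "ground_truth")
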