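#' Configuration for the CSF dynamics simulator
#'
#' Parameters of the Marmarou-type pressure-volume model used to synthesise
#' intracranial pressure (ICP) recordings.  The slow (compensatory) compartment
#' obeys
#' \deqn{dP/dt = E (P - P_0) [I_{ext}(t) + I_f - (P - P_0)/R_{out}]}
#' whose steady state under constant external flow is
#' \eqn{P_0 + R_{out} (I_f + I_{ext})}.  On top of the slow trajectory the
#' simulator adds a cardiac pulse of amplitude
#' \eqn{a(P) = a_0 + k_{amp} \max(P - P_{bp}, 0)}, a respiratory sinusoid,
#' slow ("B-wave") modulation implemented as a bounded random walk on the CSF
#' formation rate, and Gaussian measurement noise.
#'
#' Defaults are literature-typical values chosen so that the baseline ICP
#' (\eqn{P_0 + R_{out} I_f \approx 9.6} mmHg) satisfies the usual inclusion
#' criterion of baseline ICP below 15 mmHg.
#'
#' @param r_out Resistance to CSF outflow, mmHg·min/ml (> 0).
#' @param e_coef Cerebral elastance coefficient, 1/ml (> 0).
#' @param p0 Reference pressure of the pressure-volume curve, mmHg.
#' @param i_f CSF formation rate, ml/min (> 0).
#' @param f_cardiac Heart rate, Hz (0.67-3, i.e. 40-180 bpm).
#' @param f_resp Respiratory rate, Hz.
#' @param a0 Floor pulse amplitude below the breakpoint, mmHg (>= 0).
#' @param k_amp Slope of pulse amplitude vs mean ICP above the breakpoint.
#' @param p_bp Breakpoint pressure of the amplitude law, mmHg.
#' @param slow_wave_amp Amplitude of slow-wave ICP modulation, mmHg (>= 0).
#' @param slow_tau_s Time scale over which the slow-wave random walk explores
#'   its bounds, s.
#' @param resp_amp Amplitude of the respiratory pressure component, mmHg.
#' @param noise_sd Gaussian measurement noise SD, mmHg (>= 0).
#' @param fs Sampling rate, Hz (>= 20).
#' @param seed Optional RNG seed; identical seed implies bit-identical output.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(r_out = 13, noise_sd = 0, slow_wave_amp = 0)
#' cfg$r_out
#' @export
sim_config <- function(r_out = 13, e_coef = 0.11, p0 = 5, i_f = 0.35,
                       f_cardiac = 1.2, f_resp = 0.25,
                       a0 = 1, k_amp = 0.5, p_bp = 8,
                       slow_wave_amp = 0.5, slow_tau_s = 60, resp_amp = 0.2,
                       noise_sd = 0.2, fs = 100, seed = NULL) {
  cfg <- list(r_out = r_out, e_coef = e_coef, p0 = p0, i_f = i_f,
              f_cardiac = f_cardiac, f_resp = f_resp,
              a0 = a0, k_amp = k_amp, p_bp = p_bp,
              slow_wave_amp = slow_wave_amp, slow_tau_s = slow_tau_s,
              resp_amp = resp_amp, noise_sd = noise_sd, fs = fs, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$r_out), is.numeric(cfg$e_coef), is.numeric(cfg$fs))
  if (cfg$r_out <= 0) abort("`r_out` must be > 0", class = "raprout_config_error")
  if (cfg$e_coef <= 0) abort("`e_coef` must be > 0", class = "raprout_config_error")
  if (cfg$i_f <= 0) abort("`i_f` must be > 0", class = "raprout_config_error")
  if (cfg$fs < 20) abort("`fs` must be >= 20 Hz", class = "raprout_config_error")
  if (cfg$f_cardiac < 0.67 || cfg$f_cardiac > 3)
    abort("`f_cardiac` must lie in [0.67, 3] Hz", class = "raprout_config_error")
  if (cfg$a0 < 0) abort("`a0` must be >= 0", class = "raprout_config_error")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0", class = "raprout_config_error")
  if (cfg$slow_wave_amp < 0) abort("`slow_wave_amp` must be >= 0", class = "raprout_config_error")
  invisible(cfg)
}

#' Protocol for a simulated recording
#'
#' An ordered set of phases, each with a label, a duration in minutes and an
#' external flow: positive for saline infusion into the CSF space, negative
#' for drainage.  Defaults follow the clinical protocols: constant-rate
#' infusion at 1.5 ml/min and lumbar drainage at 10-15 ml/h (0.167-0.25
#' ml/min).
#'
#' @param label Character vector of phase labels, each one of
#'   `"baseline"`, `"infusion"`, `"drainage"`, `"rest"`.
#' @param duration_min Phase durations in minutes (> 0).
#' @param i_ext_ml_min External flow per phase, ml/min.
#'
#' @return A tibble of class `sim_protocol` with one row per phase.
#' @examples
#' protocol(c("baseline", "infusion"), c(10, 20), c(0, 1.5))
#' @export
protocol <- function(label, duration_min, i_ext_ml_min) {
  stopifnot(length(label) == length(duration_min),
            length(label) == length(i_ext_ml_min))
  if (length(label) == 0)
    abort("protocol must contain at least one phase", class = "raprout_config_error")
  ok <- label %in% c("baseline", "infusion", "drainage", "rest")
  if (!all(ok))
    abort(paste0("unknown phase label(s): ", paste(label[!ok], collapse = ", ")),
          class = "raprout_config_error")
  if (any(duration_min <= 0))
    abort("phase durations must be > 0", class = "raprout_config_error")
  if (any(label == "infusion" & i_ext_ml_min <= 0))
    abort("infusion phases need positive external flow", class = "raprout_config_error")
  drn <- label == "drainage"
  if (any(drn & (i_ext_ml_min < -0.25 | i_ext_ml_min > -0.167)))
    abort("drainage flow must lie in [-0.25, -0.167] ml/min (10-15 ml/h)",
          class = "raprout_config_error")
  structure(tibble::tibble(label = label, duration_min = duration_min,
                           i_ext_ml_min = i_ext_ml_min),
            class = c("sim_protocol", class(tibble::tibble())))
}

#' Configuration for the synthetic cohort generator
#'
#' Describes the statistical structure of a simulated pre-shunting cohort:
#' per-patient outflow resistance Rout (truncated normal on \[6, 25\]
#' mmHg·min/ml), a latent reserve-recovery fraction \eqn{\rho \in [0, 1]}
#' (Beta-distributed; its shape parameters are the skew knobs for the joint
#' distribution of the drainage-response quantities), marginal targets for the
#' RAP summaries, and logistic outcome-model coefficients linking the
#' probability of a desirable recovery level (dRL, modified Rankin Scale 0-2)
#' to the relative RAPmax declines and Rout:
#' \deqn{P(dRL) = logit^{-1}(\beta_0 + \beta_1 \Delta RAP1max\% +
#'   \beta_2 \Delta RAP2max\% + \beta_3 Rout)}
#'
#' Marginal defaults emulate the reported validation-set characteristics
#' (RAP1max 0.70 +/- 0.14, Rout 13.7 +/- 4.1 mmHg·min/ml, mean relative
#' declines ~40\% after day 1 and day 2, dRL prevalence ~54\%).
#'
#' @param n Cohort size (>= 1).
#' @param rout_mean,rout_sd,rout_range Truncated-normal parameters for Rout.
#' @param rho_shape1,rho_shape2 Beta shape parameters of the latent
#'   reserve-recovery fraction.
#' @param rap1max_mean,rap1max_sd Marginal target for baseline RAPmax.
#' @param drap1_mean,drap2_mean Target mean relative RAPmax decline (%) after
#'   day 1 and day 2 of drainage.
#' @param drap1_noise_sd,drap2_noise_sd Independent noise SDs (%) added to the
#'   rho-driven declines.
#' @param rout_rapb_cor Correlation between Rout and baseline RAP.
#' @param beta Outcome-model coefficients
#'   `c(intercept, drap1max_pct, drap2max_pct, rout)`.  The default intercept
#'   places the dRL prevalence near 54\% at the marginal means.
#' @param seed Optional RNG seed.
#'
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n,
                              rout_mean = 13.7, rout_sd = 4.1,
                              rout_range = c(6, 25),
                              rho_shape1 = 2, rho_shape2 = 2,
                              rap1max_mean = 0.70, rap1max_sd = 0.14,
                              drap1_mean = 40.2, drap2_mean = 40.4,
                              drap1_noise_sd = 8, drap2_noise_sd = 12,
                              rout_rapb_cor = 0.40,
                              beta = NULL, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    abort("`n` must be a single integer >= 1", class = "raprout_config_error")
  if (rout_sd <= 0 || rap1max_sd <= 0)
    abort("scale parameters must be > 0", class = "raprout_config_error")
  if (rho_shape1 <= 0 || rho_shape2 <= 0)
    abort("Beta shape parameters must be > 0", class = "raprout_config_error")
  if (length(rout_range) != 2 || diff(rout_range) <= 0)
    abort("`rout_range` must be an increasing pair", class = "raprout_config_error")
  if (drap1_noise_sd < 0 || drap2_noise_sd < 0)
    abort("noise SDs must be >= 0", class = "raprout_config_error")
  if (is.null(beta)) {
    b <- c(NA, 0.05, 0.05, 0.15)
    b[1] <- qlogis(0.544) -
      (b[2] * drap1_mean + b[3] * drap2_mean + b[4] * rout_mean)
    beta <- b
  }
  if (length(beta) != 4)
    abort("`beta` must have 4 coefficients (intercept, drap1, drap2, rout)",
          class = "raprout_config_error")
  structure(list(n = as.integer(n), rout_mean = rout_mean, rout_sd = rout_sd,
                 rout_range = rout_range,
                 rho_shape1 = rho_shape1, rho_shape2 = rho_shape2,
                 rap1max_mean = rap1max_mean, rap1max_sd = rap1max_sd,
                 drap1_mean = drap1_mean, drap2_mean = drap2_mean,
                 drap1_noise_sd = drap1_noise_sd, drap2_noise_sd = drap2_noise_sd,
                 rout_rapb_cor = rout_rapb_cor, beta = beta, seed = seed),
            class = "cohort_sim_config")
}
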