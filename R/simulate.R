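# Marmarou-type CSF dynamics simulator: slow compartment integrated in C++
# (RK4, one step per sample), cardiac/respiratory/noise components added
# additively on the slow trajectory so ground-truth steady states stay
# closed-form: P_ss = p0 + r_out * (i_f + i_ext).

# One slow-compartment segment under a per-sample external-flow vector.
# Consumes the ambient RNG stream (no seeding here) so protocols can be
# simulated phase-by-phase deterministically under one seed.
# The ODE right-hand side carries per-minute units (flows in ml/min, R in
# mmHg.min/ml) while dt is in seconds, hence the 1/60 conversion on the ODE
# rate; the slow-wave random walk lives on the simulated-seconds clock
# (compressed along with the protocol, not unit-converted).
sim_segment <- function(cfg, iext, p_init, islow_init, rate_mult = 1) {
  dt <- min(0.1, 1 / cfg$fs)
  # The compliance ODE low-passes the formation-rate walk at
  # tau = 60 / (rate_mult * E * I_f) simulated seconds; the walk bound is
  # inflated by the first-order attenuation factor so that the resulting
  # pressure excursions stay at the documented slow_wave_amp scale.
  tau_ode <- 60 / (rate_mult * cfg$e_coef * cfg$i_f)
  gain_comp <- sqrt(1 + tau_ode / cfg$slow_tau_s)
  islow_bound <- cfg$slow_wave_amp / cfg$r_out * gain_comp
  sigma_step <- if (islow_bound > 0)
    islow_bound * sqrt(dt * rate_mult / cfg$slow_tau_s) else 0
  .sim_slow_core(length(iext), p_init, islow_init, iext, dt,
                 cfg$e_coef, cfg$p0, cfg$r_out, cfg$i_f,
                 islow_bound, sigma_step, rate_mult / 60)
}

# Assemble the measured pressure from a slow trajectory: cardiac pulse with
# the amplitude law a(P) = a0 + k_amp * max(P - p_bp, 0), respiratory
# sinusoid, Gaussian noise.  `t` is global time so phase is continuous.
assemble_pressure <- function(cfg, t, p_slow) {
  amp <- cfg$a0 + cfg$k_amp * pmax(p_slow - cfg$p_bp, 0)
  p <- p_slow +
    amp * sin(2 * pi * cfg$f_cardiac * t) +
    cfg$resp_amp * sin(2 * pi * cfg$f_resp * t)
  if (cfg$noise_sd > 0) p <- p + rnorm(length(t), 0, cfg$noise_sd)
  p
}

#' Simulate an ICP recording under a phase protocol
#'
#' Integrates the slow-compartment pressure-volume ODE with fixed-step RK4
#' (step `min(0.1, 1/fs)` s) across the protocol phases and superimposes the
#' cardiac pulse, respiratory sinusoid, slow-wave modulation and measurement
#' noise described in [sim_config()].  Event annotations are emitted at every
#' phase boundary.  With `noise_sd = 0` and `slow_wave_amp = 0` the phase-end
#' pressure converges to the ODE steady state
#' \eqn{p_0 + r_{out} (i_f + i_{ext})}; identical seeds give bit-identical
#' recordings.
#'
#' @param config A [sim_config()].
#' @param protocol A [protocol()] (tibble of phases).
#' @param rate_mult Time-dilation factor applied to the slow dynamics
#'   (compressed-time mode); cardiac/respiratory components are unaffected.
#' @param patient_id Identifier stored on the recording.
#'
#' @return An [icp_recording()].  If drainage drove the slow pressure to the
#'   reference pressure floor, the flow was clamped there and the recording
#'   carries attribute `clamped = TRUE` (with a warning).
#' @examples
#' cfg <- sim_config(noise_sd = 0, slow_wave_amp = 0, fs = 20)
#' rec <- simulate_pressure(cfg, protocol("baseline", 2, 0))
#' mean(tail(rec$icp_mmhg, 100))
#' @export
simulate_pressure <- function(config, protocol, rate_mult = 1,
                              patient_id = "sim") {
  validate_sim_config(config)
  if (!inherits(protocol, "sim_protocol"))
    protocol <- protocol(protocol$label, protocol$duration_min,
                         protocol$i_ext_ml_min)
  if (!is.null(config$seed)) set.seed(config$seed)

  fs <- config$fs
  n_phase <- round(protocol$duration_min * 60 * fs)
  iext <- rep(protocol$i_ext_ml_min, n_phase)
  p_init <- config$p0 + config$r_out * (config$i_f + protocol$i_ext_ml_min[1])
  if (p_init <= config$p0)
    abort(paste0("divergent integration: initial steady pressure ",
                 signif(p_init, 4), " mmHg does not exceed the reference ",
                 "pressure p0 = ", config$p0,
                 " (first-phase net inflow must be positive)"),
          class = "raprout_sim_error")

  seg <- sim_segment(config, iext, p_init, 0, rate_mult)
  n <- length(iext)
  t <- seq_len(n) / fs
  p <- assemble_pressure(config, t, seg$p)

  bounds <- cumsum(c(0, protocol$duration_min * 60))
  ev_lab <- dplyr::case_when(
    protocol$label == "baseline" ~ "baseline_start",
    protocol$label == "infusion" ~ "infusion_start",
    protocol$label == "drainage" ~ "drainage_start",
    TRUE ~ NA_character_)
  events <- tibble::tibble(time_s = pmax(bounds[-length(bounds)], t[1]),
                           label = ev_lab)
  inf_idx <- which(protocol$label == "infusion")
  if (length(inf_idx) > 0)
    events <- dplyr::bind_rows(events,
      tibble::tibble(time_s = pmin(bounds[inf_idx + 1], t[n]),
                     label = "infusion_stop"))
  events <- events[!is.na(events$label), ]
  events <- events[order(events$time_s), ]

  clamped <- seg$n_clamped > 0
  if (clamped)
    warn("drainage drove pressure to the reference-pressure floor; flow clamped",
         class = "raprout_clamp_warning")
  icp_recording(t, p, fs, events = events, patient_id = patient_id,
                clamped = clamped, time_compress = rate_mult,
                ground_truth = list(r_out = config$r_out, e_coef = config$e_coef,
                                    p0 = config$p0, i_f = config$i_f))
}

#' Simulate a constant-rate CSF infusion test
#'
#' Emulates the clinical protocol: a baseline recording of at least 10 min, a
#' constant-rate saline infusion (default 1.5 ml/min), and a 10-min
#' post-plateau segment.  The infusion terminates when the running two-point
#' Rout estimate exceeds `rout_terminate` (clinical safety rule, default 18
#' mmHg·min/ml), when a steady plateau has been reached (minute-mean slope
#' below `plateau_slope` for `plateau_sustain_min` consecutive minutes; the
#' infusion then continues for a further `post_plateau_min` minutes), or at
#' `max_infusion_min`.
#'
#' @param config A [sim_config()].
#' @param i_inf Infusion rate, ml/min.
#' @param baseline_min Baseline duration, minutes (>= 10 clinically).
#' @param max_infusion_min Maximum infusion duration, minutes.
#' @param post_plateau_min Recording continued after the plateau, minutes.
#' @param rout_terminate Safety termination threshold on the running Rout,
#'   mmHg·min/ml; set `Inf` to disable (e.g. for ground-truth recovery
#'   studies across high resistances).
#' @param plateau_slope,plateau_sustain_min The simulator's "steady-state
#'   plateau approached" rule on the 1-min means of the slow pressure.  The
#'   default slope (0.02 mmHg/min) is deliberately stricter than the
#'   analyser's plateau-detection threshold so that noise-free recordings end
#'   on a converged plateau; with slow waves enabled the rule rarely fires
#'   and recordings simply run to `max_infusion_min` (reason
#'   `"max_duration"`), which also leaves a long converged plateau.
#' @param patient_id Identifier.
#'
#' @return An [icp_recording()] with events `baseline_start`,
#'   `infusion_start`, `infusion_stop` and attribute `termination_reason` in
#'   `"plateau_reached"`, `"rout_exceeds_18"`, `"max_duration"`.
#' @export
simulate_infusion_test <- function(config, i_inf = 1.5, baseline_min = 15,
                                   max_infusion_min = 45, post_plateau_min = 10,
                                   rout_terminate = 18, plateau_slope = 0.02,
                                   plateau_sustain_min = 5,
                                   patient_id = "sim") {
  validate_sim_config(config)
  stopifnot(i_inf > 0, baseline_min > 0, max_infusion_min >= 5)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs
  spm <- round(60 * fs)                       # samples per minute

  p_init <- config$p0 + config$r_out * config$i_f
  if (p_init <= config$p0)
    abort("divergent integration: baseline steady pressure at or below p0",
          class = "raprout_sim_error")

  # baseline
  seg <- sim_segment(config, rep(0, spm * baseline_min), p_init, 0)
  p_slow <- seg$p
  pb_slow <- mean(tail(seg$p, spm))

  # infusion, minute by minute, applying the termination rules on the slow
  # minute means (the simulator's protocol logic; the analyser sees only the
  # assembled noisy signal)
  minute_means <- numeric(0)
  reason <- "max_duration"
  stable_run <- 0
  state_p <- seg$p_final; state_i <- seg$islow_final
  mins_inf <- 0
  for (m in seq_len(max_infusion_min)) {
    seg <- sim_segment(config, rep(i_inf, spm), state_p, state_i)
    p_slow <- c(p_slow, seg$p)
    state_p <- seg$p_final; state_i <- seg$islow_final
    mins_inf <- m
    mm <- mean(seg$p)
    minute_means <- c(minute_means, mm)
    # safety rule applied once the infusion is established (>= 5 min)
    if (m >= 5 && (mm - pb_slow) / i_inf > rout_terminate) {
      reason <- "rout_exceeds_18"; break
    }
    if (m >= 2 && abs(mm - minute_means[m - 1]) < plateau_slope)
      stable_run <- stable_run + 1 else stable_run <- 0
    if (stable_run >= plateau_sustain_min) { reason <- "plateau_reached"; break }
  }

  post_min <- 0
  if (reason == "plateau_reached" && post_plateau_min > 0) {
    # recording (and infusion) continued for a further 10 min after plateau
    seg <- sim_segment(config, rep(i_inf, spm * post_plateau_min),
                       state_p, state_i)
    p_slow <- c(p_slow, seg$p)
    state_p <- seg$p_final; state_i <- seg$islow_final
    mins_inf <- mins_inf + post_plateau_min
  } else if (reason == "rout_exceeds_18" && post_plateau_min > 0) {
    # infusion aborted; pressure left to settle
    seg <- sim_segment(config, rep(0, spm * post_plateau_min),
                       state_p, state_i)
    p_slow <- c(p_slow, seg$p)
    post_min <- post_plateau_min
  }

  n <- length(p_slow)
  t <- seq_len(n) / fs
  p <- assemble_pressure(config, t, p_slow)
  t_inf <- baseline_min * 60
  t_stop <- (baseline_min + mins_inf) * 60
  events <- tibble::tibble(
    time_s = c(t[1], t_inf, min(t_stop, t[n])),
    label = c("baseline_start", "infusion_start", "infusion_stop"))
  icp_recording(t, p, fs, events = events, patient_id = patient_id,
                termination_reason = reason, i_inf = i_inf,
                ground_truth = list(
                  r_out = config$r_out, e_coef = config$e_coef,
                  p0 = config$p0, i_f = config$i_f,
                  pb_true = config$p0 + config$r_out * config$i_f,
                  pp_true = config$p0 + config$r_out * (config$i_f + i_inf)))
}

#' Simulate a continuous lumbar drainage recording
#'
#' Produces a 48-hour (configurably time-compressed) ICP recording with a
#' pre-drainage baseline and two drainage days, annotated with
#' `drainage_start`, `day1_end` and `day2_end` events.  The latent
#' reserve-recovery fraction `rho` scales a downward drift of the slow
#' operating point: with `rho = 1` the pressure settles below the pulse
#' amplitude breakpoint (AMP flat, so the compensatory reserve index RAP falls
#' toward 0), with `rho = 0` it stays at baseline above the breakpoint (RAP
#' stays high).  The drift ramps in over `ramp_h` hours after drainage onset.
#'
#' Time compression (`compress`) dilates the slow dynamics by the same factor
#' so that a 48-h protocol maps exactly onto `48/compress` hours of simulated
#' samples; cardiac and respiratory components keep physiological frequencies
#' so the spectral AMP pipeline is unchanged.
#'
#' @param config A [sim_config()].
#' @param rho Reserve-recovery fraction in \[0, 1\].
#' @param baseline_h,day_h Pre-drainage and per-day durations, protocol hours.
#' @param drain_rate_ml_h Nominal drainage rate for volume bookkeeping, ml/h
#'   (10-15 clinically).
#' @param ramp_h Ramp-in time of the drainage effect, protocol hours.
#' @param below_margin How far below the breakpoint the operating point is
#'   pulled at `rho = 1`, mmHg; defaults to `slow_wave_amp + 1` so slow waves
#'   stay below the breakpoint.
#' @param compress Time-compression factor (1 = real time).
#' @param patient_id Identifier.
#'
#' @return An [icp_recording()] with attributes `ground_truth` (including
#'   `rho`), `time_compress` and `drain_rate_ml_h`.
#' @export
simulate_drainage <- function(config, rho, baseline_h = 6, day_h = 24,
                              drain_rate_ml_h = 12.5, ramp_h = 2,
                              below_margin = NULL, compress = 30,
                              patient_id = "sim") {
  validate_sim_config(config)
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1)
    abort("`rho` must be a single value in [0, 1]", class = "raprout_config_error")
  if (drain_rate_ml_h < 10 || drain_rate_ml_h > 15)
    abort("`drain_rate_ml_h` must lie in [10, 15]", class = "raprout_config_error")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(below_margin)) below_margin <- config$slow_wave_amp + 1

  fs <- config$fs
  pb <- config$p0 + config$r_out * config$i_f
  if (pb <= config$p0)
    abort("divergent integration: baseline steady pressure at or below p0",
          class = "raprout_sim_error")
  # target operating point: rho-scaled drift from baseline to below breakpoint
  p_target <- pb - rho * (pb - (config$p_bp - below_margin))
  p_target <- max(p_target, config$p0 + 0.2)
  i_eff_full <- (p_target - pb) / config$r_out   # effective decompression flow

  sim_s <- function(h) round(h * 3600 / compress * fs) / fs
  t_base <- sim_s(baseline_h); t_day <- sim_s(day_h); t_ramp <- sim_s(ramp_h)
  n_base <- round(t_base * fs); n_day <- round(t_day * fs)
  n <- n_base + 2 * n_day
  t <- seq_len(n) / fs
  t_drain <- t_base
  ramp <- pmin(pmax((t - t_drain) / max(t_ramp, 1 / fs), 0), 1)
  iext <- i_eff_full * ramp

  seg <- sim_segment(config, iext, pb, 0, rate_mult = compress)
  p <- assemble_pressure(config, t, seg$p)

  events <- tibble::tibble(
    time_s = c(t[1], t_drain, t_drain + t_day, t_drain + 2 * t_day),
    label = c("baseline_start", "drainage_start", "day1_end", "day2_end"))
  events$time_s <- pmin(events$time_s, t[n])

  clamped <- seg$n_clamped > 0
  if (clamped)
    warn("drainage drove pressure to the reference-pressure floor; flow clamped",
         class = "raprout_clamp_warning")
  icp_recording(t, p, fs, events = events, patient_id = patient_id,
                clamped = clamped, time_compress = compress,
                drain_rate_ml_h = drain_rate_ml_h,
                ground_truth = list(r_out = config$r_out, rho = rho,
                                    pb_true = pb, p_target = p_target))
}
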