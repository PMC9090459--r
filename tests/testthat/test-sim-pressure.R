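# Pressure simulator: steady states, determinism, integrator accuracy,
# amplitude law, termination rules.

test_that("noise-free phase-end pressures converge to the closed-form steady states", {
  cfg <- quiet_cfg()
  rec <- simulate_pressure(cfg, protocol(c("baseline", "infusion"),
                                         c(10, 65), c(0, 1.5)))
  last_min <- function(t_hi) {
    mean(rec$icp_mmhg[rec$time_s > t_hi - 60 & rec$time_s <= t_hi])
  }
  expect_equal(last_min(600), 5 + 13 * 0.35, tolerance = 1e-3 / 9.55)  # 9.55
  expect_equal(last_min(75 * 60), 5 + 13 * 1.85, tolerance = 1e-3 / 29.05) # 29.05

  # steady-state identity across admissible configs (property)
  for (r_out in c(6, 18)) for (i_ext in c(1.0, 1.5)) {
    cfg2 <- quiet_cfg(r_out = r_out)
    rec2 <- simulate_pressure(cfg2, protocol(c("baseline", "infusion"),
                                             c(5, 80), c(0, i_ext)))
    target <- 5 + r_out * (0.35 + i_ext)
    tail_mean <- mean(tail(rec2$icp_mmhg, 20 * 60))
    expect_lt(abs(tail_mean - target), 1e-3)
  }
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- sim_config(seed = 42, fs = 20)
  r1 <- simulate_pressure(cfg, protocol("baseline", 2, 0))
  r2 <- simulate_pressure(cfg, protocol("baseline", 2, 0))
  expect_identical(r1$icp_mmhg, r2$icp_mmhg)

  d1 <- simulate_drainage(sim_config(seed = 7, fs = 20), rho = 0.5, compress = 60)
  d2 <- simulate_drainage(sim_config(seed = 7, fs = 20), rho = 0.5, compress = 60)
  expect_identical(d1$icp_mmhg, d2$icp_mmhg)
})

test_that("RK4 trajectory agrees with the step-halved trajectory (step-halving oracle)", {
  # same ODE integrated at dt and dt/2; compare at the coarse sample times
  core <- getFromNamespace(".sim_slow_core", "raprout")
  n <- 20 * 600                       # 10 min at 20 Hz
  iext <- rep(1.5, n)
  a <- core(n, 9.55, 0, iext, 1 / 20, 0.11, 5, 13, 0.35, 0, 0, 1)
  b <- core(2 * n, 9.55, 0, rep(1.5, 2 * n), 1 / 40, 0.11, 5, 13, 0.35, 0, 0, 1)
  expect_lt(max(abs(a$p - b$p[seq(2, 2 * n, by = 2)])), 1e-6)
})

test_that("plateau pressure increases with r_out and infusion rate (noise-free)", {
  plateau <- function(r_out, i_inf) {
    cfg <- quiet_cfg(r_out = r_out)
    rec <- simulate_pressure(cfg, protocol(c("baseline", "infusion"),
                                           c(2, 30), c(0, i_inf)))
    mean(tail(rec$icp_mmhg, 20 * 60))
  }
  p1 <- plateau(8, 1.5); p2 <- plateau(13, 1.5); p3 <- plateau(18, 1.5)
  expect_true(p1 < p2 && p2 < p3)
  q1 <- plateau(13, 1.0); q2 <- plateau(13, 2.0)
  expect_true(q1 < p2 && p2 < q2)
})

test_that("measured pulse amplitude follows a0 + k_amp * max(P - P_bp, 0) within 2%", {
  # static operating points across the pressure range (the law's regime)
  for (r in c(8, 13, 16)) {
    cfg <- sim_config(noise_sd = 0, slow_wave_amp = 0, fs = 20, r_out = r)
    w <- window_stats(simulate_pressure(cfg, protocol("baseline", 10, 0)), 10)
    law <- cfg$a0 + cfg$k_amp * pmax(w$mean_icp - cfg$p_bp, 0)
    expect_lt(max(abs(w$amp - law) / law), 0.02)
  }
  # with slow-wave modulation the within-window drift adds a little smearing
  cfg <- sim_config(noise_sd = 0, fs = 20, seed = 3)
  w <- window_stats(simulate_pressure(cfg, protocol("baseline", 30, 0)), 10)
  above <- w$valid & (w$mean_icp - cfg$slow_wave_amp > cfg$p_bp)
  expect_gt(sum(above), 50)
  law <- cfg$a0 + cfg$k_amp * pmax(w$mean_icp[above] - cfg$p_bp, 0)
  expect_lt(max(abs(w$amp[above] - law) / law), 0.02)
})

test_that("degenerate protocols are rejected and drainage clamping is flagged", {
  # no net inflow at start -> divergent integration rejected
  cfg <- quiet_cfg(i_f = 0.1)
  expect_error(simulate_pressure(cfg, protocol("drainage", 10, -0.2)),
               class = "raprout_sim_error")
  # P = P0 is an equilibrium of the model, so drainage approaches the floor
  # asymptotically without crossing it
  rec <- suppressWarnings(
    simulate_drainage(sim_config(noise_sd = 0, slow_wave_amp = 3, fs = 20,
                                 seed = 8),
                      rho = 1, below_margin = 6, compress = 60))
  expect_false(attr(rec, "clamped"))
  expect_true(all(rec$icp_mmhg > 5 - 3 - 1))  # bounded by floor minus pulse/resp
  # the integrator-level floor guard: a huge step with strong outflow
  # overshoots the reference pressure and is clamped and counted
  core <- getFromNamespace(".sim_slow_core", "raprout")
  res <- core(50, 5.5, 0, rep(-1, 50), 600, 0.11, 5, 13, 0.35, 0, 0, 1 / 60)
  expect_gt(res$n_clamped, 0)
  expect_true(all(res$p >= 5))
})

test_that("infusion test emits protocol segments, events and termination reasons", {
  cfg <- quiet_cfg(r_out = 10)
  it <- simulate_infusion_test(cfg, baseline_min = 10, rout_terminate = Inf)
  ev <- rec_events(it)
  expect_equal(ev$label[1:2], c("baseline_start", "infusion_start"))
  expect_equal(ev$time_s[ev$label == "infusion_start"], 600)  # 10-min baseline
  expect_equal(attr(it, "termination_reason"), "plateau_reached")
  # two-point estimate on the noise-free recording recovers the truth
  res <- analyze_infusion(it)
  expect_lt(abs(res$rout - 10), 0.05)

  it25 <- simulate_infusion_test(quiet_cfg(r_out = 25))
  expect_equal(attr(it25, "termination_reason"), "rout_exceeds_18")

  # too-short maximum duration with the safety rule off -> max_duration
  itmax <- simulate_infusion_test(quiet_cfg(r_out = 13), max_infusion_min = 6,
                                  rout_terminate = Inf)
  expect_equal(attr(itmax, "termination_reason"), "max_duration")
})
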