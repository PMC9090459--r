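# Drainage summaries: segmentation, segment maxima, relative declines.

drain_events <- function(t0 = 0, t_dr = 6 * 3600, t_d1 = 30 * 3600,
                         t_d2 = 54 * 3600) {
  tibble::tibble(time_s = c(t0, t_dr, t_d1, t_d2),
                 label = c("baseline_start", "drainage_start",
                           "day1_end", "day2_end"))
}

test_that("segment_rap splits on events into disjoint covering segments", {
  t <- seq(0, 54 * 3600, by = 600)
  s <- make_rap_series(t, runif(length(t), 0.3, 0.9))
  seg <- segment_rap(s, drain_events())
  expect_setequal(unique(seg$segment), c("baseline", "day1", "day2"))
  expect_equal(range(seg$t_mid[seg$segment == "baseline"])[2] < 6 * 3600, TRUE)
  # disjoint and covering: every valid in-span point lands in exactly one segment
  expect_equal(nrow(seg), sum(s$t_mid < 54 * 3600))
  expect_false(any(duplicated(seg$t_mid)))

  # series ending before day 2 -> day2 flagged empty
  s26 <- make_rap_series(t[t < 26 * 3600], 0.5)
  expect_warning(seg26 <- segment_rap(s26, drain_events()),
                 class = "raprout_empty_segment_warning")
  expect_equal(attr(seg26, "empty_segments"), "day2")

  # missing events -> protocol error
  expect_error(segment_rap(s, tibble::tibble(time_s = 0, label = "baseline_start")),
               class = "raprout_protocol_error")
  # invalid points are excluded
  sv <- make_rap_series(t, 0.5, valid = c(TRUE, FALSE))
  segv <- segment_rap(sv, drain_events())
  expect_equal(nrow(segv), sum(sv$valid & sv$t_mid < 54 * 3600))
})

test_that("rap_max applies the 5-point median smoothing contract", {
  x <- make_rap_series(1:7, c(0.5, 0.5, 0.99, 0.5, 0.5, 0.6, 0.6))
  expect_equal(rap_max(x), 0.6)                    # spike suppressed
  expect_equal(rap_max(x, smooth = FALSE), 0.99)   # raw maximum retained
  expect_equal(rap_max(make_rap_series(1:6, rep(0.7, 6))), 0.7)
  expect_error(rap_max(make_rap_series(1:4, rep(0.5, 4))),
               class = "raprout_insufficient_data_error")
})

test_that("delta_rap_max_pct implements the relative-decline formula", {
  expect_equal(delta_rap_max_pct(0.80, 0.44), 45)      # the reported cut-off scale
  expect_equal(delta_rap_max_pct(0.63, 0.63), 0)
  expect_equal(delta_rap_max_pct(0.70, 0.57), 100 * (0.70 - 0.57) / 0.70)
  expect_lt(delta_rap_max_pct(0.5, 0.6), 0)            # interim above baseline
  expect_error(delta_rap_max_pct(0, 0.3), class = "raprout_domain_error")
})

test_that("summarize_drainage reduces the cohort-table maxima consistently", {
  # Table-2-style maxima embedded in a synthetic series
  t <- seq(0, 54 * 3600, by = 600)
  rap <- ifelse(t < 6 * 3600, 0.55 + 0.15 * sin(t / 5e3),
         ifelse(t < 30 * 3600, 0.45 + 0.12 * sin(t / 7e3), 0.22 + 0.12 * sin(t / 6e3)))
  s <- make_rap_series(t, rap)
  sm <- summarize_drainage(s, drain_events(), smooth = FALSE)
  expect_equal(sm$drap1max_pct,
               100 * (sm$rap1max - sm$rap2max) / sm$rap1max, tolerance = 1e-9)
  expect_equal(sm$drap2max_pct,
               100 * (sm$rap1max - sm$rap3max) / sm$rap1max, tolerance = 1e-9)
  # the declines for maxima (0.70, 0.57, 0.34)
  expect_equal(delta_rap_max_pct(0.70, 0.57), 18.571, tolerance = 1e-4)
  expect_equal(delta_rap_max_pct(0.70, 0.34), 51.429, tolerance = 1e-4)
  # bookkeeping: 12.5 ml/h for 48 h
  expect_equal(sm$drained_volume_ml, 12.5 * 48)
})

test_that("reserve recovery drives the drainage response in simulated patients", {
  # rho = 1: strong day-2 collapse of RAP
  cfg <- sim_config(noise_sd = 0.05, fs = 20, seed = 11)
  dra1 <- simulate_drainage(cfg, rho = 1, compress = 30)
  rap1 <- compute_rap(window_stats(dra1, 10), 40)
  sm1 <- summarize_drainage(rap1, rec_events(dra1), dra1)
  expect_gt(sm1$drap1max_pct, 0)
  expect_gt(sm1$drap2max_pct, sm1$drap1max_pct)
  expect_gt(sm1$drap2max_pct, 50)
  # day-2 RAP is a max of null correlations once AMP is flat: bounded by the
  # null-max ceiling of the 40-window span, far below the baseline maximum
  expect_lt(sm1$rap3max, 0.5)
  expect_lt(sm1$rap3max, sm1$rap2max - 0.3)
  # mean drainage ICP sits below baseline, volume bookkeeping honours compression
  expect_lt(sm1$icp_dra_mean, 9.55)
  expect_equal(sm1$drained_volume_ml, 12.5 * 48)

  # rho = 0: compensatory reserve stays exhausted, declines near zero
  cfg0 <- sim_config(noise_sd = 0.05, fs = 20, seed = 13)
  dra0 <- simulate_drainage(cfg0, rho = 0, compress = 30)
  rap0 <- compute_rap(window_stats(dra0, 10), 40)
  sm0 <- summarize_drainage(rap0, rec_events(dra0), dra0)
  expect_gt(sm0$rap3max, 0.8)
  expect_lt(abs(sm0$drap1max_pct), 10)
  expect_lt(abs(sm0$drap2max_pct), 10)

  # reproducibility at fixed seed
  dra1b <- simulate_drainage(sim_config(noise_sd = 0.05, fs = 20, seed = 11),
                             rho = 1, compress = 30)
  expect_identical(dra1$icp_mmhg, dra1b$icp_mmhg)
})
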