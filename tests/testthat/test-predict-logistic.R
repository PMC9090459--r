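# Logistic IRLS, univariate screening, calibration, correlation.

test_that("IRLS matches the reference fitter and is deviance-monotone", {
  set.seed(101)
  d <- data.frame(y = rbinom(300, 1, 0.5), a = rnorm(300), b = rnorm(300))
  d$y <- rbinom(300, 1, plogis(-0.5 + 0.9 * d$a - 0.4 * d$b))
  f <- fit_logistic(d, "y", c("a", "b"))
  g <- stats::glm(y ~ a + b, binomial, d)     # independent oracle
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-4)
  expect_true(all(diff(f$deviance_trace) <= 1e-8))
  expect_true(f$converged)

  # null predictor: estimate within 2 standard errors at large n
  set.seed(102)
  d0 <- data.frame(y = rbinom(2000, 1, 0.5), x = rnorm(2000))
  f0 <- fit_logistic(d0, "y", "x")
  expect_lt(abs(f0$coefficients["x"]), 2 * f0$se["x"])

  # complete separation warned, singular design rejected
  ds <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 10, 11, 12))
  expect_warning(fs <- fit_logistic(ds, "y", "x"),
                 class = "raprout_separation_warning")
  expect_true(fs$separation)
  dd <- data.frame(y = rbinom(50, 1, 0.5), x = rnorm(50))
  dd$x2 <- 2 * dd$x
  expect_error(fit_logistic(dd, "y", c("x", "x2")),
               class = "raprout_singular_error")
})

test_that("univariate screen retains strong predictors and drops permuted ones", {
  coh <- generate_cohort(cohort_sim_config(n = 150, seed = 55))
  coh$drl <- dichotomize_mrs(coh$mrs)
  coh$strong <- qlogis(pmin(pmax(cohort_truth(coh)$p_drl, 0.01), 0.99)) +
    rnorm(150, 0, 0.01)
  coh$constant <- 5
  scr <- univariate_screen(coh, c("strong", "constant", "drap1max_pct"))
  expect_true(scr$retained[scr$predictor == "strong"])
  expect_equal(scr$flag[scr$predictor == "constant"], "zero_variance")
  expect_false(scr$retained[scr$predictor == "constant"])

  # permuted predictor: Wald p tracks an independent likelihood-ratio
  # recomputation and is null-distributed
  set.seed(56)
  y <- as.integer(coh$drl == "dRL")
  res <- t(replicate(100, {
    xp <- sample(coh$drap1max_pct)
    dat <- data.frame(y = y, xp = xp)
    p_wald <- tidy(fit_logistic(dat, "y", "xp"))$p.value[2]
    g <- stats::glm(y ~ xp, binomial, dat)
    p_lr <- stats::anova(g, test = "LRT")$`Pr(>Chi)`[2]
    c(p_wald, p_lr)
  }))
  expect_gt(mean(abs(res[, 1] - res[, 2]) < 0.01), 0.85)
  expect_gt(mean(res[, 1] >= 0.10), 0.85)
})

test_that("Hosmer-Lemeshow reproduces hand-computed tables and edge rules", {
  # O_g = E_g in every group -> statistic 0, p = 1
  p <- rep(c(0.2, 0.5, 0.8), each = 10)
  y <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(8, 2)))
  hl0 <- hosmer_lemeshow(p, y, g = 3)
  expect_equal(hl0$statistic, 0, tolerance = 1e-12)
  expect_equal(hl0$p_value, 1)

  # the 3-group toy table: n_g = 10, E = (2, 5, 8), O = (3, 5, 7)
  y2 <- c(rep(c(1, 0), c(3, 7)), rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(7, 3)))
  hl1 <- hosmer_lemeshow(p, y2, g = 3)
  stat_hand <- (3 - 2)^2 / (2 * (1 - 2 / 10)) + 0 +
    (7 - 8)^2 / (8 * (1 - 8 / 10))
  expect_equal(hl1$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(hl1$df, 1)

  # permuting outcomes among subjects of the same risk group leaves the
  # statistic unchanged (only group totals enter)
  set.seed(77)
  pr <- runif(200); yy <- rbinom(200, 1, pr)
  h_a <- hosmer_lemeshow(pr, yy)
  qs <- quantile(pr, probs = (1:9) / 10, type = 7)
  grp <- cut(pr, c(-Inf, qs, Inf), labels = FALSE, right = TRUE)
  yy_perm <- yy
  for (g in unique(grp)) {
    idx <- which(grp == g)
    yy_perm[idx] <- yy[sample(idx)]
  }
  expect_equal(hosmer_lemeshow(pr, yy_perm)$statistic, h_a$statistic)

  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), g = 10),
               class = "raprout_data_error")
})

test_that("correlate picks Pearson or Spearman by distribution shape", {
  x <- seq(-2, 2, length.out = 40) + rnorm(40, 0, 1e-6)
  r <- correlate(x, 2 * x + 1)
  expect_equal(r$estimate, 1, tolerance = 1e-6)

  set.seed(9)
  xh <- stats::rt(100, df = 1.5)       # heavy-tailed -> Spearman
  expect_equal(correlate(xh, xh + rnorm(100))$method, "spearman")

  # independent rank-permuted values: small coefficient
  set.seed(10)
  a <- rnorm(200); b <- sample(rnorm(200))
  expect_lt(abs(correlate(a, b)$estimate), 0.15)

  expect_error(correlate(rep(1, 10), rnorm(10)), class = "raprout_domain_error")
  expect_error(correlate(1:3, 1:3), class = "raprout_data_error")
})

test_that("evaluate_models emits the five specifications in order with sane rows", {
  coh <- generate_cohort(cohort_sim_config(n = 300, seed = 88))
  ev <- evaluate_models(coh)
  expect_equal(ev$model, c("rout_only", "drap1", "drap2",
                           "drap1_plus_drap2", "total_index"))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_true(all(ev$auc_ci_low <= ev$auc & ev$auc <= ev$auc_ci_high))
  expect_true(all(ev$sensitivity >= 0 & ev$sensitivity <= 100))
  # single-predictor cut-offs are in predictor units
  expect_gt(ev$cutoff[ev$model == "rout_only"], 5)
  expect_gt(ev$cutoff[ev$model == "drap1"], 10)
  # multivariate cut-offs are probabilities
  expect_lt(ev$cutoff[ev$model == "total_index"], 1)

  # null cohort: every AUC interval contains 0.5 (99% level keeps the joint
  # check over five correlated models stable)
  cc <- cohort_sim_config(n = 400, beta = c(qlogis(0.54), 0, 0, 0), seed = 89)
  ev0 <- evaluate_models(generate_cohort(cc), conf_level = 0.99)
  expect_true(all(ev0$auc_ci_low <= 0.5 & 0.5 <= ev0$auc_ci_high))

  # tidy/glance surface
  td <- tidy(ev)
  expect_true(all(c("model", "term", "estimate") %in% names(td)))
  expect_equal(nrow(glance(ev)), 5)
})

test_that("single RAPmax predictors are scored in the poor-recovery direction", {
  coh <- generate_cohort(cohort_sim_config(n = 300, seed = 90))
  # rap3max low when recovery is good, so it predicts non-dRL positively
  e <- evaluate_predictor(coh, "rap3max", direction = "non_dRL")
  expect_gt(e$auc, 0.5)
  expect_true(e$ci_low <= e$auc & e$auc <= e$ci_high)
})
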