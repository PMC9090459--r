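# ROC/AUC, DeLong intervals, Youden cut-offs, diagnostic metrics.

test_that("roc_auc equals brute-force pairwise concordance on random fixtures", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), class = "raprout_domain_error")

  set.seed(21)
  for (k in 1:30) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n, y), sample(c(0, 1, 8), 1))  # induce ties sometimes
    expect_identical(roc_auc(s, y)$auc, auc_bruteforce(s, y))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(3)
  y <- rbinom(80, 1, 0.4); s <- rnorm(80, y)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(qlogis(plogis(3 * s - 1)), y)$auc, a0)
})

test_that("DeLong interval covers and matches a bootstrap oracle", {
  set.seed(5)
  # identical score distributions: CI contains 0.5
  s0 <- rnorm(400); y0 <- rep(c(0, 1), each = 200)
  ci0 <- auc_ci(s0, y0)
  expect_true(ci0$ci_low <= 0.5 && 0.5 <= ci0$ci_high)
  expect_gt(ci0$p_value, 0.05)

  # perfect separation at n = 50/50
  s1 <- c(rnorm(50, 10), rnorm(50)); y1 <- rep(c(1, 0), each = 50)
  expect_gte(auc_ci(s1, y1)$ci_low, 0.9)

  # DeLong variance close to the bootstrap variance (stratified resampling)
  s <- c(rnorm(100, 1), rnorm(100)); y <- rep(c(1, 0), each = 100)
  dl <- auc_ci(s, y)
  boot <- replicate(2000, {
    i1 <- sample(which(y == 1), replace = TRUE)
    i0 <- sample(which(y == 0), replace = TRUE)
    roc_auc(s[c(i1, i0)], y[c(i1, i0)])$auc
  })
  expect_lt(abs(dl$se - sd(boot)) / sd(boot), 0.20)
})

test_that("youden_cutoff equals exhaustive threshold search with the tie-break contract", {
  y4 <- c(0, 0, 1, 1); s4 <- c(0.1, 0.4, 0.35, 0.8)
  got <- youden_cutoff(s4, y4)
  ora <- youden_exhaustive(s4, y4)
  expect_equal(got$cutoff, ora$th)
  expect_equal(got$sensitivity, 100 * ora$sens)
  expect_equal(got$specificity, 100 * ora$spec)

  set.seed(31)
  for (k in 1:25) {
    n <- sample(10:120, 1)
    y <- rbinom(n, 1, 0.5); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n, 0.8 * y), sample(0:1, 1))
    got <- youden_cutoff(s, y); ora <- youden_exhaustive(s, y)
    expect_equal(got$cutoff, ora$th)
    expect_equal(got$youden, ora$j, tolerance = 1e-12)
  }

  # perfectly separated scores: sens = spec = 100
  gp <- youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(c(gp$sensitivity, gp$specificity), c(100, 100))
  # rank invariance: monotone transform moves the cut-off, not the rates
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1); s <- rnorm(60, y)
  g1 <- youden_cutoff(s, y); g2 <- youden_cutoff(exp(s), y)
  expect_equal(c(g1$sensitivity, g1$specificity),
               c(g2$sensitivity, g2$specificity))
  expect_equal(g2$cutoff, exp(g1$cutoff))
})

test_that("confusion metrics reproduce the reported diagnostic accuracies", {
  # counts reconstructed from the reported rates at 38 dRL / 32 non-dRL
  m1 <- confusion_metrics(34, 4, 14, 18)
  expect_equal(round1_half_up(c(m1$sensitivity, m1$specificity, m1$ppv, m1$npv)),
               c(89.5, 56.3, 70.8, 81.8))
  m2 <- confusion_metrics(29, 9, 8, 24)
  expect_equal(round1_half_up(c(m2$sensitivity, m2$specificity, m2$ppv, m2$npv)),
               c(76.3, 75.0, 78.4, 72.7))
  m3 <- confusion_metrics(10, 0, 0, 10)
  expect_equal(unlist(m3[1, 1:4], use.names = FALSE), rep(100, 4))
  expect_error(confusion_metrics(0, 0, 0, 0), class = "raprout_domain_error")
  # zero denominator flagged, not an error
  mz <- confusion_metrics(0, 0, 3, 7)
  expect_true(is.na(mz$sensitivity) && mz$flag == "zero_denominator")
})

test_that("metrics_from_rates applies the Bayes identity at the cohort prevalence", {
  p1 <- metrics_from_rates(0.8947, 0.5625, 38 / 70)
  expect_equal(round(p1$ppv, 3), 0.708)
  expect_equal(round(p1$npv, 3), 0.818)
  p2 <- metrics_from_rates(0.8158, 0.9062, 38 / 70)
  expect_equal(round(p2$ppv, 3), 0.912)
  expect_equal(round(p2$npv, 3), 0.806)
  expect_equal(unlist(metrics_from_rates(1, 1, 0.3)[1, 1:2], use.names = FALSE),
               c(1, 1))
})

test_that("confusion_metrics and metrics_from_rates agree on reconstructed tables", {
  # reconstruct counts from rates at the printed precision, then round-trip
  cases <- list(c(0.8947, 0.5625), c(0.7632, 0.7500), c(0.8158, 0.9062),
                c(0.4211, 0.8437), c(0.8947, 0.8440))
  for (cs in cases) {
    tp <- round(cs[1] * 38); fn <- 38 - tp
    tn <- round(cs[2] * 32); fp <- 32 - tn
    cm <- confusion_metrics(tp, fn, fp, tn)
    br <- metrics_from_rates(tp / 38, tn / 32, 38 / 70)
    expect_equal(round1_half_up(cm$ppv), round1_half_up(100 * br$ppv))
    expect_equal(round1_half_up(cm$npv), round1_half_up(100 * br$npv))
  }
})

test_that("mRS dichotomisation follows the desirable-recovery rule", {
  expect_equal(as.character(dichotomize_mrs(c(0, 2, 3, 6))),
               c("dRL", "dRL", "non_dRL", "non_dRL"))
  expect_error(dichotomize_mrs(7), class = "raprout_domain_error")
  expect_error(dichotomize_mrs(-1), class = "raprout_domain_error")
})
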