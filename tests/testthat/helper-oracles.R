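# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: direct summation, brute-force enumeration.

# Pearson correlation by direct summation (no stats::cor)
pearson_direct <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  num / den
}

# AUC by brute-force all-pairs concordance, ties counted 1/2
auc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Youden cut-off by exhaustive search over every observed threshold,
# same tie-breaking contract (higher sensitivity, then lower threshold)
youden_exhaustive <- function(scores, y) {
  thr <- sort(unique(scores))
  best <- NULL
  for (th in thr) {
    sens <- mean(scores[y == 1] >= th)
    spec <- mean(scores[y == 0] < th)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && (sens > best$sens + 1e-12))) {
      best <- list(th = th, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# half-up rounding to one decimal (reporting convention)
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

# small noise-free simulator config for fast deterministic module tests
quiet_cfg <- function(...) {
  sim_config(noise_sd = 0, slow_wave_amp = 0, resp_amp = 0, a0 = 0,
             k_amp = 0, fs = 20, ...)
}

# synthetic window table with a prescribed (mean_icp, amp) relation
make_windows <- function(mean_icp, amp, valid = TRUE, window_s = 10) {
  n <- length(mean_icp)
  tibble::tibble(t_start = (seq_len(n) - 1) * window_s,
                 t_end = seq_len(n) * window_s,
                 mean_icp = mean_icp, amp = amp,
                 f_peak = 1.2, valid = rep_len(valid, n),
                 flag = NA_character_)
}

# synthetic RAP series at fixed spacing
make_rap_series <- function(t_mid, rap, valid = TRUE) {
  tibble::tibble(t_mid = t_mid, rap = rap, valid = rep_len(valid, length(t_mid)),
                 window_count = 40L)
}
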