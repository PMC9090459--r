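# 48-h lumbar-drainage RAP series -> segment maxima and relative declines.

#' Segment a RAP series around the drainage days
#'
#' Splits a RAP series into the pre-drainage baseline, day 1 and day 2
#' segments using the `drainage_start`, `day1_end` and `day2_end` events
#' (half-open intervals `[start, end)`); invalid RAP points are excluded.
#'
#' A RAP point summarises a whole correlation span, so points are assigned to
#' segments by the span's start time when the series carries one (`t_start`
#' from [compute_rap()]); this stops spans that begin before drainage onset
#' — which still reflect the pre-drainage operating point — from leaking into
#' day 1.  Series without `t_start` (e.g. re-read from CSV) fall back to
#' `t_mid`.
#'
#' @param series RAP series from [compute_rap()].
#' @param events Event tibble (`time_s`, `label`), e.g. [rec_events()].
#'
#' @return The valid RAP points with an added `segment` column
#'   (`"baseline"`, `"day1"`, `"day2"`); empty segments are reported in the
#'   `empty_segments` attribute.
#' @export
segment_rap <- function(series, events) {
  events <- validate_events(events)
  need <- c("drainage_start", "day1_end", "day2_end")
  have <- need %in% events$label
  if (!all(have))
    abort(paste0("missing event(s): ", paste(need[!have], collapse = ", ")),
          class = "raprout_protocol_error")
  t_dr <- events$time_s[events$label == "drainage_start"][1]
  t_d1 <- events$time_s[events$label == "day1_end"][1]
  t_d2 <- events$time_s[events$label == "day2_end"][1]
  if (!(t_dr < t_d1 && t_d1 < t_d2))
    abort("drainage events out of order", class = "raprout_protocol_error")
  ok <- series[series$valid, , drop = FALSE]
  loc <- if ("t_start" %in% names(ok) && !all(is.na(ok$t_start)))
    ok$t_start else ok$t_mid
  seg <- dplyr::case_when(
    loc < t_dr ~ "baseline",
    loc < t_d1 ~ "day1",
    loc < t_d2 ~ "day2",
    TRUE ~ NA_character_)
  out <- dplyr::mutate(ok, segment = seg)
  out <- out[!is.na(out$segment), , drop = FALSE]
  empty <- setdiff(c("baseline", "day1", "day2"), unique(out$segment))
  if (length(empty) > 0)
    warn(paste0("empty segment(s): ", paste(empty, collapse = ", ")),
         class = "raprout_empty_segment_warning")
  attr(out, "empty_segments") <- empty
  out
}

#' Segment-wise maximum RAP
#'
#' The highest RAP value of a segment, after a 5-point moving-median
#' smoothing of the valid points (guards against single-window spikes;
#' suppressible with `smooth = FALSE`).
#'
#' @param segment RAP points of one segment (needs >= 5 valid points).
#' @param smooth Apply the 5-point moving median before taking the maximum?
#'
#' @return The segment RAPmax (scalar).
#' @examples
#' x <- tibble::tibble(t_mid = 1:7,
#'                     rap = c(0.5, 0.5, 0.99, 0.5, 0.5, 0.6, 0.6),
#'                     valid = TRUE)
#' rap_max(x)             # 0.6 (spike suppressed)
#' rap_max(x, smooth = FALSE)  # 0.99
#' @export
rap_max <- function(segment, smooth = TRUE) {
  r <- segment$rap[segment$valid]
  if (length(r) < 5)
    abort("fewer than 5 valid RAP points in segment",
          class = "raprout_insufficient_data_error")
  if (smooth) r <- runmed(r, 5, endrule = "median")
  max(r)
}

#' Relative decline of RAPmax from baseline
#'
#' \eqn{\Delta RAPmax\% = 100 (RAPmax_{baseline} - RAPmax_{interim}) /
#' RAPmax_{baseline}}; negative when the interim maximum exceeds baseline.
#'
#' @param baseline_max Baseline RAPmax (> 0).
#' @param interim_max Interim RAPmax.
#' @return The relative decline in percent.
#' @examples
#' delta_rap_max_pct(0.80, 0.44)  # 45
#' @export
delta_rap_max_pct <- function(baseline_max, interim_max) {
  if (any(baseline_max <= 0))
    abort("`baseline_max` must be > 0", class = "raprout_domain_error")
  100 * (baseline_max - interim_max) / baseline_max
}

#' Summarise a drainage recording
#'
#' Reduces a drainage-phase RAP series to the segment maxima RAP1max (pre-
#' drainage baseline), RAP2max (day 1) and RAP3max (day 2), the relative
#' declines dRAP1max% (after day 1) and dRAP2max% (after day 2), the mean ICP
#' during drainage, and the drained-volume bookkeeping (configured rate times
#' protocol duration; the recording's `time_compress` attribute converts
#' simulated seconds back to protocol hours).
#'
#' @param series RAP series from [compute_rap()].
#' @param events Event tibble with the drainage events.
#' @param rec Optional [icp_recording()] for the drainage-phase mean ICP.
#' @param drain_rate_ml_h Drainage rate for bookkeeping, ml/h.
#' @param smooth Passed to [rap_max()].
#'
#' @return A one-row tibble of class `drainage_summary`: `rap1max`, `rap2max`,
#'   `rap3max`, `drap1max_pct`, `drap2max_pct`, `icp_dra_mean`,
#'   `drained_volume_ml`.  Fields whose segment failed are `NA` and the
#'   reasons are stored in the `failed` attribute.
#' @export
summarize_drainage <- function(series, events, rec = NULL,
                               drain_rate_ml_h = NULL, smooth = TRUE) {
  seg <- segment_rap(series, events)
  get_max <- function(name) {
    tryCatch(rap_max(seg[seg$segment == name, , drop = FALSE], smooth = smooth),
             error = function(e) structure(NA_real_, reason = conditionMessage(e)))
  }
  r1 <- get_max("baseline"); r2 <- get_max("day1"); r3 <- get_max("day2")
  d1 <- if (!is.na(r1) && !is.na(r2) && r1 > 0) delta_rap_max_pct(r1, r2) else NA_real_
  d2 <- if (!is.na(r1) && !is.na(r3) && r1 > 0) delta_rap_max_pct(r1, r3) else NA_real_

  events <- validate_events(events)
  t_dr <- events$time_s[events$label == "drainage_start"][1]
  t_d2 <- events$time_s[events$label == "day2_end"][1]
  icp_dra <- NA_real_
  if (!is.null(rec)) {
    s <- rec$time_s >= t_dr & rec$time_s < t_d2
    if (any(s)) icp_dra <- mean(rec$icp_mmhg[s])
  }
  compress <- (if (!is.null(rec)) attr(rec, "time_compress")) %||% 1
  if (is.null(drain_rate_ml_h))
    drain_rate_ml_h <- (if (!is.null(rec)) attr(rec, "drain_rate_ml_h")) %||% 12.5
  vol <- drain_rate_ml_h * (t_d2 - t_dr) * compress / 3600

  out <- tibble::tibble(rap1max = as.numeric(r1), rap2max = as.numeric(r2),
                        rap3max = as.numeric(r3),
                        drap1max_pct = d1, drap2max_pct = d2,
                        icp_dra_mean = icp_dra, drained_volume_ml = vol)
  failed <- purrr::compact(list(rap1max = attr(r1, "reason"),
                                rap2max = attr(r2, "reason"),
                                rap3max = attr(r3, "reason")))
  attr(out, "failed") <- failed
  class(out) <- c("drainage_summary", class(out))
  out
}

#' @export
glance.drainage_summary <- function(x, ...) tibble::as_tibble(x)
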