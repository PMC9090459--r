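#' Construct an ICP recording
#'
#' A uniformly sampled intracranial-pressure series with protocol event
#' annotations.  The container is a tibble (columns `time_s`, `icp_mmhg`) with
#' the sampling rate, events and provenance carried as attributes, so it can
#' flow through dplyr/ggplot2 pipelines unchanged.
#'
#' @param time_s Sample times in seconds, strictly increasing and uniform.
#' @param icp_mmhg ICP samples, mmHg.
#' @param fs Sampling rate, Hz.
#' @param events Tibble with columns `time_s`, `label`; labels must come from
#'   the controlled vocabulary `baseline_start`, `infusion_start`,
#'   `infusion_stop`, `drainage_start`, `day1_end`, `day2_end`.
#' @param patient_id Opaque identifier.
#' @param ... Extra attributes (e.g. `termination_reason`, `ground_truth`,
#'   `time_compress`) stored on the object.
#'
#' @return A tibble of class `icp_recording`.
#' @export
icp_recording <- function(time_s, icp_mmhg, fs,
                          events = empty_events(), patient_id = "sim", ...) {
  n <- length(time_s)
  stopifnot(length(icp_mmhg) == n, n >= 2)
  dt <- diff(time_s)
  if (any(dt <= 0))
    abort("`time_s` must be strictly increasing", class = "raprout_data_error")
  if (max(dt) - min(dt) > 1e-9 + 1e-9 * max(dt))
    abort("`time_s` must be uniformly sampled", class = "raprout_data_error")
  if (fs < 6)
    abort("`fs` must be at least 6 Hz to resolve the cardiac band",
          class = "raprout_data_error")
  events <- validate_events(events, range(time_s))
  extra <- list(...)
  out <- tibble::tibble(time_s = time_s, icp_mmhg = icp_mmhg)
  attr(out, "fs") <- fs
  attr(out, "events") <- events
  attr(out, "patient_id") <- patient_id
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("icp_recording", class(out))
  out
}

empty_events <- function() {
  tibble::tibble(time_s = numeric(0), label = character(0))
}

validate_events <- function(events, t_range = NULL) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("time_s", "label") %in% names(events)))
  bad <- !(events$label %in% EVENT_LABELS)
  if (any(bad))
    abort(paste0("unknown event label(s): ",
                 paste(unique(events$label[bad]), collapse = ", ")),
          class = "raprout_vocabulary_error")
  if (is.unsorted(events$time_s))
    events <- events[order(events$time_s), ]
  if (!is.null(t_range) && nrow(events) > 0 &&
      (min(events$time_s) < t_range[1] - 1e-9 ||
       max(events$time_s) > t_range[2] + 1e-9))
    abort("events must lie within the recording time span",
          class = "raprout_data_error")
  events
}

#' @rdname icp_recording
#' @param x,rec An `icp_recording`.
#' @export
rec_fs <- function(rec) attr(rec, "fs")

#' @rdname icp_recording
#' @export
rec_events <- function(rec) attr(rec, "events")

#' @rdname icp_recording
#' @export
rec_patient_id <- function(rec) attr(rec, "patient_id")

event_time <- function(rec, label) {
  ev <- rec_events(rec)
  tt <- ev$time_s[ev$label == label]
  if (length(tt) == 0) return(NA_real_)
  tt[1]
}

#' @export
print.icp_recording <- function(x, ...) {
  fs <- attr(x, "fs")
  ev <- attr(x, "events")
  cat(sprintf("<icp_recording> %s: %d samples @ %g Hz (%.1f min)\n",
              attr(x, "patient_id"), nrow(x), fs, nrow(x) / fs / 60))
  if (!is.null(attr(x, "termination_reason")))
    cat("  termination:", attr(x, "termination_reason"), "\n")
  if (nrow(ev) > 0)
    cat("  events:", paste(sprintf("%s@%.0fs", ev$label, ev$time_s),
                           collapse = ", "), "\n")
  NextMethod()
}
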