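# Readers/writers for the pipeline's CSV/JSON formats and the pipeline
# configuration.  CSV is the interchange format (no open standard exists for
# ICP recordings); times are seconds from recording start, segments are
# half-open [start, end).

SCHEMA_VERSION <- "1.0"

COHORT_COLUMNS <- c("patient_id", "age_years", "gcs_severe", "dc_history",
                    "interval_tbi_weeks", "shunt_type", "icp_b_mmhg", "rout",
                    "rap_b", "rap_dra", "rap1max", "rap2max", "rap3max",
                    "drap1max_pct", "drap2max_pct", "mrs", "followup_months")

#' Read an ICP waveform (and optional events) from CSV
#'
#' Waveform files have header `time_s,icp_mmhg`; event files have
#' `time_s,label` with labels from the controlled vocabulary.  Errors name
#' the offending line.
#'
#' @param path Waveform CSV path.
#' @param events_path Optional events CSV path.
#' @return An [icp_recording()].
#' @export
read_waveform <- function(path, events_path = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  if (!identical(names(df), c("time_s", "icp_mmhg")))
    abort(sprintf("%s: expected header 'time_s,icp_mmhg', got '%s'",
                  path, paste(names(df), collapse = ",")),
          class = "raprout_parse_error")
  bad_na <- which(!is.finite(df$icp_mmhg))
  if (length(bad_na) > 0)
    abort(sprintf("%s: non-finite pressure at line %d", path, bad_na[1] + 1),
          class = "raprout_parse_error")
  dt <- diff(df$time_s)
  bad <- which(dt <= 0)
  if (length(bad) > 0)
    abort(sprintf("%s: time not increasing at line %d", path, bad[1] + 2),
          class = "raprout_parse_error")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    abort(sprintf("%s: non-uniform sampling", path), class = "raprout_parse_error")
  fs <- 1 / stats::median(dt)
  events <- if (!is.null(events_path)) read_events(events_path) else empty_events()
  icp_recording(df$time_s, df$icp_mmhg, fs, events = events,
                patient_id = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_waveform
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), label = readr::col_character()),
    progress = FALSE)
  if (!identical(names(df), c("time_s", "label")))
    abort(sprintf("%s: expected header 'time_s,label'", path),
          class = "raprout_parse_error")
  bad <- which(!(df$label %in% EVENT_LABELS))
  if (length(bad) > 0)
    abort(sprintf("%s: unknown event label '%s' at line %d",
                  path, df$label[bad[1]], bad[1] + 1),
          class = "raprout_vocabulary_error")
  df
}

#' Write a recording (waveform + events) to CSV
#'
#' @param rec An [icp_recording()].
#' @param dir Output directory; files are `<stem>.csv` and
#'   `<stem>_events.csv`.
#' @param stem File stem (default the patient id).
#' @return Invisibly, the paths written.
#' @export
write_waveform <- function(rec, dir, stem = NULL) {
  if (is.null(stem)) stem <- rec_patient_id(rec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wf <- file.path(dir, paste0(stem, ".csv"))
  ef <- file.path(dir, paste0(stem, "_events.csv"))
  readr::write_csv(tibble::tibble(time_s = rec$time_s, icp_mmhg = rec$icp_mmhg), wf)
  readr::write_csv(rec_events(rec), ef)
  invisible(c(waveform = wf, events = ef))
}

#' Read or write a cohort table
#'
#' Cohort CSVs carry one row per patient with the declared column set
#' (missing values as empty cells).  On read, rows are validated (`mrs` in
#' 0-6, `shunt_type` in VP/LP) and the stored relative declines are
#' cross-checked against the stored maxima (mismatch beyond 0.1 warns,
#' naming the patient).
#'
#' @param path CSV path.
#' @return A tibble with the cohort records.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), shunt_type = readr::col_character(),
    mrs = readr::col_integer(), followup_months = readr::col_integer(),
    gcs_severe = readr::col_integer(), dc_history = readr::col_integer(),
    .default = readr::col_double()), progress = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "raprout_parse_error")
  bad_mrs <- which(!is.na(df$mrs) & (df$mrs < 0 | df$mrs > 6))
  if (length(bad_mrs) > 0)
    abort(sprintf("%s: mrs out of range 0-6 for patient %s",
                  path, df$patient_id[bad_mrs[1]]),
          class = "raprout_parse_error")
  bad_sh <- which(!is.na(df$shunt_type) & !(df$shunt_type %in% c("VP", "LP")))
  if (length(bad_sh) > 0)
    abort(sprintf("%s: shunt_type must be VP or LP (patient %s)",
                  path, df$patient_id[bad_sh[1]]),
          class = "raprout_parse_error")
  for (k in 1:2) {
    dcol <- c("drap1max_pct", "drap2max_pct")[k]
    rcol <- c("rap2max", "rap3max")[k]
    ok <- !is.na(df[[dcol]]) & !is.na(df$rap1max) & !is.na(df[[rcol]]) &
      df$rap1max > 0
    mismatch <- ok & abs(df[[dcol]] -
                           100 * (df$rap1max - df[[rcol]]) / df$rap1max) > 0.1
    if (any(mismatch))
      warn(sprintf("%s inconsistent with stored maxima for patient(s): %s",
                   dcol, paste(df$patient_id[mismatch], collapse = ", ")),
           class = "raprout_consistency_warning")
  }
  df
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort)[, intersect(COHORT_COLUMNS,
                                                         names(cohort))], path)
  invisible(path)
}

#' Write / read a RAP series as CSV
#'
#' Columns: `t_mid_s`, `rap`, `valid` (window means are kept alongside when
#' available from the window table).
#'
#' @param series RAP series from [compute_rap()].
#' @param path CSV path.
#' @export
write_rap_series <- function(series, path) {
  readr::write_csv(tibble::tibble(t_mid_s = series$t_mid, rap = series$rap,
                                  valid = series$valid), path)
  invisible(path)
}

#' @rdname write_rap_series
#' @export
read_rap_series <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    t_mid_s = readr::col_double(), rap = readr::col_double(),
    valid = readr::col_logical()), progress = FALSE)
  tibble::tibble(t_mid = df$t_mid_s, rap = df$rap, valid = df$valid,
                 window_count = NA_integer_)
}

#' Pipeline configuration
#'
#' Nested configuration for every stage, with the protocol constants as
#' defaults: infusion at 1.5 ml/min with a 10-min baseline and the Rout
#' safety threshold at 18 mmHg·min/ml; drainage at 10-15 ml/h; univariate
#' screening at p < 0.10.  Unknown keys and out-of-range values are rejected.
#'
#' @param ... Named overrides of the form `section = list(key = value)`.
#' @return A validated nested list of class `rap_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg))
      abort(paste0("unknown config section: ", sec), class = "raprout_config_error")
    if (sec == "seed") { cfg$seed <- over$seed; next }
    for (key in names(over[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        abort(paste0("unknown config key: ", sec, ".", key),
              class = "raprout_config_error")
      cfg[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  validate_config(cfg)
}

default_config <- function() {
  list(
    signal = list(window_s = 10, rap_span_n = 40, cardiac_band = c(0.67, 3),
                  amp_method = "spectral"),
    infusion = list(rate_ml_min = 1.5, baseline_min = 10,
                    steady_span_mmhg = 1, plateau_slope = 0.2,
                    plateau_sustain_min = 5, rout_terminate = 18),
    drainage = list(drain_rate_ml_h = 12.5, smoothing = TRUE),
    predict = list(alpha_screen = 0.10, hl_groups = 10, ci_method = "delong"),
    sim = unclass(sim_config())[setdiff(names(sim_config()), "seed")],
    seed = NULL)
}

validate_config <- function(cfg) {
  s <- cfg$signal
  if (s$window_s <= 0 || s$rap_span_n < 3)
    abort("signal config out of range", class = "raprout_config_error")
  if (!s$amp_method %in% c("spectral", "peak_to_peak"))
    abort("amp_method must be 'spectral' or 'peak_to_peak'",
          class = "raprout_config_error")
  i <- cfg$infusion
  if (i$rate_ml_min <= 0 || i$baseline_min <= 0 || i$plateau_slope <= 0 ||
      i$plateau_sustain_min <= 0 || i$rout_terminate <= 0)
    abort("infusion config out of range", class = "raprout_config_error")
  d <- cfg$drainage
  if (d$drain_rate_ml_h < 10 || d$drain_rate_ml_h > 15)
    abort("drain_rate_ml_h must lie in [10, 15]", class = "raprout_config_error")
  p <- cfg$predict
  if (p$alpha_screen <= 0 || p$alpha_screen >= 1 || p$hl_groups < 3)
    abort("predict config out of range", class = "raprout_config_error")
  if (!p$ci_method %in% c("delong"))
    abort("ci_method must be 'delong'", class = "raprout_config_error")
  do.call(sim_config, c(cfg$sim, list(seed = NULL)))  # range-checks sim block
  structure(cfg, class = "rap_config")
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path Config file; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return A validated `rap_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- raw$seed
  raw$seed <- NULL
  do.call(pipeline_config, c(raw, if (!is.null(seed)) list(seed = seed)))
}

#' Write model-evaluation results as JSON
#'
#' One object per model, mirroring the evaluation fields, under a top-level
#' `schema_version` key.
#'
#' @param eval A `shunt_model_eval` table.
#' @param path Output JSON path.
#' @export
write_eval_json <- function(eval, path) {
  flat <- tibble::as_tibble(eval)[, setdiff(names(eval), c("coefficients", "roc"))]
  models <- purrr::map(seq_len(nrow(flat)), function(i) as.list(flat[i, -1]))
  names(models) <- flat$model
  coefs <- purrr::map(eval$coefficients, function(td)
    if (is.null(td)) NULL else as.list(setNames(td$estimate, td$term)))
  names(coefs) <- flat$model
  for (m in names(models)) models[[m]]$coefficients <- coefs[[m]]
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION, models = models),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
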