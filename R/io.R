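# Delimited-text readers and writers for the device stream and artifact
# formats. Timestamps are written ISO-8601; epoch spacing is validated on
# read (30 s wrist, 1 s hip), with the offending line reported.

.ts_fmt <- "%Y-%m-%dT%H:%M:%S"

fmt_ts <- function(x) format(x, .ts_fmt, tz = .tz)

#' Write / read a wrist epoch stream
#'
#' Columns: `participant_id, timestamp, counts, offwrist, lux` with
#' ISO-8601 timestamps at exact 30-s spacing.
#'
#' @param wrist Wrist tibble.
#' @param path File path (CSV).
#' @return `read_wrist()` returns the validated tibble.
#' @export
write_wrist <- function(wrist, path) {
  wrist %>%
    mutate(timestamp = fmt_ts(.data$timestamp)) %>%
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_wrist
#' @export
read_wrist <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_datetime(format = ""),
    counts = readr::col_integer(),
    offwrist = readr::col_integer(),
    lux = readr::col_double()
  ))
  x$timestamp <- lubridate::with_tz(x$timestamp, .tz)
  validate_stream_file(x, 30, "wrist")
  x
}

#' Write / read a hip 1-s count stream
#'
#' Columns: `participant_id, timestamp, counts`.
#'
#' @param hip Hip tibble.
#' @param path File path (CSV).
#' @return `read_hip()` returns the validated tibble.
#' @export
write_hip <- function(hip, path) {
  hip %>%
    mutate(timestamp = fmt_ts(.data$timestamp)) %>%
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_hip
#' @export
read_hip <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_datetime(format = ""),
    counts = readr::col_integer()
  ))
  x$timestamp <- lubridate::with_tz(x$timestamp, .tz)
  validate_stream_file(x, 1, "hip")
  x
}

validate_stream_file <- function(x, step, what) {
  offset <- 0L
  for (id in unique(x$participant_id)) {
    sel <- which(x$participant_id == id)
    d <- diff(as.numeric(x$timestamp[sel]))
    bad <- which(d != step)
    if (length(bad)) {
      abort(sprintf(
        "%s stream: non-monotonic or mis-spaced timestamps for participant %s at data line %d (expected %d-s spacing)",
        what, id, sel[bad[1] + 1L] + 1L, step))
    }
  }
  invisible(x)
}

#' Write / read the participant covariate table
#'
#' One row per participant with the sociodemographic covariates; factor
#' levels are restored with the analysis reference level first.
#'
#' @param covariates Covariate tibble.
#' @param path File path (CSV).
#' @return `read_covariates()` returns the tibble with factor columns.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols())
  for (nm in names(.cov_levels)[names(.cov_levels) %in% names(x)]) {
    x[[nm]] <- factor(x[[nm]], levels = names(.cov_levels[[nm]]))
  }
  x
}

#' Write the scored sleep-interval table
#'
#' One row per interval: `participant_id, date, role, onset, offset,
#' duration_min, sleep_min, sme_pct, valid, reason`.
#'
#' @param intervals Interval tibble from [score_sleep()].
#' @param path File path (CSV).
#' @export
write_sleep_intervals <- function(intervals, path) {
  intervals %>%
    mutate(onset = fmt_ts(.data$onset), offset = fmt_ts(.data$offset)) %>%
    readr::write_csv(path)
  invisible(path)
}

#' Write the minute label table
#'
#' @param minutes Minute table from [classify_activity()].
#' @param path File path (CSV).
#' @export
write_minutes <- function(minutes, path) {
  minutes %>%
    mutate(minute_start = fmt_ts(.data$minute_start)) %>%
    readr::write_csv(path)
  invisible(path)
}

#' Write / read the person-day analysis table
#'
#' @param person_days Person-day tibble from [build_person_days()].
#' @param path File path (CSV).
#' @return `read_person_days()` returns the tibble.
#' @export
write_person_days <- function(person_days, path) {
  person_days %>%
    mutate(across(dplyr::where(~ inherits(.x, "POSIXct")), fmt_ts)) %>%
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_person_days
#' @export
read_person_days <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date()
  ))
  for (nm in intersect(c("day_start", "day_end", "offset_time",
                         "cluster_midpoint"), names(x))) {
    x[[nm]] <- lubridate::ymd_hms(x[[nm]], tz = .tz)
  }
  x
}
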