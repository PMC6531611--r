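# Rule-based sleep scoring of wrist 30-s epoch streams.
#
# All rules operate on the published count thresholds: an epoch is
# quiescent when its activity count is <= `count_threshold` (10 by
# default) and the device is worn. Off-wrist epochs are excluded from the
# count-rule scans (they break quiescent runs: zeros from non-wear must
# not fake sleep).

.EPOCH_SEC <- 30

#' Sleep scoring options
#'
#' Bundles every tunable threshold of the sleep-scoring rules. Defaults
#' are the published values; they are deliberately exposed because the
#' thresholds *are* the method.
#'
#' @param count_threshold Counts above which a 30-s epoch is active (10).
#' @param quiet_run Number of consecutive quiescent epochs required by the
#'   onset/offset rules (5).
#' @param onset_epoch Which epoch's start time is reported as sleep onset:
#'   `"quiet"` (the first quiescent epoch, immobility start) or `"active"`
#'   (the last active epoch, the literal rule text). The two differ by one
#'   30-s epoch.
#' @param min_block_min Minimum quiescent run (minutes) that seeds a
#'   candidate rest block (5).
#' @param rest_gap_max_min Wake gaps shorter than this merge neighbouring
#'   rest blocks into one rest period before splitting (180).
#' @param split_awakening_min Awakenings at least this long (minutes)
#'   split a rest period into separate intervals (60).
#' @param min_interval_min Minimum scored interval duration kept (20).
#' @param main_window_start,main_window_end Clock hours bounding the
#'   nighttime window used by main-sleep selection (22 and 8).
#' @param main_rule `"total"` compares each window-overlapping interval's
#'   total duration; `"within_window"` compares only the overlapping
#'   portion.
#' @param offwrist_invalid_min Total daily off-wrist minutes that
#'   invalidate a (non-first/last) sleep day (240).
#' @param first_day_wear_min Minimum wear before onset required on the
#'   first day (120).
#' @param edge_offwrist_min,edge_margin_min An off-wrist run of at least
#'   `edge_offwrist_min` minutes starting or ending within
#'   `edge_margin_min` minutes of the main-sleep onset/offset invalidates
#'   the day (60 and 10).
#' @param cutpoint_hour Clock hour at which the 24-h cut-point day starts
#'   (12, noon-to-noon).
#' @return A list of class `"sleep_opts"`.
#' @export
sleep_opts <- function(count_threshold = 10,
                       quiet_run = 5L,
                       onset_epoch = c("quiet", "active"),
                       min_block_min = 5,
                       rest_gap_max_min = 180,
                       split_awakening_min = 60,
                       min_interval_min = 20,
                       main_window_start = 22,
                       main_window_end = 8,
                       main_rule = c("total", "within_window"),
                       offwrist_invalid_min = 240,
                       first_day_wear_min = 120,
                       edge_offwrist_min = 60,
                       edge_margin_min = 10,
                       cutpoint_hour = 12) {
  structure(list(
    count_threshold = count_threshold,
    quiet_run = as.integer(quiet_run),
    onset_epoch = match.arg(onset_epoch),
    min_block_min = min_block_min,
    rest_gap_max_min = rest_gap_max_min,
    split_awakening_min = split_awakening_min,
    min_interval_min = min_interval_min,
    main_window_start = main_window_start,
    main_window_end = main_window_end,
    main_rule = match.arg(main_rule),
    offwrist_invalid_min = offwrist_invalid_min,
    first_day_wear_min = first_day_wear_min,
    edge_offwrist_min = edge_offwrist_min,
    edge_margin_min = edge_margin_min,
    cutpoint_hour = cutpoint_hour
  ), class = "sleep_opts")
}

epoch_flags <- function(epochs, opts) {
  off <- if ("offwrist" %in% names(epochs)) epochs$offwrist > 0 else
    rep(FALSE, nrow(epochs))
  quiet <- !off & epochs$counts <= opts$count_threshold
  active <- !off & epochs$counts > opts$count_threshold
  list(quiet = quiet, active = active, off = off)
}

# positions i where quiet[i..i+k-1] are all TRUE
quiet_run_starts <- function(quiet, k) {
  n <- length(quiet)
  if (n < k) return(logical(0))
  cs <- cumsum(as.integer(quiet))
  run <- cs[k:n] - c(0, cs)[1:(n - k + 1)]
  c(run == k, rep(FALSE, k - 1))
}

#' Score sleep onset within a rest segment
#'
#' Scans forward for the first 30-s epoch of activity above the count
#' threshold that is followed by `quiet_run` consecutive quiescent epochs.
#' The reported instant is the start of the first quiescent epoch
#' (`onset_epoch = "quiet"`, default) or of the active epoch itself
#' (`"active"`); the two conventions differ by exactly one epoch.
#'
#' @param epochs Tibble with `timestamp`, `counts` and optionally
#'   `offwrist` over a candidate rest segment.
#' @param opts A [sleep_opts()] object.
#' @return A POSIXct instant, or `NA` if no qualifying pattern exists
#'   (including segments shorter than `quiet_run + 1` epochs).
#' @export
#' @examples
#' ep <- tibble::tibble(
#'   timestamp = lubridate::ymd_hms("2023-10-02 23:00:00") + 30 * (0:9),
#'   counts = c(50, 30, 12, 0, 0, 0, 0, 0, 0, 0)
#' )
#' score_onset(ep, sleep_opts(onset_epoch = "active")) # 23:01:00
score_onset <- function(epochs, opts = sleep_opts()) {
  n <- nrow(epochs)
  if (n < opts$quiet_run + 1L) return(as.POSIXct(NA, tz = .tz))
  f <- epoch_flags(epochs, opts)
  qs <- quiet_run_starts(f$quiet, opts$quiet_run)
  cand <- which(f$active & c(qs[-1], FALSE))
  if (!length(cand)) return(as.POSIXct(NA, tz = .tz))
  i <- cand[1]
  if (opts$onset_epoch == "active") epochs$timestamp[i] else epochs$timestamp[i + 1L]
}

#' Score sleep offset within a rest segment
#'
#' Mirror of [score_onset()], scanning from the end of the segment: the
#' reported instant is the first 30-s epoch of activity above the count
#' threshold that follows `quiet_run` consecutive quiescent epochs (the
#' literal rule: the time of the waking epoch).
#'
#' @inheritParams score_onset
#' @return A POSIXct instant or `NA`.
#' @export
score_offset <- function(epochs, opts = sleep_opts()) {
  n <- nrow(epochs)
  if (n < opts$quiet_run + 1L) return(as.POSIXct(NA, tz = .tz))
  f <- epoch_flags(epochs, opts)
  k <- opts$quiet_run
  # quiet run ending at position i: quiet[i-k+1 .. i]
  qs <- quiet_run_starts(f$quiet, k)          # starts of k-runs
  run_ends <- c(rep(FALSE, k - 1), qs[seq_len(n - k + 1)])
  cand <- which(f$active & c(FALSE, run_ends[-n]))
  if (!length(cand)) return(as.POSIXct(NA, tz = .tz))
  epochs$timestamp[cand[length(cand)]]
}

#' Split a rest period at awakenings of at least one hour
#'
#' Labels each epoch of the segment sleep or wake by the count threshold
#' and cuts the segment wherever a contiguous worn-wake (or off-wrist) run
#' lasts at least `split_awakening_min` minutes; each piece is then
#' re-scored for its own onset and offset.
#'
#' @inheritParams score_onset
#' @return A tibble with one row per scored sub-interval: `onset`,
#'   `offset` (POSIXct). Pieces without a scorable onset/offset or shorter
#'   than `min_interval_min` are dropped.
#' @export
split_intervals <- function(epochs, opts = sleep_opts()) {
  f <- epoch_flags(epochs, opts)
  wake <- !f$quiet   # active or off-wrist epochs interrupt sleep
  wake_runs <- runs_of(wake)
  cut_runs <- wake_runs %>%
    filter(.data$len >= opts$split_awakening_min * 60 / .EPOCH_SEC)
  bounds <- c(0L, as.integer(t(as.matrix(cut_runs[, c("start", "end")]))),
              nrow(epochs) + 1L)
  pieces <- matrix(bounds, ncol = 2, byrow = TRUE)
  out <- list()
  for (r in seq_len(nrow(pieces))) {
    lo <- pieces[r, 1] + 1L
    hi <- pieces[r, 2] - 1L
    if (hi - lo + 1L < opts$quiet_run + 1L) next
    # include the bounding wake epochs so the scans see an active flank
    lo2 <- max(1L, lo - 1L)
    hi2 <- min(nrow(epochs), hi + 1L)
    seg <- epochs[lo2:hi2, ]
    on <- score_onset(seg, opts)
    off <- score_offset(seg, opts)
    if (is.na(on) || is.na(off) || off <= on) next
    dur <- as.numeric(difftime(off, on, units = "mins"))
    if (dur < opts$min_interval_min) next
    out[[length(out) + 1L]] <- tibble(onset = on, offset = off)
  }
  if (!length(out)) {
    return(tibble(onset = as.POSIXct(character(), tz = .tz),
                  offset = as.POSIXct(character(), tz = .tz)))
  }
  bind_rows(out)
}

#' Select the main sleep interval of a cut-point day
#'
#' Among the day's scored intervals, picks the one with the longest
#' duration among intervals overlapping the nighttime window (22:00 to
#' 08:00 by default); the remainder are naps. With
#' `main_rule = "within_window"` only the window-overlapping portion of
#' each interval is compared. Ties break by larger window overlap, then
#' earlier onset.
#'
#' @param intervals Tibble with `onset`/`offset` POSIXct columns, all
#'   belonging to one cut-point day.
#' @param cutpoint_date The calendar date on which the cut-point day
#'   starts (its noon).
#' @param opts A [sleep_opts()] object.
#' @return Row index of the main interval, or `NA_integer_` if no
#'   interval overlaps the window (an invalid sleep day).
#' @export
select_main_sleep <- function(intervals, cutpoint_date, opts = sleep_opts()) {
  if (nrow(intervals) == 0) return(NA_integer_)
  w0 <- as.POSIXct(cutpoint_date, tz = .tz) + opts$main_window_start * 3600
  w1 <- as.POSIXct(cutpoint_date + 1, tz = .tz) + opts$main_window_end * 3600
  ov <- overlap_len(intervals$onset, intervals$offset, w0, w1) / 60
  dur <- as.numeric(difftime(intervals$offset, intervals$onset, units = "mins"))
  score <- if (opts$main_rule == "total") ifelse(ov > 0, dur, -Inf) else
    ifelse(ov > 0, ov, -Inf)
  if (all(score == -Inf)) return(NA_integer_)
  ord <- order(-score, -ov, intervals$onset)
  ord[1]
}

#' Label epochs within a scored interval as sleep or wake
#'
#' Every worn 30-s epoch with counts above the threshold is wake; quiet
#' worn epochs are sleep; off-wrist epochs are wake (not credited as
#' sleep). Sleep minutes are half the number of sleep epochs.
#'
#' @param epochs Epoch tibble covering at least `[onset, offset)`.
#' @param onset,offset Interval bounds (POSIXct).
#' @param opts A [sleep_opts()] object.
#' @return A list with `labels` (character, per epoch in the interval),
#'   `sleep_min`, `duration_min` and `sme_pct` (= 100 x sleep/duration).
#' @export
score_sleep_wake <- function(epochs, onset, offset, opts = sleep_opts()) {
  sel <- epochs$timestamp >= onset & epochs$timestamp < offset
  seg <- epochs[sel, ]
  f <- epoch_flags(seg, opts)
  labels <- ifelse(f$quiet, "sleep", "wake")
  sleep_min <- sum(labels == "sleep") * .EPOCH_SEC / 60
  duration_min <- as.numeric(difftime(offset, onset, units = "mins"))
  list(labels = labels, sleep_min = sleep_min, duration_min = duration_min,
       sme_pct = if (duration_min > 0) 100 * sleep_min / duration_min else NA_real_)
}

#' Validate a scored sleep day
#'
#' A cut-point day is invalid when (a) total off-wrist time reaches 4
#' hours (except the first and last recording day), (b) on the first day
#' the device was worn for less than 2 hours before sleep onset, or (c)
#' any off-wrist run of at least 60 minutes starts or ends within 10
#' minutes of the main-sleep onset or offset.
#'
#' @param day_epochs Epoch tibble of the cut-point day.
#' @param main_onset,main_offset Main-sleep bounds (POSIXct), or `NA`.
#' @param is_first,is_last Whether this is the first/last recording day.
#' @param opts A [sleep_opts()] object.
#' @return A list with `valid` (logical) and `reason` (character).
#' @export
validate_sleep_day <- function(day_epochs, main_onset, main_offset,
                               is_first = FALSE, is_last = FALSE,
                               opts = sleep_opts()) {
  if (is.na(main_onset) || is.na(main_offset)) {
    return(list(valid = FALSE, reason = "no_main_sleep"))
  }
  off <- if ("offwrist" %in% names(day_epochs)) day_epochs$offwrist > 0 else
    rep(FALSE, nrow(day_epochs))
  off_min_total <- sum(off) * .EPOCH_SEC / 60
  if (!is_first && !is_last && off_min_total >= opts$offwrist_invalid_min) {
    return(list(valid = FALSE, reason = "offwrist_total"))
  }
  if (is_first) {
    pre <- day_epochs$timestamp < main_onset
    wear_min <- sum(pre & !off) * .EPOCH_SEC / 60
    if (wear_min < opts$first_day_wear_min) {
      return(list(valid = FALSE, reason = "first_day_wear"))
    }
  }
  offruns <- runs_of(off)
  offruns <- offruns %>%
    filter(.data$len >= opts$edge_offwrist_min * 60 / .EPOCH_SEC)
  if (nrow(offruns)) {
    run_start <- day_epochs$timestamp[offruns$start]
    run_end <- day_epochs$timestamp[offruns$end] + .EPOCH_SEC
    marg <- opts$edge_margin_min * 60
    near <- function(a, b) abs(as.numeric(a) - as.numeric(b)) <= marg
    bad <- near(run_start, main_onset) | near(run_start, main_offset) |
      near(run_end, main_onset) | near(run_end, main_offset)
    if (any(bad)) return(list(valid = FALSE, reason = "offwrist_near_sleep"))
  }
  list(valid = TRUE, reason = "ok")
}

# candidate rest periods: quiescent blocks merged across gaps shorter than
# rest_gap_max_min; returns epoch index bounds, slightly extended so the
# onset/offset scans can see the flanking active epochs
find_rest_periods <- function(epochs, opts) {
  f <- epoch_flags(epochs, opts)
  blocks <- runs_of(f$quiet) %>%
    filter(.data$len >= opts$min_block_min * 60 / .EPOCH_SEC)
  if (nrow(blocks) == 0) return(blocks[0, ])
  gap_max <- opts$rest_gap_max_min * 60 / .EPOCH_SEC
  grp <- cumsum(c(1, (blocks$start[-1] - blocks$end[-nrow(blocks)]) > gap_max))
  blocks %>%
    mutate(grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    mutate(start = pmax(1L, .data$start - 20L),
           end = pmin(nrow(epochs), .data$end + 20L))
}

#' Score a wrist epoch stream into sleep intervals and nightly metrics
#'
#' Full sleep-scoring driver: finds candidate rest periods, splits them at
#' awakenings of an hour or more, scores each interval's onset/offset by
#' the count rules, assigns intervals to 24-h cut-point days, selects the
#' main nighttime sleep per day, computes duration / sleep minutes /
#' maintenance efficiency, and applies the day-validity rules.
#'
#' @param wrist Wrist epoch tibble (`participant_id`, `timestamp`,
#'   `counts`, `offwrist`, optionally `lux`) with strictly increasing
#'   30-s-spaced timestamps per participant.
#' @param opts A [sleep_opts()] object.
#' @return A tibble with one row per scored interval: `participant_id`,
#'   `date` (cut-point day), `role` (`"main"`/`"nap"`), `onset`, `offset`,
#'   `duration_min`, `sleep_min`, `sme_pct`, `valid`, `reason`. Days whose
#'   main sleep fails validation keep their row with `valid = FALSE`.
#' @export
score_sleep <- function(wrist, opts = sleep_opts()) {
  stopifnot_cols(wrist, c("participant_id", "timestamp", "counts"), "wrist")
  wrist %>%
    group_by(.data$participant_id) %>%
    dplyr::group_split() %>%
    map(function(ep) {
      check_epoch_spacing(ep$timestamp, .EPOCH_SEC, ep$participant_id[1])
      score_sleep_one(ep, opts)
    }) %>%
    list_rbind()
}

check_epoch_spacing <- function(ts, step, id) {
  d <- diff(as.numeric(ts))
  bad <- which(d != step)
  if (length(bad)) {
    abort(sprintf(
      "participant %s: timestamps must be strictly increasing with constant %d-s spacing (first violation at row %d)",
      id, step, bad[1] + 1L))
  }
}

score_sleep_one <- function(ep, opts) {
  rp <- find_rest_periods(ep, opts)
  ints <- list()
  for (r in seq_len(nrow(rp))) {
    seg <- ep[rp$start[r]:rp$end[r], ]
    ints[[length(ints) + 1L]] <- split_intervals(seg, opts)
  }
  ints <- if (length(ints)) bind_rows(ints) else tibble(onset = as.POSIXct(character(), tz = .tz), offset = as.POSIXct(character(), tz = .tz))
  if (nrow(ints) == 0) {
    return(tibble(participant_id = character(), date = as.Date(character()),
                  role = character(), onset = as.POSIXct(character(), tz = .tz),
                  offset = as.POSIXct(character(), tz = .tz),
                  duration_min = numeric(), sleep_min = numeric(),
                  sme_pct = numeric(), valid = logical(), reason = character()))
  }
  ints <- ints %>%
    arrange(.data$onset) %>%
    mutate(date = as.Date(.data$onset - opts$cutpoint_hour * 3600, tz = .tz))

  first_date <- as.Date(ep$timestamp[1] - opts$cutpoint_hour * 3600, tz = .tz)
  last_date <- as.Date(ep$timestamp[nrow(ep)] - opts$cutpoint_hour * 3600, tz = .tz)

  out <- list()
  for (d in sort(unique(ints$date))) {
    d <- as.Date(d, origin = "1970-01-01")
    day_ints <- ints %>% filter(.data$date == d)
    main_idx <- select_main_sleep(day_ints, d, opts)
    day_start <- as.POSIXct(d, tz = .tz) + opts$cutpoint_hour * 3600
    day_ep <- ep %>% filter(.data$timestamp >= day_start,
                            .data$timestamp < day_start + 86400)
    main_on <- if (is.na(main_idx)) as.POSIXct(NA, tz = .tz) else day_ints$onset[main_idx]
    main_off <- if (is.na(main_idx)) as.POSIXct(NA, tz = .tz) else day_ints$offset[main_idx]
    v <- validate_sleep_day(day_ep, main_on, main_off,
                            is_first = d == first_date, is_last = d == last_date,
                            opts = opts)
    for (j in seq_len(nrow(day_ints))) {
      sw <- score_sleep_wake(ep, day_ints$onset[j], day_ints$offset[j], opts)
      out[[length(out) + 1L]] <- tibble(
        participant_id = ep$participant_id[1],
        date = d,
        role = if (!is.na(main_idx) && j == main_idx) "main" else "nap",
        onset = day_ints$onset[j],
        offset = day_ints$offset[j],
        duration_min = sw$duration_min,
        sleep_min = sw$sleep_min,
        sme_pct = sw$sme_pct,
        valid = v$valid,
        reason = v$reason
      )
    }
    if (is.na(main_idx)) {
      out[[length(out) + 1L]] <- tibble(
        participant_id = ep$participant_id[1], date = d, role = "main",
        onset = as.POSIXct(NA, tz = .tz), offset = as.POSIXct(NA, tz = .tz),
        duration_min = NA_real_, sleep_min = NA_real_, sme_pct = NA_real_,
        valid = FALSE, reason = v$reason
      )
    }
  }
  bind_rows(out)
}
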