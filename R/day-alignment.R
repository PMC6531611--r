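# Sleep-onset-anchored person-day construction: merges scored sleep
# intervals with classified activity minutes into one analysis row per
# "day", where a day runs from a night's sleep onset to the next night's
# sleep onset.

#' Day-alignment options
#'
#' @param max_nonwear_pct Maximum percent non-wear in the wake portion of
#'   a valid physical-activity day (25).
#' @param min_forced_day_h Minimum length (hours) of a forced-ended day
#'   (20).
#' @param forced_offwrist_min Off-wrist run (minutes) that ends a day with
#'   no terminating main sleep (60; the rule is "more than 1 hour").
#' @param cluster_window_min Width of the sliding MVPA-cluster window
#'   (120).
#' @param cluster_rule `"window_center"` reports the center of the
#'   maximizing window; `"centroid"` reports the mean time of the MVPA
#'   minutes inside it.
#' @param nap_in_denominator Whether scored nap minutes stay in the
#'   denominator of the non-wear percentage (default `FALSE`: the wake
#'   portion excludes scored sleep).
#' @return A list of class `"align_opts"`.
#' @export
align_opts <- function(max_nonwear_pct = 25,
                       min_forced_day_h = 20,
                       forced_offwrist_min = 60,
                       cluster_window_min = 120,
                       cluster_rule = c("window_center", "centroid"),
                       nap_in_denominator = FALSE) {
  structure(list(
    max_nonwear_pct = max_nonwear_pct,
    min_forced_day_h = min_forced_day_h,
    forced_offwrist_min = forced_offwrist_min,
    cluster_window_min = cluster_window_min,
    cluster_rule = match.arg(cluster_rule),
    nap_in_denominator = nap_in_denominator
  ), class = "align_opts")
}

#' Segment a participant's record into sleep-onset-anchored days
#'
#' Each day runs from a valid main-sleep onset to the next day's valid
#' main-sleep onset. When the terminating night has no valid main sleep,
#' the day is force-ended at the first of: the start of an off-wrist run
#' longer than [align_opts()]`$forced_offwrist_min`, or the onset of an
#' apparent (scored but unvalidated) sleep interval, or the end of the
#' recording.
#'
#' @param intervals Scored sleep-interval table from [score_sleep()].
#' @param wrist Wrist epoch tibble (for off-wrist runs).
#' @param opts An [align_opts()] object.
#' @return A tibble of person-day skeletons: `participant_id`, `date`
#'   (cut-point date of the anchoring night), `day_start`, `day_end`,
#'   `day_length_h`, `forced_end`, the anchoring night's sleep metrics
#'   (`onset_h` midnight-centered, `offset_h` 24-h clock, `duration_min`,
#'   `sme_pct`, `offset_time`), and weekend flags (`weekend_night` for
#'   Friday/Saturday nights, `weekend_day` for Saturday/Sunday wake days).
#' @export
segment_days <- function(intervals, wrist, opts = align_opts()) {
  ids <- unique(intervals$participant_id)
  out <- lapply(ids, function(id) {
    iv <- intervals %>% filter(.data$participant_id == id) %>% arrange(.data$onset)
    ep <- wrist %>% filter(.data$participant_id == id)
    segment_days_one(iv, ep, opts)
  })
  list_rbind(out)
}

segment_days_one <- function(iv, ep, opts) {
  mains <- iv %>%
    filter(.data$role == "main", .data$valid, !is.na(.data$onset)) %>%
    arrange(.data$date)
  if (nrow(mains) == 0) return(empty_person_day_skeleton())
  stream_end <- max(ep$timestamp) + .EPOCH_SEC
  rows <- list()
  for (r in seq_len(nrow(mains))) {
    night <- mains[r, ]
    nxt <- mains %>% filter(.data$date == night$date + 1)
    if (nrow(nxt) == 1) {
      day_end <- nxt$onset[1]
      forced <- FALSE
    } else {
      limit <- if (r < nrow(mains)) mains$onset[r + 1] else stream_end
      day_end <- forced_day_end(iv, ep, night$offset, limit, opts)
      forced <- TRUE
    }
    M <- as.POSIXct(night$date + 1, tz = .tz)
    rows[[length(rows) + 1L]] <- tibble(
      participant_id = night$participant_id,
      date = night$date,
      day_start = night$onset,
      day_end = day_end,
      day_length_h = as.numeric(difftime(day_end, night$onset, units = "hours")),
      forced_end = forced,
      onset_h = as.numeric(difftime(night$onset, M, units = "hours")),
      offset_h = as.numeric(difftime(night$offset, M, units = "hours")),
      duration_min = night$duration_min,
      sme_pct = night$sme_pct,
      offset_time = night$offset,
      weekend_night = lubridate::wday(night$date, week_start = 1) %in% c(5L, 6L),
      weekend_day = lubridate::wday(as.Date(night$offset, tz = .tz),
                                    week_start = 1) %in% c(6L, 7L)
    )
  }
  list_rbind(rows)
}

forced_day_end <- function(iv, ep, from, limit, opts) {
  cands <- as.POSIXct(numeric(0), tz = .tz)
  off <- if ("offwrist" %in% names(ep)) ep$offwrist > 0 else rep(FALSE, nrow(ep))
  runs <- runs_of(off)
  runs <- runs %>% filter(.data$len > opts$forced_offwrist_min * 60 / .EPOCH_SEC)
  if (nrow(runs)) {
    st <- ep$timestamp[runs$start]
    st <- st[st > from & st < limit]
    cands <- c(cands, st)
  }
  app <- iv %>% filter(.data$onset > from, .data$onset < limit, !is.na(.data$onset))
  if (nrow(app)) cands <- c(cands, app$onset)
  if (length(cands)) min(cands) else limit
}

empty_person_day_skeleton <- function() {
  tibble(participant_id = character(), date = as.Date(character()),
         day_start = as.POSIXct(character(), tz = .tz),
         day_end = as.POSIXct(character(), tz = .tz),
         day_length_h = numeric(), forced_end = logical(),
         onset_h = numeric(), offset_h = numeric(), duration_min = numeric(),
         sme_pct = numeric(), offset_time = as.POSIXct(character(), tz = .tz),
         weekend_night = logical(), weekend_day = logical())
}

# nap intervals of one participant clipped to [a, b)
naps_in_window <- function(iv, a, b) {
  iv %>%
    filter(.data$role == "nap", .data$offset > a, .data$onset < b) %>%
    mutate(onset = pmax(.data$onset, a), offset = pmin(.data$offset, b))
}

#' Merge classified minutes into a day's activity totals
#'
#' Counts MVPA and sedentary minutes within the wake portion of a day
#' (sleep offset to day end); sedentary minutes overlapping any scored
#' nap interval do not count towards sedentary time.
#'
#' @param day One person-day skeleton row (from [segment_days()]).
#' @param minutes Minute label table for the participant.
#' @param naps Nap intervals (`onset`/`offset`) of the participant.
#' @return A list with `mvpa_min`, `sedentary_min`, `nonwear_min`,
#'   `wake_min`, `nap_min`.
#' @export
merge_minutes <- function(day, minutes, naps) {
  a <- day$offset_time
  b <- day$day_end
  mm <- minutes %>% filter(.data$minute_start >= a, .data$minute_start < b)
  in_nap <- rep(FALSE, nrow(mm))
  if (nrow(naps)) {
    for (j in seq_len(nrow(naps))) {
      in_nap <- in_nap | (mm$minute_start >= naps$onset[j] &
                            mm$minute_start < naps$offset[j])
    }
  }
  wake_min <- as.numeric(difftime(b, a, units = "mins"))
  nap_min <- if (nrow(naps)) sum(overlap_len(naps$onset, naps$offset, a, b)) / 60 else 0
  list(
    mvpa_min = sum(mm$class3 == "MVPA" & !mm$nonwear, na.rm = TRUE),
    sedentary_min = sum(mm$class3 == "sedentary" & !mm$nonwear & !in_nap,
                        na.rm = TRUE),
    nonwear_min = sum(mm$nonwear & !in_nap),
    wake_min = wake_min,
    nap_min = nap_min
  )
}

#' Validate a physical-activity day
#'
#' A day's activity totals are invalid when more than 25% of its wake
#' portion is non-wear, or when a forced-ended day is shorter than 20
#' hours.
#'
#' @param day Person-day row with `forced_end` and `day_length_h`.
#' @param nonwear_min,wake_min,nap_min Minutes from [merge_minutes()].
#' @param opts An [align_opts()] object.
#' @return A list with `valid_pa` (logical) and `nonwear_pct`.
#' @export
validate_pa_day <- function(day, nonwear_min, wake_min, nap_min,
                            opts = align_opts()) {
  denom <- if (opts$nap_in_denominator) wake_min else wake_min - nap_min
  pct <- if (denom > 0) 100 * nonwear_min / denom else 100
  valid <- pct <= opts$max_nonwear_pct
  if (day$forced_end && day$day_length_h < opts$min_forced_day_h) valid <- FALSE
  list(valid_pa = valid, nonwear_pct = pct)
}

#' Densest two-hour MVPA cluster of a day
#'
#' Slides a 120-minute window in 1-minute steps across the daytime span
#' (sleep offset to the day's end) and finds the window containing the
#' most MVPA minutes; ties go to the earliest window. Returns the window
#' center (or the centroid of its MVPA minutes under
#' `cluster_rule = "centroid"`) and the minute count.
#'
#' @param day Person-day row.
#' @param minutes Minute label table for the participant.
#' @param opts An [align_opts()] object.
#' @return A list with `midpoint` (POSIXct or `NA` when the daytime span
#'   is shorter than the window), `cluster_mvpa_min`, and the maximizing
#'   window bounds `win_start`/`win_end`.
#' @export
mvpa_cluster <- function(day, minutes, opts = align_opts()) {
  a <- day$offset_time
  b <- day$day_end
  W <- opts$cluster_window_min
  L <- floor(as.numeric(difftime(b, a, units = "mins")))
  if (L < W) {
    return(list(midpoint = as.POSIXct(NA, tz = .tz),
                cluster_mvpa_min = NA_real_,
                win_start = as.POSIXct(NA, tz = .tz),
                win_end = as.POSIXct(NA, tz = .tz)))
  }
  grid <- a + 60 * (seq_len(L) - 1L)
  mm <- minutes %>%
    filter(.data$minute_start >= a, .data$minute_start < b,
           !is.na(.data$class3), .data$class3 == "MVPA", !.data$nonwear)
  ind <- as.integer(grid %in% mm$minute_start)
  cs <- c(0, cumsum(ind))
  win_counts <- cs[(W + 1):(L + 1)] - cs[1:(L - W + 1)]
  k <- which.max(win_counts)   # earliest maximum
  win_start <- grid[k]
  win_end <- win_start + W * 60
  midpoint <- if (opts$cluster_rule == "window_center" || win_counts[k] == 0) {
    win_start + W * 30
  } else {
    in_win <- mm$minute_start[mm$minute_start >= win_start &
                                mm$minute_start < win_end]
    as.POSIXct(mean(as.numeric(in_win) + 30), origin = "1970-01-01", tz = .tz)
  }
  list(midpoint = midpoint, cluster_mvpa_min = as.numeric(win_counts[k]),
       win_start = win_start, win_end = win_end)
}

#' Daytime and cluster-window mean light levels
#'
#' Arithmetic means of white-light lux over worn wrist epochs in the
#' daytime span and in the densest-MVPA-cluster window.
#'
#' @param day Person-day row.
#' @param wrist Wrist epochs of the participant (with `lux`).
#' @param win_start,win_end Cluster window bounds (may be `NA`).
#' @return A list with `lux_day_mean` and `lux_cluster_mean` (`NA` when
#'   every epoch in the window is off-wrist or the window is missing).
#' @export
light_means <- function(day, wrist, win_start, win_end) {
  worn_mean <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    seg <- wrist %>% filter(.data$timestamp >= a, .data$timestamp < b,
                            .data$offwrist == 0)
    if (nrow(seg) == 0) NA_real_ else mean(seg$lux)
  }
  list(lux_day_mean = worn_mean(day$offset_time, day$day_end),
       lux_cluster_mean = worn_mean(win_start, win_end))
}

#' Build the person-day analysis table
#'
#' Driver combining [segment_days()], [merge_minutes()],
#' [validate_pa_day()], [mvpa_cluster()] and [light_means()] into the
#' single table consumed by the modelling stage.
#'
#' @param intervals Scored sleep intervals ([score_sleep()]).
#' @param minutes Minute label table ([classify_activity()]).
#' @param wrist Wrist epoch tibble.
#' @param opts An [align_opts()] object.
#' @return A tibble with one row per person-day (see [segment_days()] for
#'   the skeleton columns) plus `mvpa_min`, `sedentary_min`,
#'   `nonwear_pct`, `valid_pa`, `cluster_midpoint`, `cluster_mvpa_min`,
#'   `lux_day_mean`, `lux_cluster_mean`.
#' @export
build_person_days <- function(intervals, minutes, wrist, opts = align_opts()) {
  skel <- segment_days(intervals, wrist, opts)
  if (nrow(skel) == 0) {
    return(skel %>% mutate(mvpa_min = numeric(), sedentary_min = numeric(),
                           nonwear_pct = numeric(), valid_pa = logical(),
                           cluster_midpoint = as.POSIXct(character(), tz = .tz),
                           cluster_mvpa_min = numeric(),
                           lux_day_mean = numeric(), lux_cluster_mean = numeric()))
  }
  rows <- lapply(seq_len(nrow(skel)), function(r) {
    day <- skel[r, ]
    id <- day$participant_id
    iv <- intervals %>% filter(.data$participant_id == id)
    mm <- minutes %>% filter(.data$participant_id == id)
    ep <- wrist %>% filter(.data$participant_id == id)
    naps <- naps_in_window(iv, day$offset_time, day$day_end)
    tot <- merge_minutes(day, mm, naps)
    v <- validate_pa_day(day, tot$nonwear_min, tot$wake_min, tot$nap_min, opts)
    cl <- mvpa_cluster(day, mm, opts)
    lx <- light_means(day, ep, cl$win_start, cl$win_end)
    day %>% mutate(
      mvpa_min = tot$mvpa_min, sedentary_min = tot$sedentary_min,
      nonwear_pct = v$nonwear_pct, valid_pa = v$valid_pa,
      cluster_midpoint = cl$midpoint, cluster_mvpa_min = cl$cluster_mvpa_min,
      lux_day_mean = lx$lux_day_mean, lux_cluster_mean = lx$lux_cluster_mean
    )
  })
  list_rbind(rows)
}

#' Apply the cohort inclusion rules
#'
#' Keeps participants with at least `min_consecutive_sleep` consecutive
#' valid sleep days and at least `min_pa_days` valid physical-activity
#' days, optionally restricted by season of the first valid actigraphy
#' day (school year = September through May).
#'
#' @param person_days Person-day table from [build_person_days()].
#' @param intervals Scored sleep intervals (for day-level sleep validity).
#' @param season `"all"`, `"school_year"` or `"summer"`.
#' @param min_consecutive_sleep,min_pa_days Inclusion thresholds (3, 3).
#' @return The filtered person-day table.
#' @export
filter_participants <- function(person_days, intervals,
                                season = c("all", "school_year", "summer"),
                                min_consecutive_sleep = 3,
                                min_pa_days = 3) {
  season <- match.arg(season)
  keep <- intervals %>%
    filter(.data$role == "main", .data$valid) %>%
    group_by(.data$participant_id) %>%
    summarise(
      max_consec = max_consecutive_run(sort(unique(.data$date))),
      first_valid = min(.data$date),
      .groups = "drop"
    ) %>%
    filter(.data$max_consec >= min_consecutive_sleep)
  if (season != "all") {
    sch <- lubridate::month(keep$first_valid) %in% c(9:12, 1:5)
    keep <- keep[if (season == "school_year") sch else !sch, ]
  }
  pa_ok <- person_days %>%
    filter(.data$valid_pa) %>%
    count(.data$participant_id) %>%
    filter(.data$n >= min_pa_days)
  person_days %>%
    filter(.data$participant_id %in% keep$participant_id,
           .data$participant_id %in% pa_ok$participant_id)
}

max_consecutive_run <- function(dates) {
  if (length(dates) == 0) return(0L)
  gaps <- c(1L, as.integer(diff(dates)))
  runs <- rle(gaps == 1L)
  # a run of m consecutive unit gaps spans m dates but begins a new run at
  # each break; count dates per maximal chain
  chain <- 1L
  best <- 1L
  for (g in gaps[-1]) {
    chain <- if (g == 1L) chain + 1L else 1L
    best <- max(best, chain)
  }
  best
}

#' Stratify to participants with meaningful MVPA clusters
#'
#' Keeps participants whose mean densest-cluster MVPA across days is at
#' least `min_cluster_min` minutes (exercise-bout guideline threshold).
#'
#' @param person_days Person-day table with `cluster_mvpa_min`.
#' @param min_cluster_min Threshold in minutes (10).
#' @return The stratified person-day table.
#' @export
cluster_sample_strata <- function(person_days, min_cluster_min = 10) {
  keep <- person_days %>%
    group_by(.data$participant_id) %>%
    summarise(m = mean(.data$cluster_mvpa_min, na.rm = TRUE), .groups = "drop") %>%
    filter(!is.na(.data$m), .data$m >= min_cluster_min)
  person_days %>% filter(.data$participant_id %in% keep$participant_id)
}
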