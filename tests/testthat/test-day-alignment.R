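# Sleep-onset-anchored day construction, daily totals, cluster statistic
# and inclusion rules.

TZ <- "UTC"
ts <- function(x) lubridate::ymd_hms(x, tz = TZ)

mk_main <- function(onsets, offsets, id = "P001", valid = TRUE) {
  onsets <- ts(onsets); offsets <- ts(offsets)
  tibble::tibble(
    participant_id = id,
    date = as.Date(onsets - 12 * 3600, tz = TZ),
    role = "main",
    onset = onsets, offset = offsets,
    duration_min = as.numeric(difftime(offsets, onsets, units = "mins")),
    sleep_min = 0.92 * as.numeric(difftime(offsets, onsets, units = "mins")),
    sme_pct = 92, valid = valid, reason = ifelse(valid, "ok", "offwrist_total")
  )
}

mk_worn_wrist <- function(from, to, id = "P001") {
  t0 <- ts(from); t1 <- ts(to)
  n <- as.numeric(difftime(t1, t0, units = "secs")) / 30
  tibble::tibble(participant_id = id, timestamp = t0 + 30 * (seq_len(n) - 1L),
                 counts = 100L, offwrist = 0L, lux = 150)
}

test_that("day lengths follow the onset-to-onset definition", {
  iv <- mk_main(c("2023-10-02 22:00:00", "2023-10-03 23:30:00"),
                c("2023-10-03 07:00:00", "2023-10-04 07:30:00"))
  wr <- mk_worn_wrist("2023-10-02 18:00:00", "2023-10-04 09:00:00")
  days <- segment_days(iv, wr)
  expect_equal(days$day_length_h[1], 25.5)
  expect_equal(days$onset_h[1], -2.0)      # 22:00 midnight-centered
  expect_false(days$forced_end[1])

  iv2 <- mk_main(paste0("2023-10-0", 2:5, " 23:00:00"),
                 paste0("2023-10-0", 3:6, " 07:00:00"))
  wr2 <- mk_worn_wrist("2023-10-02 18:00:00", "2023-10-06 09:00:00")
  d2 <- segment_days(iv2, wr2)
  expect_equal(d2$day_length_h[1:3], rep(24, 3))
  # sum of non-forced day lengths equals the anchor span
  expect_equal(sum(d2$day_length_h[1:3]) * 3600,
               as.numeric(ts("2023-10-05 23:00:00")) -
                 as.numeric(ts("2023-10-02 23:00:00")))
  # midnight-centered encoding: 00:04 -> +0.067
  iv3 <- mk_main("2023-10-03 00:04:00", "2023-10-03 07:49:00")
  d3 <- segment_days(iv3, mk_worn_wrist("2023-10-02 18:00:00",
                                        "2023-10-03 12:00:00"))
  expect_equal(round(d3$onset_h, 3), 0.067)
  expect_equal(round(d3$offset_h, 2), 7.82)
})

test_that("days without a terminating main sleep are force-ended correctly", {
  iv <- mk_main(c("2023-10-02 23:00:00", "2023-10-04 23:00:00"),
                c("2023-10-03 07:00:00", "2023-10-05 07:00:00"))
  wr <- mk_worn_wrist("2023-10-02 18:00:00", "2023-10-05 09:00:00")
  # a 70-min off-wrist block at 21:00 on the invalid night
  sel <- wr$timestamp >= ts("2023-10-03 21:00:00") &
    wr$timestamp < ts("2023-10-03 22:10:00")
  wr$offwrist[sel] <- 1L
  d <- segment_days(iv, wr)
  expect_true(d$forced_end[1])
  expect_equal(d$day_end[1], ts("2023-10-03 21:00:00"))

  # an apparent sleep interval arriving earlier wins
  iv2 <- dplyr::bind_rows(iv, mk_main("2023-10-03 20:00:00",
                                      "2023-10-03 22:30:00", valid = FALSE) %>%
                            dplyr::mutate(role = "nap"))
  d2 <- segment_days(iv2, wr)
  expect_equal(d2$day_end[1], ts("2023-10-03 20:00:00"))

  # no off-wrist, no apparent sleep: the day runs to the recording end
  d3 <- segment_days(iv[1, ], mk_worn_wrist("2023-10-02 18:00:00",
                                            "2023-10-03 20:00:00"))
  expect_true(d3$forced_end[1])
  expect_equal(d3$day_end[1], ts("2023-10-03 20:00:00"))
})

test_that("nap minutes are excluded from sedentary totals by overlap", {
  day <- tibble::tibble(offset_time = ts("2023-10-03 07:00:00"),
                        day_end = ts("2023-10-03 23:00:00"))
  sed_block <- tibble::tibble(
    participant_id = "P001",
    minute_start = ts("2023-10-03 14:00:00") + 60 * (0:59),
    raw_class = "sedentary", class3 = "sedentary", nonwear = FALSE)
  # nap fully covering the block
  naps_full <- tibble::tibble(onset = ts("2023-10-03 13:30:00"),
                              offset = ts("2023-10-03 15:30:00"))
  expect_equal(merge_minutes(day, sed_block, naps_full)$sedentary_min, 0)
  # no naps: raw count
  expect_equal(merge_minutes(day, sed_block, naps_full[0, ])$sedentary_min, 60)
  # half-overlapping 60-min nap: 30 minutes counted
  naps_half <- tibble::tibble(onset = ts("2023-10-03 14:30:00"),
                              offset = ts("2023-10-03 15:30:00"))
  expect_equal(merge_minutes(day, sed_block, naps_half)$sedentary_min, 30)
})

test_that("physical-activity day validity trips at the stated rules", {
  day_ok <- tibble::tibble(forced_end = FALSE, day_length_h = 24)
  expect_true(validate_pa_day(day_ok, nonwear_min = 0, wake_min = 960,
                              nap_min = 0)$valid_pa)
  v26 <- validate_pa_day(day_ok, nonwear_min = 0.26 * 960, wake_min = 960,
                         nap_min = 0)
  expect_false(v26$valid_pa)
  expect_equal(round(v26$nonwear_pct), 26)
  expect_true(validate_pa_day(day_ok, nonwear_min = 0.25 * 960,
                              wake_min = 960, nap_min = 0)$valid_pa)
  day_forced <- tibble::tibble(forced_end = TRUE, day_length_h = 19.5)
  expect_false(validate_pa_day(day_forced, 0, 700, 0)$valid_pa)
  day_forced_ok <- tibble::tibble(forced_end = TRUE, day_length_h = 21)
  expect_true(validate_pa_day(day_forced_ok, 0, 800, 0)$valid_pa)
})

mk_mvpa_minutes <- function(mvpa_starts_min, day_offset, id = "P001") {
  tibble::tibble(
    participant_id = id,
    minute_start = day_offset + 60 * mvpa_starts_min,
    raw_class = "walking", class3 = "MVPA", nonwear = FALSE)
}

test_that("the densest two-hour MVPA cluster follows the window rules", {
  off <- ts("2023-10-03 08:00:00")
  day <- tibble::tibble(offset_time = off, day_end = ts("2023-10-03 23:00:00"))
  # 45 MVPA minutes at 16:00-16:45 (480..524 minutes after offset)
  m45 <- mk_mvpa_minutes(480:524, off)
  cl <- mvpa_cluster(day, m45)
  expect_equal(cl$cluster_mvpa_min, 45)
  grid_mvpa <- as.integer((off + 60 * (0:899)) %in% m45$minute_start)
  want <- oracle_cluster(grid_mvpa)
  expect_equal(cl$win_start, off + 60 * (want$start - 1))
  expect_equal(cl$midpoint, cl$win_start + 60 * 60)

  # zero MVPA: zero minutes, earliest window center (flagged degenerate)
  cl0 <- mvpa_cluster(day, m45[0, ])
  expect_equal(cl0$cluster_mvpa_min, 0)
  expect_equal(cl0$midpoint, off + 60 * 60)

  # two equal 20-min bouts: the earliest window wins
  m2 <- mk_mvpa_minutes(c(60:79, 600:619), off)
  cl2 <- mvpa_cluster(day, m2)
  expect_equal(cl2$cluster_mvpa_min, 20)
  expect_lte(cl2$win_start, off + 60 * 60)

  # daytime span shorter than the window: no cluster
  short <- tibble::tibble(offset_time = off, day_end = off + 100 * 60)
  expect_true(is.na(mvpa_cluster(short, m45)$midpoint))

  # exhaustive-window equivalence on random days
  set.seed(77)
  for (k in 1:200) {
    L <- sample(120:600, 1)
    ind <- rbinom(L, 1, runif(1, 0, 0.2))
    dayk <- tibble::tibble(offset_time = off, day_end = off + L * 60)
    mk <- tibble::tibble(participant_id = "P001",
                         minute_start = off + 60 * (which(ind == 1) - 1L),
                         raw_class = "walking", class3 = "MVPA", nonwear = FALSE)
    got <- mvpa_cluster(dayk, mk)
    want <- oracle_cluster(ind)
    expect_equal(got$cluster_mvpa_min, want$count)
    expect_equal(got$win_start, off + 60 * (want$start - 1))
  }
})

test_that("light means average worn epochs over the right windows", {
  off <- ts("2023-10-03 08:00:00")
  day <- tibble::tibble(offset_time = off, day_end = off + 8 * 3600)
  wr <- mk_worn_wrist("2023-10-03 07:00:00", "2023-10-03 17:00:00")
  wr$lux <- 200
  lm1 <- light_means(day, wr, off + 3600, off + 3600 + 7200)
  expect_equal(lm1$lux_day_mean, 200)
  expect_equal(lm1$lux_cluster_mean, 200)
  # half 0 / half 400 during the daytime
  wr2 <- wr
  half <- wr2$timestamp >= off & wr2$timestamp < off + 4 * 3600
  wr2$lux[half] <- 0
  wr2$lux[wr2$timestamp >= off + 4 * 3600] <- 400
  expect_equal(light_means(day, wr2, NA, NA)$lux_day_mean, 200)
  # missing cluster window
  expect_true(is.na(light_means(day, wr, NA, NA)$lux_cluster_mean))
  # all off-wrist in window
  wr3 <- wr
  wr3$offwrist <- 1L
  expect_true(is.na(light_means(day, wr3, off, off + 3600)$lux_day_mean))
})

test_that("inclusion rules require consecutive sleep days and enough PA days", {
  mk_pd <- function(id, dates, valid_pa = TRUE) {
    tibble::tibble(participant_id = id, date = as.Date(dates),
                   valid_pa = valid_pa, cluster_mvpa_min = 12)
  }
  iv_ok <- mk_main(paste("2023-10-0", 2:8, " 23:00:00", sep = ""),
                   paste("2023-10-0", 3:9, " 07:00:00", sep = ""))
  pd_ok <- mk_pd("P001", as.Date("2023-10-02") + 0:6)
  kept <- filter_participants(pd_ok, iv_ok)
  expect_equal(nrow(kept), 7L)

  # valid sleep days {1,2,4,5}: longest consecutive run is 2 -> excluded
  iv_gap <- mk_main(c("2023-10-02 23:00:00", "2023-10-03 23:00:00",
                      "2023-10-05 23:00:00", "2023-10-06 23:00:00"),
                    c("2023-10-03 07:00:00", "2023-10-04 07:00:00",
                      "2023-10-06 07:00:00", "2023-10-07 07:00:00"))
  pd_gap <- mk_pd("P001", as.Date(c("2023-10-02", "2023-10-03",
                                    "2023-10-05", "2023-10-06")))
  expect_equal(nrow(filter_participants(pd_gap, iv_gap)), 0L)

  # too few valid PA days
  pd_pa <- mk_pd("P001", as.Date("2023-10-02") + 0:6,
                 valid_pa = c(TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(nrow(filter_participants(pd_pa, iv_ok)), 0L)

  # school-year filter: July start excluded, October start kept
  iv_jul <- mk_main(paste0("2023-07-0", 2:6, " 23:00:00"),
                    paste0("2023-07-0", 3:7, " 07:00:00"))
  pd_jul <- mk_pd("P001", as.Date("2023-07-02") + 0:4)
  expect_equal(nrow(filter_participants(pd_jul, iv_jul,
                                        season = "school_year")), 0L)
  expect_equal(nrow(filter_participants(pd_jul, iv_jul, season = "summer")), 5L)
  expect_equal(nrow(filter_participants(pd_ok, iv_ok,
                                        season = "school_year")), 7L)
})

test_that("cluster stratification uses the 10-minute average boundary", {
  pd <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), each = 2),
    cluster_mvpa_min = c(9.8, 10.0, 10.0, 10.0, 0, 0))
  kept <- cluster_sample_strata(pd)
  expect_setequal(unique(kept$participant_id), "B")   # A averages 9.9
  none <- cluster_sample_strata(pd %>% dplyr::mutate(cluster_mvpa_min = 0))
  expect_equal(nrow(none), 0L)
})

test_that("merged daily totals equal ground truth on a clean cohort", {
  cfg <- synth_config_clean(n_participants = 2, n_days = 4, seed = 91)
  b <- run_pipeline(cfg, classifier = "oracle", fit_models = FALSE)
  pd <- b$person_days %>% dplyr::filter(!forced_end) %>%
    dplyr::arrange(participant_id, date)
  td <- b$truth$days %>%
    dplyr::mutate(date = date - 1) %>%
    dplyr::semi_join(pd, by = c("participant_id", "date")) %>%
    dplyr::arrange(participant_id, date)
  expect_equal(nrow(pd), 2 * 4)
  expect_equal(pd$mvpa_min, td$mvpa_min)
  expect_equal(pd$sedentary_min, td$sedentary_min)
})
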