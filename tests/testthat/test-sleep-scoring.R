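# Count-threshold sleep scoring rules against worked examples and the
# brute-force scan oracle.

test_that("onset rule matches worked examples under both epoch conventions", {
  ep <- wrist_series(c(50, 30, 12, 0, 0, 0, 0, 0, 0, 0))
  # literal rule: last active epoch (count 12) at 23:01:00
  expect_equal(score_onset(ep, sleep_opts(onset_epoch = "active")),
               lubridate::ymd_hms("2023-10-02 23:01:00", tz = "UTC"))
  # immobility-start convention: one epoch later
  expect_equal(score_onset(ep, sleep_opts(onset_epoch = "quiet")),
               lubridate::ymd_hms("2023-10-02 23:01:30", tz = "UTC"))

  # a quiet run of only 4 epochs does not qualify
  ep2 <- wrist_series(c(40, 0, 0, 0, 0, 20, 0, 0, 0, 0, 0, 30))
  expect_equal(score_onset(ep2, sleep_opts(onset_epoch = "active")),
               ep2$timestamp[6])

  # vacuous antecedent: no active epoch precedes quiescence
  ep3 <- wrist_series(rep(3, 20))
  expect_true(is.na(score_onset(ep3)))
  # segment shorter than 6 epochs
  expect_true(is.na(score_onset(wrist_series(c(50, 0, 0, 0, 0)))))
})

test_that("offset rule matches worked examples and mirrors onset", {
  ep <- wrist_series(c(60, 0, 0, 0, 0, 0, 35, 60, 40))
  expect_equal(score_offset(ep), ep$timestamp[7])
  # quiet tail never broken: no offset
  expect_true(is.na(score_offset(wrist_series(c(60, 0, 0, 0, 0, 0, 0)))))
  # time-reversal: offset of x equals the mirrored active-onset of rev(x)
  set.seed(11)
  for (k in 1:50) {
    counts <- sample(c(0, 0, 0, 5, 12, 40, 200), 40, replace = TRUE)
    ep <- wrist_series(counts)
    off <- score_offset(ep)
    on_rev <- oracle_onset_idx(rev(counts), convention = "active")
    if (is.na(on_rev)) {
      expect_true(is.na(off))
    } else {
      expect_equal(off, ep$timestamp[length(counts) + 1L - on_rev])
    }
  }
})

test_that("onset/offset agree with the exhaustive scan oracle on random series", {
  set.seed(202)
  for (k in 1:200) {
    n <- sample(8:120, 1)
    counts <- sample(c(0, 1, 4, 9, 10, 11, 15, 80, 300), n, replace = TRUE,
                     prob = c(.3, .1, .1, .05, .05, .05, .1, .15, .1))
    off <- rbinom(n, 1, 0.05)
    ep <- wrist_series(counts, offwrist = off)
    oi <- oracle_onset_idx(counts, off, convention = "active")
    got <- score_onset(ep, sleep_opts(onset_epoch = "active"))
    expect_identical(is.na(got), is.na(oi))
    if (!is.na(oi)) expect_equal(got, ep$timestamp[oi])
    fi <- oracle_offset_idx(counts, off)
    gotf <- score_offset(ep)
    expect_identical(is.na(gotf), is.na(fi))
    if (!is.na(fi)) expect_equal(gotf, ep$timestamp[fi])
  }
})

test_that("awakenings of an hour or more split an interval; shorter ones do not", {
  # 8 h rest: 2 h sleep, block, then sleep to the end
  mk_rest <- function(wake_min) {
    c(rep(100, 4),                 # active flank
      rep(0, 240),                 # 2 h sleep
      rep(80, wake_min * 2),       # wake block
      rep(0, 480),                 # 4 h sleep
      rep(100, 4))
  }
  two <- split_intervals(wrist_series(mk_rest(70)))
  expect_equal(nrow(two), 2L)
  one <- split_intervals(wrist_series(mk_rest(50)))
  expect_equal(nrow(one), 1L)
  none <- split_intervals(wrist_series(c(rep(100, 3), rep(0, 480), rep(100, 3))))
  expect_equal(nrow(none), 1L)
})

test_that("main sleep selection follows the nighttime-window rule", {
  d <- as.Date("2023-10-02")
  mk <- function(s1, e1, s2, e2) {
    tibble::tibble(
      onset = lubridate::ymd_hms(paste(c(s1, s2)), tz = "UTC"),
      offset = lubridate::ymd_hms(paste(c(e1, e2)), tz = "UTC")
    )
  }
  iv <- mk("2023-10-02 23:00:00", "2023-10-03 07:00:00",
           "2023-10-02 14:00:00", "2023-10-02 15:00:00")
  expect_equal(select_main_sleep(iv, d), 1L)
  # two window-overlapping intervals: total duration decides
  iv2 <- mk("2023-10-02 22:30:00", "2023-10-03 02:00:00",
            "2023-10-03 03:00:00", "2023-10-03 07:30:00")
  expect_equal(select_main_sleep(iv2, d), 2L)
  # a single daytime nap only: no main sleep
  iv3 <- tibble::tibble(
    onset = lubridate::ymd_hms("2023-10-02 13:00:00", tz = "UTC"),
    offset = lubridate::ymd_hms("2023-10-02 14:00:00", tz = "UTC"))
  expect_true(is.na(select_main_sleep(iv3, d)))
})

test_that("sleep/wake labelling yields the expected maintenance efficiency", {
  start <- lubridate::ymd_hms("2023-10-02 23:00:00", tz = "UTC")
  counts <- rep(0, 960)                       # 480 min all quiet
  ep <- wrist_series(counts)
  sw <- score_sleep_wake(ep, start, start + 480 * 60)
  expect_equal(sw$sme_pct, 100)
  expect_equal(sw$sleep_min, sw$duration_min)

  counts[101:180] <- 50                        # 40 min of wake epochs
  ep2 <- wrist_series(counts)
  sw2 <- score_sleep_wake(ep2, start, start + 480 * 60)
  expect_equal(sw2$sleep_min, 440)
  expect_equal(round(sw2$sme_pct, 1), 91.7)

  # efficiency is monotone non-increasing as the wake threshold drops
  set.seed(33)
  ep3 <- wrist_series(sample(0:60, 960, replace = TRUE))
  effs <- vapply(c(40, 20, 10, 5, 0), function(th) {
    score_sleep_wake(ep3, start, start + 480 * 60,
                     sleep_opts(count_threshold = th))$sme_pct
  }, numeric(1))
  expect_true(all(diff(effs) <= 0))
})

test_that("sleep-day validity rules fire at their stated boundaries", {
  start <- lubridate::ymd_hms("2023-10-02 12:00:00", tz = "UTC")
  n <- 2880                                    # 24 h of 30-s epochs
  onset <- lubridate::ymd_hms("2023-10-02 23:30:00", tz = "UTC")
  offset <- lubridate::ymd_hms("2023-10-03 07:30:00", tz = "UTC")
  base <- tibble::tibble(
    participant_id = "P001",
    timestamp = start + 30 * (seq_len(n) - 1L),
    counts = 100L, offwrist = 0L, lux = 100
  )
  expect_true(validate_sleep_day(base, onset, offset)$valid)

  # 239 minutes off-wrist on a middle day: still valid
  d239 <- base
  d239$offwrist[1:478] <- 1L
  expect_true(validate_sleep_day(d239, onset, offset)$valid)
  d240 <- base
  d240$offwrist[1:480] <- 1L
  v <- validate_sleep_day(d240, onset, offset)
  expect_false(v$valid)
  expect_equal(v$reason, "offwrist_total")
  # ... but first/last days are exempt from the 4-hour rule
  expect_true(validate_sleep_day(d240, onset, offset, is_last = TRUE)$valid)

  # 60-min off-wrist run ending 5 min before scored onset
  dedge <- base
  run_end <- onset - 5 * 60
  sel <- dedge$timestamp >= run_end - 60 * 60 & dedge$timestamp < run_end
  dedge$offwrist[sel] <- 1L
  v2 <- validate_sleep_day(dedge, onset, offset)
  expect_false(v2$valid)
  expect_equal(v2$reason, "offwrist_near_sleep")

  # first-day wear rule: < 2 h worn before onset
  dfirst <- base
  dfirst$offwrist[dfirst$timestamp < onset - 90 * 60] <- 1L
  expect_false(validate_sleep_day(dfirst, onset, offset, is_first = TRUE)$valid)

  expect_false(validate_sleep_day(base, as.POSIXct(NA), as.POSIXct(NA))$valid)
})

test_that("clean synthetic nights are scored at the true instants", {
  cfg <- synth_config_clean(n_participants = 2, n_days = 4, seed = 51)
  coh <- generate_cohort(cfg)
  iv <- score_sleep(coh$wrist) %>% dplyr::filter(role == "main")
  td <- coh$truth$days %>% dplyr::arrange(participant_id, night)
  expect_equal(nrow(iv), nrow(td))
  expect_true(all(iv$onset == td$onset_time))
  expect_true(all(iv$offset == td$offset_time))
  expect_lt(max(abs(iv$sme_pct - td$sme_pct)), 1e-9)
})

test_that("default-noise cohorts score onset/offset within one epoch", {
  cfg <- synth_config(3, n_days = 5, seed = 77)
  coh <- generate_cohort(cfg)
  iv <- score_sleep(coh$wrist) %>%
    dplyr::filter(role == "main", !is.na(onset))
  td <- coh$truth$days
  # interval rows carry the cut-point date the night starts on; truth rows
  # carry the wake-day date (one later)
  m <- dplyr::inner_join(
    iv, td %>% dplyr::mutate(date = date - 1),
    by = c("participant_id", "date"),
    suffix = c("", "_true")
  )
  expect_gt(nrow(m), 0.9 * nrow(td))
  don <- abs(as.numeric(m$onset) - as.numeric(m$onset_time))
  doff <- abs(as.numeric(m$offset) - as.numeric(m$offset_time))
  expect_gte(mean(don <= 30 & doff <= 30), 0.99)
})
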