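# Synthetic dual-device cohort generation.
#
# Two entry points share one RNG discipline: the global seed seeds a
# master stream from which one well-mixed sub-seed per participant is
# drawn; participant i then draws everything from set.seed(sub_seed[i]).
# The day-level structural draws are a fixed prefix of that substream, so
# simulate_daily_truth() yields byte-identical daily outcomes whether or
# not the epoch streams are rendered afterwards by generate_cohort().
# Sub-seeds are drawn through the RNG rather than computed as seed + i
# or another arithmetic mix: integer seeds that form arithmetic families
# produce measurably cross-correlated Mersenne-Twister streams, which
# breaks the independence that replicate simulations assume.

participant_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483647L, n, replace = TRUE)
}

.outcome_names <- c("onset", "offset", "sme", "mvpa", "sedentary")

# covariate category tables (population shares of the emulated cohort)
.cov_levels <- list(
  sex = c(Female = 0.53, Male = 0.47),
  race = c("White, non-Hispanic" = 0.15, "Black, non-Hispanic" = 0.43,
           "Hispanic" = 0.28, "Other" = 0.14),
  mother_education = c("Less than High School" = 0.18,
                       "High School or Equivalent" = 0.19,
                       "Some College/Technical School" = 0.48,
                       "College or Graduate School" = 0.15),
  family_structure = c("Biomother + Biofather" = 0.30,
                       "Other Living Arrangements" = 0.09,
                       "Biomother + New Partner" = 0.24,
                       "Biomother Only" = 0.37),
  income_band = c(">=300%" = 0.28, "<49%" = 0.13, "50-99%" = 0.17,
                  "100-199%" = 0.28, "200-299%" = 0.14)
)

draw_covariates <- function(id) {
  draw1 <- function(tbl) {
    factor(sample(names(tbl), 1L, prob = tbl), levels = names(tbl))
  }
  tibble::new_tibble(list(
    participant_id = id,
    sex = draw1(.cov_levels$sex),
    age = round(rnorm(1, 15.5, 0.6), 1),
    race = draw1(.cov_levels$race),
    mother_education = draw1(.cov_levels$mother_education),
    family_structure = draw1(.cov_levels$family_structure),
    income_band = draw1(.cov_levels$income_band),
    bmi_pct = round(min(100, max(1, rnorm(1, 73.4, 25.1))), 1)
  ), nrow = 1L)
}

# stationary AR(1) series with marginal SD sd and lag-1 correlation rho
ar1_series <- function(n, rho, sd) {
  if (sd == 0 || n == 0) return(rep(0, n))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    z <- rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (t in 2:n) e[t] <- rho * e[t - 1] + z[t - 1]
  }
  e
}

coupling_term <- function(coupling, outcome, centered) {
  # centered: named vector of person-centered predictor values for one day
  total <- 0
  for (nm in names(coupling)) {
    parts <- strsplit(nm, "_to_", fixed = TRUE)[[1]]
    if (parts[2] == outcome && parts[1] %in% names(centered)) {
      total <- total + coupling[[nm]] * centered[[parts[1]]]
    }
  }
  total
}

# daily structural draws for one participant; assumes the RNG substream is set
person_daily_truth <- function(cfg, i) {
  id <- sprintf("P%03d", i)
  cov <- draw_covariates(id)
  male <- cov$sex == "Male"
  n_nights <- cfg$n_days + 1L

  # night t spans the evening of start_date + (t-1) into the next morning;
  # M_t is the midnight inside night t and the calendar date of wake day t
  M <- as.POSIXct(cfg$start_date, tz = .tz) + (1:n_nights) * 86400
  evening_wd <- lubridate::wday(M - 86400, week_start = 1)   # 1=Mon .. 7=Sun
  day_wd <- lubridate::wday(M, week_start = 1)
  weekend_night <- evening_wd %in% c(5L, 6L)                 # Fri/Sat nights
  weekend_day <- day_wd %in% c(6L, 7L)                       # Sat/Sun days

  u <- c(onset = rnorm(1, 0, cfg$onset_sd_between),
         offset = rnorm(1, 0, cfg$offset_sd_between),
         sme = rnorm(1, 0, cfg$sme_sd_between),
         mvpa = rnorm(1, 0, cfg$mvpa_sd_between),
         sedentary = rnorm(1, 0, cfg$sedentary_sd_between))
  rs <- cfg$resid_sd_by_outcome
  e <- lapply(setNames(.outcome_names, .outcome_names),
              function(o) ar1_series(n_nights, cfg$ar1_rho, rs[[o]]))

  wk <- cfg$weekend_effects
  sx <- cfg$sex_effects
  base <- c(onset = cfg$onset_mean, offset = cfg$offset_mean,
            sme = cfg$sme_mean, mvpa = cfg$mvpa_daily_mean,
            sedentary = cfg$sedentary_daily_mean)
  # sex and weekend enter as share-centered contrasts so the configured
  # means are the cohort's marginal means (descriptive-table emulation)
  sexdev <- as.numeric(male) - .cov_levels$sex[["Male"]]
  sexadd <- vapply(.outcome_names, function(o) sexdev * sx[[o]], numeric(1))
  wkn_share <- mean(weekend_night)
  wkd_share <- mean(weekend_day)
  # latent person means, used to center predictors when both coupling
  # directions are active (true simultaneity: realized means are unknown
  # mid-sequence)
  mu <- vapply(.outcome_names, function(o) {
    base[[o]] + sexadd[[o]] + u[[o]]
  }, numeric(1))
  mu["duration"] <- (mu[["offset"]] - mu[["onset"]]) * 60

  sleep_preds <- c("onset", "offset", "duration", "sme")
  pred_of <- vapply(names(cfg$coupling),
                    function(nm) strsplit(nm, "_to_", fixed = TRUE)[[1]][1],
                    character(1))
  sleep_drives_pa <- any(pred_of %in% sleep_preds)

  onset_h <- offset_h <- sme <- mvpa <- sed <- numeric(n_nights)
  pa_value <- function(o, t, sleep_centered) {
    base[[o]] + sexadd[[o]] + u[[o]] +
      wk[[o]] * (weekend_day[t] - wkd_share) + e[[o]][t] +
      coupling_term(cfg$coupling, o, sleep_centered)
  }
  if (!sleep_drives_pa) {
    # activity does not depend on sleep: realise the whole activity series
    # first, so the activity -> sleep coupling can be centered at the
    # *realized* person mean over the study days — the estimand the
    # within/between decomposition estimates. Only days 1..n_days feed a
    # following night (and are rendered in full), so the mean is over them.
    for (t in seq_len(n_nights)) {
      mvpa[t] <- round(min(max(pa_value("mvpa", t, NULL), 0), 240))
      sed[t] <- round(min(max(pa_value("sedentary", t, NULL), 30), 700))
    }
    pa_mean <- c(mvpa = mean(mvpa[seq_len(cfg$n_days)]),
                 sedentary = mean(sed[seq_len(cfg$n_days)]))
  } else {
    pa_mean <- c(mvpa = mu[["mvpa"]], sedentary = mu[["sedentary"]])
  }

  prev_pa_centered <- c(mvpa = 0, sedentary = 0)
  for (t in seq_len(n_nights)) {
    wkn <- weekend_night[t]
    o_raw <- base[["onset"]] + sexadd[["onset"]] + u[["onset"]] +
      wk[["onset"]] * (wkn - wkn_share) + e$onset[t] +
      coupling_term(cfg$coupling, "onset", prev_pa_centered)
    f_raw <- base[["offset"]] + sexadd[["offset"]] + u[["offset"]] +
      wk[["offset"]] * (wkn - wkn_share) + e$offset[t] +
      coupling_term(cfg$coupling, "offset", prev_pa_centered)
    o_raw <- min(max(o_raw, -5), 7)
    f_raw <- min(max(f_raw, o_raw + 3), min(o_raw + 11, 14))
    # snap instants to whole minutes; realized clock values are the truth
    onset_h[t] <- round(o_raw * 60) / 60
    offset_h[t] <- round(f_raw * 60) / 60
    s_raw <- base[["sme"]] + sexadd[["sme"]] + u[["sme"]] +
      wk[["sme"]] * (wkn - wkn_share) + e$sme[t] +
      coupling_term(cfg$coupling, "sme", prev_pa_centered)
    sme[t] <- min(max(s_raw, 70), 100)

    if (sleep_drives_pa) {
      sleep_centered <- c(
        onset = onset_h[t] - mu[["onset"]],
        offset = offset_h[t] - mu[["offset"]],
        duration = (offset_h[t] - onset_h[t]) * 60 - mu[["duration"]],
        sme = sme[t] - mu[["sme"]]
      )
      mvpa[t] <- round(min(max(pa_value("mvpa", t, sleep_centered), 0), 240))
      sed[t] <- round(min(max(pa_value("sedentary", t, sleep_centered), 30), 700))
    }
    prev_pa_centered <- c(mvpa = mvpa[t] - pa_mean[["mvpa"]],
                          sedentary = sed[t] - pa_mean[["sedentary"]])
  }
  # nap draws consume RNG after the (draw-free) outcome computations
  nap_start <- nap_end <- as.POSIXct(rep(NA_real_, n_nights), tz = .tz)
  for (t in seq_len(n_nights)) {
    if (runif(1) < cfg$nap_prob) {
      st <- M[t] + round(runif(1, 13 * 60, 16 * 60)) * 60
      nap_start[t] <- st
      nap_end[t] <- st + round(runif(1, 30, 80)) * 60
    }
  }

  onset_time <- M + round(onset_h * 3600)
  offset_time <- M + round(offset_h * 3600)

  days <- tibble::new_tibble(list(
    participant_id = rep(id, n_nights),
    night = seq_len(n_nights),
    date = as.Date(M, tz = .tz),
    onset_time = onset_time,
    offset_time = offset_time,
    onset_h = onset_h,
    offset_h = offset_h,
    duration_min = (offset_h - onset_h) * 60,
    sme_pct = sme,
    weekend_night = weekend_night,
    weekend_day = weekend_day,
    mvpa_min = mvpa,
    sedentary_min = sed,
    nap_start = nap_start,
    nap_end = nap_end
  ), nrow = n_nights)

  # injected daytime non-wear gaps, drawn per day and device
  nw_dev <- character(0); nw_start <- nw_end <- numeric(0)
  for (t in seq_len(cfg$n_days)) {
    for (device in c("wrist", "hip")) {
      k <- rpois(1, cfg$nonwear_rate)
      if (k > 0) {
        lo <- as.numeric(offset_time[t]) + 30 * 60
        hi <- as.numeric(onset_time[t + 1]) - 30 * 60
        for (j in seq_len(k)) {
          len <- round(runif(1, 60, 200)) * 60
          if (hi - len <= lo) next
          st <- round(runif(1, lo, hi - len) / 60) * 60
          nw_dev <- c(nw_dev, device)
          nw_start <- c(nw_start, st)
          nw_end <- c(nw_end, st + len)
        }
      }
    }
  }
  nonwear <- tibble::new_tibble(list(
    participant_id = rep(id, length(nw_dev)),
    device = nw_dev,
    start = as.POSIXct(nw_start, origin = "1970-01-01", tz = .tz),
    end = as.POSIXct(nw_end, origin = "1970-01-01", tz = .tz)
  ), nrow = length(nw_dev))

  list(days = days, covariates = cov, nonwear = nonwear,
       intercepts = tibble::new_tibble(c(list(participant_id = id), as.list(u)), nrow = 1L))
}

#' Simulate the day-level structural panel with known ground truth
#'
#' Draws daily sleep (onset, offset, maintenance efficiency) and activity
#' (MVPA, sedentary) outcomes from the generating model
#' `outcome = person intercept + covariate effects + weekend shift +
#' coupling x person-centered predictor + AR(1) noise`, without rendering
#' epoch streams. This is the generator used directly by estimator
#' recovery simulations; [generate_cohort()] renders the same draws into
#' raw device streams.
#'
#' @param config A [synth_config()] object.
#' @return A list with `days` (one row per night/day per participant,
#'   including true instants, totals and weekend flags), `covariates`,
#'   `nonwear` (injected gap windows), `intercepts` (person random
#'   intercept draws) and `config`.
#' @export
#' @examples
#' truth <- simulate_daily_truth(synth_config(3, n_days = 4, seed = 1))
#' head(truth$days)
simulate_daily_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sub <- participant_seeds(config$seed, config$n_participants)
  parts <- lapply(seq_len(config$n_participants), function(i) {
    set.seed(sub[i])
    person_daily_truth(config, i)
  })
  list(
    days = bind_rows(lapply(parts, `[[`, "days")),
    covariates = bind_rows(lapply(parts, `[[`, "covariates")),
    nonwear = bind_rows(lapply(parts, `[[`, "nonwear")),
    intercepts = bind_rows(lapply(parts, `[[`, "intercepts")),
    config = config
  )
}

# ---- minute-label layout -----------------------------------------------

# Arrange one wake portion (length L minutes, nap already positioned) into
# per-minute hip activity labels. Returns character vector length L.
layout_wake_minutes <- function(L, mvpa_total, sed_total, nap_idx) {
  lab <- rep("light", L)
  lab[nap_idx] <- "sedentary"      # lying/sitting during the nap
  free_n <- L - length(nap_idx)
  # keep a morning and a pre-bed buffer free of MVPA
  mvpa_total <- min(mvpa_total, max(0, free_n - 180))
  sed_total <- min(sed_total, max(0, free_n - mvpa_total - 150))

  bouts <- list()
  if (mvpa_total > 0) {
    main <- round(0.6 * mvpa_total)
    rem <- mvpa_total - main
    if (main > 0) bouts[[length(bouts) + 1L]] <- c(len = main, mvpa = 1)
    while (rem > 0) {
      b <- min(rem, sample(1:8, 1))
      bouts[[length(bouts) + 1L]] <- c(len = b, mvpa = 1)
      rem <- rem - b
    }
  }
  rem <- sed_total
  while (rem > 0) {
    b <- min(rem, sample(15:60, 1))
    bouts[[length(bouts) + 1L]] <- c(len = b, mvpa = 0)
    rem <- rem - b
  }
  seq_free <- setdiff(seq_len(L), nap_idx)
  if (length(bouts)) {
    bouts <- bouts[sample(length(bouts))]
    total_bout <- sum(vapply(bouts, `[[`, numeric(1), "len"))
    light_n <- free_n - total_bout
    tail_buffer <- min(120, light_n)  # wind-down light block before bed
    spread <- light_n - tail_buffer
    # random light gaps before each bout (multinomial split)
    gaps <- if (spread > 0) {
      as.vector(stats::rmultinom(1, spread, rep(1, length(bouts) + 1L)))
    } else rep(0L, length(bouts) + 1L)
    lin <- character(0)
    for (b in seq_along(bouts)) {
      cls <- if (bouts[[b]][["mvpa"]] == 1) {
        sample(c("modvig", "walking", "running"), 1, prob = c(.4, .4, .2))
      } else "sedentary"
      lin <- c(lin, rep("light", gaps[b]), rep(cls, bouts[[b]][["len"]]))
    }
    lin <- c(lin, rep("light", gaps[length(gaps)] + tail_buffer))
    lab[seq_free] <- lin
  }
  lab
}

# per-minute 1-s hip counts for a block of minutes sharing one label
hip_counts_for <- function(label, n_min, sed_zero_prob) {
  if (n_min == 0) return(matrix(integer(0), nrow = 60))
  ns <- 60L * n_min
  m <- switch(
    label,
    sleep = ,
    nonwear = matrix(0L, nrow = 60, ncol = n_min),
    sedentary = {
      m <- matrix(0L, nrow = 60, ncol = n_min)
      for (j in seq_len(n_min)) {
        if (runif(1) < sed_zero_prob) next
        na <- 2L + rbinom(1, 56, 0.05)
        pos <- sample.int(60, na)
        m[pos, j] <- 1L + rpois(na, 12)
      }
      m
    },
    light = matrix(rbinom(ns, 1, 0.65) * rpois(ns, 35), nrow = 60),
    walking = {
      lev <- rep(rnorm(n_min, 180, 12), each = 60)
      e <- as.numeric(stats::filter(rnorm(ns, 0, 25), 0.85, "recursive"))
      matrix(pmax(0L, as.integer(round(lev + e))), nrow = 60)
    },
    running = {
      lev <- rep(rnorm(n_min, 700, 40), each = 60)
      e <- as.numeric(stats::filter(rnorm(ns, 0, 35), 0.85, "recursive"))
      matrix(pmax(0L, as.integer(round(lev + e))), nrow = 60)
    },
    modvig = {
      burst <- rbinom(ns, 1, 0.5)
      matrix(as.integer(burst * rpois(ns, 450) + rpois(ns, 50)), nrow = 60)
    },
    abort(sprintf("unknown minute label '%s'", label))
  )
  m
}

# render one participant's wrist and hip streams from daily truth;
# continues the participant's RNG substream
person_render <- function(pt, cfg) {
  days <- pt$days
  n_nights <- nrow(days)
  id <- days$participant_id[1]
  stream_start <- days$onset_time[1] - 240 * 60
  stream_end <- days$offset_time[n_nights] + 60 * 60
  minute_grid <- seq(stream_start, stream_end - 60, by = 60)
  n_min <- length(minute_grid)

  # --- minute labels over the whole stream -------------------------------
  lab <- rep("light", n_min)
  idx_of <- function(tm) as.integer(difftime(tm, stream_start, units = "mins")) + 1L
  realized_mvpa <- realized_sed <- rep(NA_integer_, n_nights)
  for (t in seq_len(n_nights)) {
    a <- idx_of(days$onset_time[t]); b <- idx_of(days$offset_time[t]) - 1L
    lab[a:b] <- "sleep"
  }
  for (t in seq_len(cfg$n_days)) {
    w0 <- idx_of(days$offset_time[t])
    w1 <- idx_of(days$onset_time[t + 1]) - 1L
    L <- w1 - w0 + 1L
    nap_idx <- integer(0)
    if (!is.na(days$nap_start[t])) {
      nap_idx <- (idx_of(days$nap_start[t]):(idx_of(days$nap_end[t]) - 1L)) - w0 + 1L
      nap_idx <- nap_idx[nap_idx >= 1 & nap_idx <= L]
    }
    wl <- layout_wake_minutes(L, days$mvpa_min[t], days$sedentary_min[t], nap_idx)
    lab[w0:w1] <- wl
    # realized totals after capacity clamping become the ground truth;
    # sedentary truth excludes nap minutes (scored as sleep downstream)
    keep <- rep(TRUE, L); keep[nap_idx] <- FALSE
    realized_mvpa[t] <- sum(wl %in% c("modvig", "walking", "running"))
    realized_sed[t] <- sum(wl == "sedentary" & keep)
  }
  days$mvpa_min[seq_len(cfg$n_days)] <- realized_mvpa[seq_len(cfg$n_days)]
  days$sedentary_min[seq_len(cfg$n_days)] <- realized_sed[seq_len(cfg$n_days)]

  # --- wrist stream (30-s epochs) ---------------------------------------
  ep_time <- seq(stream_start, stream_end - 30, by = 30)
  n_ep <- length(ep_time)
  ep_min_idx <- rep(seq_len(n_min), each = 2L)[seq_len(n_ep)]
  ep_lab <- lab[ep_min_idx]
  asleep <- ep_lab == "sleep"
  # nap wrist epochs are quiescent too
  for (t in seq_len(n_nights)) {
    if (!is.na(days$nap_start[t])) {
      sel <- ep_time >= days$nap_start[t] & ep_time < days$nap_end[t]
      asleep <- asleep | sel
    }
  }
  counts <- integer(n_ep)
  n_wake_ep <- sum(!asleep)
  quiet_wake <- runif(n_wake_ep) < cfg$wake_quiet_prob
  wake_counts <- ifelse(quiet_wake, sample(0:10, n_wake_ep, replace = TRUE),
                        11L + rpois(n_wake_ep, 150))
  counts[!asleep] <- wake_counts
  sl_counts <- ifelse(runif(sum(asleep)) < 0.75, 0L, pmin(10L, rpois(sum(asleep), 3)))
  counts[asleep] <- sl_counts

  # within-night wake bouts realise the target maintenance efficiency;
  # kept >= 6 min away from the interval edges (arousals cluster mid-night)
  sme_real <- numeric(n_nights)
  for (t in seq_len(n_nights)) {
    a <- which(ep_time == days$onset_time[t])
    b <- which(ep_time == days$offset_time[t]) - 1L
    n_int <- b - a + 1L
    nw <- round((1 - days$sme_pct[t] / 100) * n_int)
    margin <- 12L
    interior <- if (n_int > 2 * margin + 2) (a + margin):(b - margin) else integer(0)
    nw <- min(nw, length(interior))
    if (nw > 0) {
      pos <- sample(interior, nw)
      counts[pos] <- 11L + rpois(nw, 40)
    }
    sme_real[t] <- 100 * (1 - nw / n_int)
  }
  days$sme_pct <- sme_real
  # pin the boundary epochs so the count rules fire exactly at the truth
  for (t in seq_len(n_nights)) {
    a <- which(ep_time == days$onset_time[t])
    b <- which(ep_time == days$offset_time[t])
    pre <- max(1L, a - 2L):(a - 1L)
    post <- b:min(n_ep, b + 1L)
    counts[pre] <- 60L + rpois(length(pre), 60)
    counts[post] <- 60L + rpois(length(post), 60)
  }

  lux <- numeric(n_ep)
  lux[!asleep] <- round(rlnorm(n_wake_ep, log(250), 0.7), 1)
  lux[asleep] <- round(runif(sum(asleep), 0, 3), 1)

  wrist <- tibble(
    participant_id = id, timestamp = ep_time,
    counts = as.integer(counts), offwrist = 0L, lux = lux
  )

  # --- hip stream (1-s counts) ------------------------------------------
  sec_counts <- matrix(0L, nrow = 60, ncol = n_min)
  for (cl in c("sedentary", "light", "walking", "running", "modvig")) {
    sel <- which(lab == cl)
    if (length(sel)) {
      sec_counts[, sel] <- hip_counts_for(cl, length(sel), cfg$sed_zero_minute_prob)
    }
  }
  hip <- tibble(
    participant_id = id,
    timestamp = rep(minute_grid, each = 60) + rep(0:59, n_min),
    counts = as.integer(sec_counts)
  )

  # --- injected non-wear -------------------------------------------------
  nw <- pt$nonwear
  wrist_win <- nw[nw$device == "wrist", c("start", "end")]
  hip_win <- nw[nw$device == "hip", c("start", "end")]
  if (nrow(wrist_win)) wrist <- inject_nonwear(wrist, wrist_win)
  if (nrow(hip_win)) hip <- inject_nonwear(hip, hip_win)

  minute_truth <- tibble(
    participant_id = id, minute_start = minute_grid, true_class = lab
  )
  if (nrow(hip_win)) {
    for (j in seq_len(nrow(hip_win))) {
      sel <- minute_truth$minute_start >= hip_win$start[j] &
        minute_truth$minute_start < hip_win$end[j]
      minute_truth$true_class[sel] <- "nonwear"
    }
  }

  list(wrist = wrist, hip = hip, days = days, minute_truth = minute_truth)
}

#' Generate a full synthetic dual-device cohort
#'
#' Renders the day-level draws of [simulate_daily_truth()] into raw device
#' streams: a wrist series of 30-second epochs (activity counts, off-wrist
#' flag, white-light lux) and a hip series of 1-second vertical-axis
#' counts, per participant, together with the covariate table and the
#' complete ground truth (true sleep instants, minute-level activity
#' labels, nap and non-wear windows).
#'
#' The generated streams are consistent with their ground truth by
#' construction: within true sleep, counts exceed 10 only in the wake
#' bouts that set maintenance efficiency; injected non-wear windows have
#' zero counts (and the off-wrist flag set on the wrist device).
#'
#' @param config A [synth_config()] object.
#' @return A list with `wrist`, `hip` (epoch tibbles across participants),
#'   `covariates`, and `truth` (the updated daily table, per-minute true
#'   labels, nap/non-wear windows, intercepts and the coupling used).
#' @export
#' @examples
#' coh <- generate_cohort(synth_config(1, n_days = 3, seed = 2))
#' dplyr::count(coh$truth$minute_truth, true_class)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sub <- participant_seeds(config$seed, config$n_participants)
  out <- lapply(seq_len(config$n_participants), function(i) {
    set.seed(sub[i])
    pt <- person_daily_truth(config, i)
    r <- person_render(pt, config)
    list(wrist = r$wrist, hip = r$hip, days = r$days,
         minute_truth = r$minute_truth, covariates = pt$covariates,
         nonwear = pt$nonwear, intercepts = pt$intercepts)
  })
  list(
    wrist = bind_rows(lapply(out, `[[`, "wrist")),
    hip = bind_rows(lapply(out, `[[`, "hip")),
    covariates = bind_rows(lapply(out, `[[`, "covariates")),
    truth = list(
      days = bind_rows(lapply(out, `[[`, "days")),
      minute_truth = bind_rows(lapply(out, `[[`, "minute_truth")),
      nonwear = bind_rows(lapply(out, `[[`, "nonwear")),
      intercepts = bind_rows(lapply(out, `[[`, "intercepts")),
      coupling = config$coupling
    ),
    config = config
  )
}

#' Inject non-wear windows into a device stream
#'
#' Zeroes activity counts inside the given windows; for wrist streams
#' (recognised by their `offwrist` column) the off-wrist flag is also set
#' and lux zeroed. Overlapping windows are merged, not an error.
#'
#' @param stream A wrist or hip epoch tibble.
#' @param windows A data frame with `start`/`end` POSIXct columns; each
#'   window is `[start, end)` and must lie within the stream span.
#' @return The modified stream.
#' @export
inject_nonwear <- function(stream, windows) {
  stopifnot_cols(stream, c("timestamp", "counts"), "stream")
  if (nrow(windows) == 0) return(stream)
  stopifnot_cols(windows, c("start", "end"), "windows")
  if (any(windows$end <= windows$start)) abort("windows must have end > start.")
  span <- range(stream$timestamp)
  if (any(windows$start < span[1] - 60) || any(windows$end > span[2] + 60)) {
    abort("non-wear windows must lie within the stream span.")
  }
  w <- windows %>% arrange(.data$start)
  merged <- list(c(as.numeric(w$start[1]), as.numeric(w$end[1])))
  if (nrow(w) > 1) {
    for (j in 2:nrow(w)) {
      lastw <- merged[[length(merged)]]
      if (as.numeric(w$start[j]) <= lastw[2]) {
        merged[[length(merged)]][2] <- max(lastw[2], as.numeric(w$end[j]))
      } else {
        merged[[length(merged) + 1L]] <- c(as.numeric(w$start[j]), as.numeric(w$end[j]))
      }
    }
  }
  ts <- as.numeric(stream$timestamp)
  hit <- rep(FALSE, length(ts))
  for (mw in merged) hit <- hit | (ts >= mw[1] & ts < mw[2])
  stream$counts[hit] <- 0L
  if ("offwrist" %in% names(stream)) {
    stream$offwrist[hit] <- 1L
    if ("lux" %in% names(stream)) stream$lux[hit] <- 0
  }
  stream
}
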