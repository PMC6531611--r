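#' Configuration for the synthetic dual-device cohort generator
#'
#' Builds and validates the parameter set that drives [generate_cohort()].
#' Defaults reproduce the descriptive profile of a school-year adolescent
#' cohort: mean sleep onset a few minutes past midnight, offset near 07:49,
#' about 45 daily minutes of moderate-to-vigorous physical activity (MVPA)
#' and about 390 sedentary minutes, with day-to-day residuals following an
#' AR(1) process within person.
#'
#' Sleep timing is parameterised on two clock scales used throughout the
#' package: *onset* is midnight-centered signed hours (00:04 -> +0.067,
#' 22:00 -> -2.0) and *offset* is hours since midnight of the wake day
#' (07:49 -> 7.817).
#'
#' @param n_participants Number of participants to simulate.
#' @param n_days Number of complete onset-to-onset person-days per
#'   participant (the generator simulates `n_days + 1` nights so every day
#'   has both bounding sleep onsets). Must be at least 3, matching the
#'   3-valid-day inclusion rule.
#' @param seed Integer seed. Each participant draws from a substream
#'   derived deterministically from `(seed, participant index)`, so
#'   cohorts are reproducible participant-by-participant while different
#'   seeds yield non-overlapping substream families.
#' @param start_date Calendar date of the first night (its evening); the
#'   default is a Monday in October so a default week spans both weekday
#'   and weekend nights inside the school year.
#' @param onset_mean,offset_mean Mean sleep onset (midnight-centered hours)
#'   and offset (24-h clock hours).
#' @param onset_sd_between,offset_sd_between Between-person SDs (hours) of
#'   the sleep-timing random intercepts.
#' @param sme_mean,sme_sd_between Mean and between-person SD of sleep
#'   maintenance efficiency (percent).
#' @param mvpa_daily_mean,mvpa_sd_between Daily MVPA minutes: mean and
#'   between-person SD.
#' @param sedentary_daily_mean,sedentary_sd_between Daily sedentary
#'   minutes: mean and between-person SD.
#' @param coupling Named list of true within-person coefficients linking a
#'   person-centered predictor on one side to an outcome on the other,
#'   named `"<predictor>_to_<outcome>"` with predictor/outcome in
#'   `onset`, `offset`, `duration`, `sme`, `mvpa`, `sedentary`. Sleep-side
#'   outcomes respond to the *same calendar day's* activity; activity-side
#'   outcomes respond to the *preceding night's* sleep. Units follow the
#'   variables, e.g. `mvpa_to_onset = -0.005` is hours of onset shift per
#'   within-person MVPA minute.
#' @param ar1_rho Lag-1 autocorrelation of day-to-day residuals, |rho| < 1.
#' @param resid_sd_by_outcome Named residual (level-1) SDs for `onset`,
#'   `offset` (hours), `sme` (percent), `mvpa`, `sedentary` (minutes).
#' @param weekend_effects Named shifts applied on weekend nights
#'   (Friday/Saturday, sleep outcomes) or weekend days (Saturday/Sunday,
#'   activity outcomes).
#' @param sex_effects Named shifts for male (vs female) participants; the
#'   only nonzero covariate effects in the default generator.
#' @param nonwear_rate Expected number of injected daytime non-wear gaps
#'   per day and device (Poisson).
#' @param nap_prob Probability per day of an afternoon nap.
#' @param wake_quiet_prob Probability that a daytime worn wrist epoch falls
#'   at or below the 10-count quiescence threshold (isolated stillness).
#' @param sed_zero_minute_prob Probability that a sedentary minute on the
#'   hip device sums to zero counts (perfect stillness).
#'
#' @return A validated list of class `"synth_config"`.
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 4, n_days = 5, seed = 1)
#' cfg$mvpa_daily_mean
synth_config <- function(n_participants,
                         n_days = 7,
                         seed = 1L,
                         start_date = as.Date("2023-10-02"),
                         onset_mean = 4 / 60,
                         onset_sd_between = 1.0,
                         offset_mean = 7 + 49 / 60,
                         offset_sd_between = 1.0,
                         sme_mean = 90.9,
                         sme_sd_between = 2.2,
                         mvpa_daily_mean = 45,
                         mvpa_sd_between = 18,
                         sedentary_daily_mean = 390,
                         sedentary_sd_between = 65,
                         coupling = list(),
                         ar1_rho = 0.2,
                         resid_sd_by_outcome = c(onset = 0.75, offset = 0.75,
                                                 sme = 1.7, mvpa = 17,
                                                 sedentary = 65),
                         weekend_effects = c(onset = 0.93, offset = 1.86,
                                             sme = 0.07, mvpa = -21.2,
                                             sedentary = -18.2),
                         sex_effects = c(onset = 0.62, offset = 0.30,
                                         sme = -0.7, mvpa = 8,
                                         sedentary = -36),
                         nonwear_rate = 0.2,
                         nap_prob = 0.1,
                         wake_quiet_prob = 0.03,
                         sed_zero_minute_prob = 0.02) {
  if (n_days < 3) {
    abort("n_days must be >= 3: shorter cohorts cannot satisfy the 3-valid-day inclusion rule.")
  }
  if (n_participants < 1) abort("n_participants must be >= 1.")
  if (abs(ar1_rho) >= 1) abort("ar1_rho must satisfy |rho| < 1.")
  sds <- c(onset_sd_between, offset_sd_between, sme_sd_between,
           mvpa_sd_between, sedentary_sd_between, resid_sd_by_outcome)
  if (any(sds < 0)) abort("all SDs must be >= 0.")
  probs <- c(nap_prob, wake_quiet_prob, sed_zero_minute_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1].")
  if (nonwear_rate < 0) abort("nonwear_rate must be >= 0.")
  outcomes <- c("onset", "offset", "duration", "sme", "mvpa", "sedentary")
  if (length(coupling)) {
    parts <- strsplit(names(coupling), "_to_", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 2 && all(p %in% outcomes),
                 logical(1))
    if (!all(ok)) {
      abort("coupling names must be '<predictor>_to_<outcome>' over onset/offset/duration/sme/mvpa/sedentary.")
    }
    if (any(vapply(parts, function(p) p[2] == "duration", logical(1)))) {
      abort("duration is derived (offset - onset); couple onto onset and/or offset instead.")
    }
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_days = as.integer(n_days),
      seed = as.integer(seed),
      start_date = as.Date(start_date),
      onset_mean = onset_mean, onset_sd_between = onset_sd_between,
      offset_mean = offset_mean, offset_sd_between = offset_sd_between,
      sme_mean = sme_mean, sme_sd_between = sme_sd_between,
      mvpa_daily_mean = mvpa_daily_mean, mvpa_sd_between = mvpa_sd_between,
      sedentary_daily_mean = sedentary_daily_mean,
      sedentary_sd_between = sedentary_sd_between,
      coupling = coupling,
      ar1_rho = ar1_rho,
      resid_sd_by_outcome = resid_sd_by_outcome,
      weekend_effects = weekend_effects,
      sex_effects = sex_effects,
      nonwear_rate = nonwear_rate,
      nap_prob = nap_prob,
      wake_quiet_prob = wake_quiet_prob,
      sed_zero_minute_prob = sed_zero_minute_prob
    ),
    class = "synth_config"
  )
}

#' A noise-free variant of a synthetic configuration
#'
#' Convenience wrapper that switches off naps, non-wear and count-level
#' noise sources so that every scored quantity can be compared with ground
#' truth exactly; used by the pipeline-conservation checks.
#'
#' @param ... Passed to [synth_config()].
#' @return A `"synth_config"` object.
#' @export
synth_config_clean <- function(...) {
  args <- list(...)
  args$nonwear_rate <- 0
  args$nap_prob <- 0
  args$wake_quiet_prob <- 0
  args$sed_zero_minute_prob <- 0
  do.call(synth_config, args)
}
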