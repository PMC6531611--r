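# Estimator validation studies: parameter recovery and type-I error of
# the within-person Wald test, run against the day-level generating model.

# lagged structural panel from generator truth: day t-1 activity paired
# with night t sleep, the generating model's own alignment
truth_lagged <- function(truth) {
  truth$days %>%
    group_by(.data$participant_id) %>%
    arrange(.data$night, .by_group = TRUE) %>%
    mutate(mvpa_prev = lag(.data$mvpa_min), day = .data$night) %>%
    ungroup() %>%
    filter(!is.na(.data$mvpa_prev))
}

#' Parameter-recovery simulation for the LMM-AR(1) estimator
#'
#' Generates replicate cohorts from the day-level structural model with a
#' known within-person MVPA-to-onset coupling, refits the estimator on
#' each, and summarises bias and Wald 95% CI coverage. Replicate cohort
#' seeds are drawn through the RNG from `base_seed`, so replicates use
#' independent, well-mixed substream families.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_participants,n_days Cohort size per replicate.
#' @param coupling True within-person coefficient (hours of sleep-onset
#'   shift per daily MVPA minute).
#' @param rho AR(1) residual correlation used in generation.
#' @param base_seed Seed anchoring the replicate seed sequence.
#' @return A list with `estimates` (per-replicate tibble: `est`, `se`,
#'   `rho`, `covered`) and `summary` (mean estimate, Monte-Carlo SE of
#'   the mean, coverage, mean rho).
#' @export
recovery_simulation <- function(n_reps = 100, n_participants = 400,
                                n_days = 7, coupling = -0.005, rho = 0.2,
                                base_seed = 1L) {
  set.seed(base_seed)
  rep_seeds <- sample.int(2147483647L, n_reps, replace = TRUE)
  res <- lapply(seq_len(n_reps), function(r) {
    cfg <- synth_config(n_participants, n_days = n_days,
                        seed = rep_seeds[r],
                        coupling = if (coupling != 0)
                          list(mvpa_to_onset = coupling) else list(),
                        ar1_rho = rho)
    tr <- simulate_daily_truth(cfg)
    d <- center_within_between(truth_lagged(tr), "mvpa_prev")
    f <- fit_lmm_ar1(d, onset_h ~ mvpa_prev_bp + mvpa_prev_wp + weekend_night)
    co <- f$coefficients[f$coefficients$term == "mvpa_prev_wp", ]
    tibble(est = co$estimate, se = co$std.error, p = co$p.value, rho = f$rho)
  })
  est <- bind_rows(res) %>%
    mutate(covered = abs(.data$est - coupling) <= qnorm(0.975) * .data$se)
  list(
    estimates = est,
    summary = tibble(
      truth = coupling,
      mean_est = mean(est$est),
      mc_se = sd(est$est) / sqrt(n_reps),
      coverage = mean(est$covered),
      mean_rho = mean(est$rho),
      n_reps = n_reps
    )
  )
}

#' Type-I error simulation for the within-person Wald test
#'
#' Generates replicate cohorts with no coupling and records how often the
#' within-person Wald test rejects at the given level.
#'
#' @inheritParams recovery_simulation
#' @param alpha Nominal test level.
#' @return A list with `p_values` and `summary` (rejection rate, MC SE).
#' @export
type1_simulation <- function(n_reps = 1000, n_participants = 100,
                             n_days = 7, alpha = 0.05, base_seed = 20000L) {
  set.seed(base_seed)
  rep_seeds <- sample.int(2147483647L, n_reps, replace = TRUE)
  p <- vapply(seq_len(n_reps), function(r) {
    cfg <- synth_config(n_participants, n_days = n_days,
                        seed = rep_seeds[r])
    tr <- simulate_daily_truth(cfg)
    d <- center_within_between(truth_lagged(tr), "mvpa_prev")
    f <- suppressWarnings(
      fit_lmm_ar1(d, onset_h ~ mvpa_prev_bp + mvpa_prev_wp + weekend_night))
    f$coefficients$p.value[f$coefficients$term == "mvpa_prev_wp"]
  }, numeric(1))
  rate <- mean(p < alpha)
  list(p_values = p,
       summary = tibble(alpha = alpha, rejection_rate = rate,
                        mc_se = sqrt(rate * (1 - rate) / n_reps),
                        n_reps = n_reps))
}
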