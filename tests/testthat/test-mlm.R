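# Within/between decomposition, lagged panel alignment, the profiled
# ML estimator against independent oracles, and coefficient scaling.

test_that("within/between centering follows the definitions", {
  p <- tibble::tibble(participant_id = c("a", "a", "b", "b"),
                      mvpa = c(30, 60, 40, 60))
  out <- center_within_between(p, "mvpa")
  expect_equal(out$mvpa_wp, c(-15, 15, -10, 10))
  expect_equal(out$mvpa_bp, c(-2.5, -2.5, 2.5, 2.5))   # means 45, 50
  # sum of within components per person is zero
  sums <- out %>% dplyr::group_by(participant_id) %>%
    dplyr::summarise(s = sum(mvpa_wp)) %>% dplyr::pull(s)
  expect_equal(sums, c(0, 0))
  # two persons with means 40 and 50: between components -5 / +5
  p2 <- tibble::tibble(participant_id = c("a", "a", "b", "b"),
                       x = c(30, 50, 45, 55))
  expect_equal(center_within_between(p2, "x")$x_bp, c(-5, -5, 5, 5))
  # single-day person: within identically zero, person kept
  p3 <- tibble::tibble(participant_id = c("a", "b", "b"), x = c(10, 4, 8))
  o3 <- center_within_between(p3, "x")
  expect_equal(o3$x_wp[1], 0)
  expect_equal(nrow(o3), 3L)
})

mk_person_days <- function(id = "P001", n = 7, start = "2023-10-02",
                           valid_pa = TRUE) {
  dates <- as.Date(start) + seq_len(n) - 1L
  tibble::tibble(
    participant_id = id, date = dates,
    valid_pa = rep_len(valid_pa, n),
    onset_h = rnorm(n, 0, 1), offset_h = rnorm(n, 7.8, 1),
    duration_min = rnorm(n, 460, 50), sme_pct = rnorm(n, 91, 2),
    mvpa_min = rpois(n, 45), sedentary_min = rpois(n, 390),
    weekend_night = FALSE, weekend_day = FALSE
  )
}

test_that("lagged panels align the two directions correctly", {
  set.seed(1)
  pd <- mk_person_days(n = 7)
  expect_equal(nrow(build_lagged_panel(pd, direction = "sleep_to_pa")), 7L)
  lag_p <- build_lagged_panel(pd, direction = "pa_to_sleep")
  expect_equal(nrow(lag_p), 6L)   # first night has no prior day
  # outcome sleep of record r+1 is paired with activity of record r
  expect_equal(lag_p$onset_h, pd$onset_h[2:7])
  expect_equal(lag_p$mvpa_min, pd$mvpa_min[1:6])

  # a missing middle record drops both adjacent lagged rows
  pd_gap <- pd[-4, ]
  expect_equal(nrow(build_lagged_panel(pd_gap, direction = "pa_to_sleep")), 4L)

  # an invalid-PA day drops its sleep_to_pa row and its pa_to_sleep pairing
  pd_bad <- pd
  pd_bad$valid_pa[4] <- FALSE
  expect_equal(nrow(build_lagged_panel(pd_bad, direction = "sleep_to_pa")), 6L)
  expect_equal(nrow(build_lagged_panel(pd_bad, direction = "pa_to_sleep")), 5L)

  # a single valid day yields no lagged rows
  pd1 <- mk_person_days(n = 1)
  expect_equal(nrow(build_lagged_panel(pd1, direction = "pa_to_sleep")), 0L)
})

test_that("with variance components fixed at zero the fit reduces to OLS", {
  set.seed(5)
  d <- toy_panel(8, 5)
  f <- fit_lmm_ar1(d, y ~ x, fix_lambda = 0, fix_rho = 0)
  ols <- lm(y ~ x, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  # ML residual variance: RSS/n
  expect_equal(f$sigma2_e, sum(residuals(ols)^2) / nrow(d), tolerance = 1e-8)
})

test_that("structured log-likelihood equals the dense MVN evaluation", {
  set.seed(8)
  for (k in 1:5) {
    m <- sample(2:6, 1); n_i <- sample(2:5, 1)
    d <- toy_panel(m, n_i, gaps = k > 3)
    X <- cbind(1, d$x)
    beta <- rnorm(2)
    s2u <- runif(1, 0.1, 2); s2e <- runif(1, 0.3, 2); rho <- runif(1, -0.8, 0.8)
    expect_equal(
      loglik_lmm_ar1(d$y, X, d$participant_id, d$day, beta, s2u, s2e, rho),
      dense_loglik(d$y, X, d$participant_id, d$day, beta, s2u, s2e, rho),
      tolerance = 1e-10)
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  set.seed(13)
  d <- toy_panel(12, 6, rho = 0.4)
  f <- fit_lmm_ar1(d, y ~ x, method = "ML")
  g <- nlme::lme(y ~ x, random = ~ 1 | participant_id,
                 correlation = nlme::corAR1(form = ~ day | participant_id),
                 data = d, method = "ML")
  expect_equal(f$coefficients$estimate, unname(nlme::fixef(g)), tolerance = 1e-4)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-5)
  expect_equal(f$rho,
               as.numeric(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  vc <- nlme::VarCorr(g)
  expect_equal(f$sigma2_u, as.numeric(vc[1, 1]), tolerance = 1e-3)
  expect_equal(f$sigma2_e, as.numeric(vc[2, 1]), tolerance = 1e-4)
  # REML variant also runs and gives a larger intercept-variance estimate
  fr <- fit_lmm_ar1(d, y ~ x, method = "REML")
  gr <- nlme::lme(y ~ x, random = ~ 1 | participant_id,
                  correlation = nlme::corAR1(form = ~ day | participant_id),
                  data = d, method = "REML")
  expect_equal(fr$coefficients$estimate, unname(nlme::fixef(gr)),
               tolerance = 1e-4)
  expect_equal(fr$coefficients$std.error,
               unname(sqrt(diag(stats::vcov(gr)))), tolerance = 1e-3)
})

test_that("recentering a predictor changes only the intercept", {
  set.seed(21)
  d <- toy_panel(10, 5, rho = 0.3)
  f1 <- fit_lmm_ar1(d, y ~ x)
  d2 <- d %>% dplyr::mutate(x = x + 100)
  f2 <- fit_lmm_ar1(d2, y ~ x)
  expect_equal(f1$coefficients$estimate[2], f2$coefficients$estimate[2],
               tolerance = 1e-6)
  expect_equal(f2$coefficients$estimate[1],
               f1$coefficients$estimate[1] - 100 * f1$coefficients$estimate[2],
               tolerance = 1e-4)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-5)
})

test_that("the fitter validates its inputs and flags boundaries", {
  d <- toy_panel(1, 5)
  expect_error(fit_lmm_ar1(d, y ~ x), "at least 2 participants")
  set.seed(3)
  # person-demeaned outcomes leave no between-person variance at all, so
  # the intercept-variance estimate must hit the zero boundary
  d2 <- toy_panel(10, 5, s2u = 0, rho = 0) %>%
    dplyr::group_by(participant_id) %>%
    dplyr::mutate(y = y - mean(y)) %>%
    dplyr::ungroup()
  expect_warning(fit_lmm_ar1(d2, y ~ x), "zero boundary")
})

test_that("coefficient scaling reproduces the unit conversions", {
  expect_equal(scale_coefficient(-0.005, "hours"), -18)
  expect_equal(scale_coefficient(0.17, "minutes"), 10.2)
  expect_equal(scale_coefficient(0.17, "minutes", digits = 0), 10)
  expect_equal(scale_coefficient(0, "hours"), 0)
  expect_equal(scale_coefficient(0.01, "percent"), 0.6)
  expect_error(scale_coefficient(1, "fortnights"))
})

test_that("the sixteen-model suite runs and recovers coupling signs", {
  set.seed(31)
  pd <- dplyr::bind_rows(lapply(1:12, function(i)
    mk_person_days(id = sprintf("P%03d", i))))
  # reduced covariate-free configuration: intercept + focal + weekend
  suite <- suppressWarnings(run_model_suite(pd, covariates = NULL))
  expect_s3_class(suite, "actisleep_suite")
  expect_equal(nrow(suite$models), 16L)
  expect_true(all(vapply(suite$models$fit, Negate(is.null), logical(1))))
  hl <- suite_headline(suite)
  expect_equal(nrow(hl), 16L)
  expect_true(all(is.finite(hl$effect_per_hour)))

  # coupled cohort: the recovered within-person signs match the generator
  cfg <- synth_config(150, n_days = 7, seed = 8000,
                      coupling = list(mvpa_to_onset = -0.005,
                                      sedentary_to_onset = 0.005))
  tr <- simulate_daily_truth(cfg)
  d <- truth_lagged_panel(tr)
  d <- center_within_between(d, "mvpa_prev")
  d <- center_within_between(d, "sed_prev")
  f_m <- fit_lmm_ar1(d, onset_h ~ mvpa_prev_bp + mvpa_prev_wp + weekend_night)
  f_s <- fit_lmm_ar1(d, onset_h ~ sed_prev_bp + sed_prev_wp + weekend_night)
  expect_lt(dplyr::filter(tidy(f_m), term == "mvpa_prev_wp")$estimate, 0)
  expect_gt(dplyr::filter(tidy(f_s), term == "sed_prev_wp")$estimate, 0)
})
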