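# Two-level linear mixed models with a person random intercept and AR(1)
# within-person errors:
#
#   y_it = x_it' beta + u_i + e_it,  u_i ~ N(0, sigma2_u),
#   cov(e_it, e_is) = sigma2_e * rho^|d_it - d_is|
#
# where d is the scored-day index (missing days widen the gap). Estimation
# profiles beta (GLS) and sigma2_e out of the (restricted) likelihood and
# optimises over (log lambda, atanh rho) with lambda = sigma2_u/sigma2_e.
# Persons sharing a day-gap pattern share one correlation matrix, so the
# per-evaluation cost is a handful of small dense solves plus vectorised
# cross-products — balanced panels hit a single-pattern fast path.

#' Decompose a daily variable into within- and between-person components
#'
#' Adds `<variable>_wp` (value minus the person's own mean over their
#' observed days) and `<variable>_bp` (person mean minus the sample mean
#' of person means). Persons contributing a single day get a within
#' component identically zero and are kept.
#'
#' @param panel A person-day tibble.
#' @param variable Name of the column to decompose.
#' @param id Grouping column (default `"participant_id"`).
#' @return The panel with the two new columns.
#' @export
#' @examples
#' p <- tibble::tibble(participant_id = c("a", "a", "b", "b"),
#'                     mvpa = c(30, 60, 40, 60))
#' center_within_between(p, "mvpa")
center_within_between <- function(panel, variable, id = "participant_id") {
  stopifnot_cols(panel, c(id, variable), "panel")
  v <- sym(variable)
  out <- panel %>%
    group_by(.data[[id]]) %>%
    mutate("{variable}_pmean" := mean(!!v)) %>%
    ungroup()
  pmeans <- out %>% distinct(.data[[id]], .data[[paste0(variable, "_pmean")]])
  grand <- mean(pmeans[[paste0(variable, "_pmean")]])
  out %>%
    mutate(
      "{variable}_wp" := !!v - .data[[paste0(variable, "_pmean")]],
      "{variable}_bp" := .data[[paste0(variable, "_pmean")]] - grand
    ) %>%
    select(-dplyr::all_of(paste0(variable, "_pmean")))
}

#' Build the lagged bidirectional model panel
#'
#' Pairs sleep and activity across the correct lag for each modelling
#' direction. With person-days defined from one night's sleep onset to
#' the next, `"sleep_to_pa"` pairs a record's night sleep with the
#' activity of the day it opens (same record); `"pa_to_sleep"` pairs a
#' day's activity with the sleep of the *following* record (that
#' evening's night), losing the first night and any record whose
#' successor is missing.
#'
#' @param person_days Filtered person-day table.
#' @param covariates Participant covariate table (joined by id), or NULL.
#' @param direction `"sleep_to_pa"` or `"pa_to_sleep"`.
#' @return A model tibble with `participant_id`, `day` (AR(1) day index
#'   of the outcome), `weekend` (night flag for sleep outcomes, day flag
#'   for activity outcomes), outcome and predictor columns, and any
#'   covariates.
#' @export
build_lagged_panel <- function(person_days, covariates = NULL,
                               direction = c("sleep_to_pa", "pa_to_sleep")) {
  direction <- match.arg(direction)
  pd <- person_days %>%
    filter(.data$valid_pa) %>%
    group_by(.data$participant_id) %>%
    arrange(.data$date, .by_group = TRUE) %>%
    ungroup()
  if (direction == "sleep_to_pa") {
    out <- pd %>%
      group_by(.data$participant_id) %>%
      mutate(day = as.integer(.data$date - min(.data$date))) %>%
      ungroup() %>%
      mutate(weekend = .data$weekend_day) %>%
      select("participant_id", "day", "weekend",
             "onset_h", "offset_h", "duration_min", "sme_pct",
             "mvpa_min", "sedentary_min")
  } else {
    # sleep outcome of record r+1 against activity of record r; records
    # must be calendar-consecutive
    nights <- person_days %>%
      group_by(.data$participant_id) %>%
      arrange(.data$date, .by_group = TRUE) %>%
      mutate(day = as.integer(.data$date - min(.data$date))) %>%
      ungroup() %>%
      select("participant_id", "date", "day",
             "onset_h", "offset_h", "duration_min", "sme_pct",
             "weekend_night")
    acts <- pd %>%
      mutate(date = .data$date + 1L) %>%
      select("participant_id", "date", "mvpa_min", "sedentary_min")
    out <- nights %>%
      dplyr::inner_join(acts, by = c("participant_id", "date")) %>%
      mutate(weekend = .data$weekend_night) %>%
      select("participant_id", "day", "weekend",
             "onset_h", "offset_h", "duration_min", "sme_pct",
             "mvpa_min", "sedentary_min")
  }
  if (!is.null(covariates)) {
    out <- out %>% left_join(covariates, by = "participant_id")
  }
  out %>% filter(complete.cases(.))
}

# ---- likelihood machinery ----------------------------------------------

# split rows into gap-pattern groups; data must be sorted by id then day
ar1_patterns <- function(id, day) {
  ord <- order(id, day)
  if (any(ord != seq_along(id))) abort("rows must be sorted by id, day.")
  per <- split(seq_along(id), factor(id, levels = unique(id)))
  sig <- vapply(per, function(ix) paste(diff(day[ix]), collapse = ","),
                character(1))
  if (any(vapply(per, function(ix) anyDuplicated(day[ix]) > 0, logical(1)))) {
    abort("duplicated day index within a person.")
  }
  groups <- split(per, sig)
  lapply(groups, function(g) {
    n_i <- length(g[[1]])
    gaps <- if (n_i > 1) diff(day[g[[1]]]) else integer(0)
    pos <- cumsum(c(0, gaps))
    list(rows = unlist(g, use.names = FALSE), n = n_i, m = length(g),
         dist = abs(outer(pos, pos, "-")))
  })
}

# profiled quantities for W = lambda * J + R(rho), shared by ML and REML
ar1_profile <- function(y, X, patterns, lambda, rho) {
  q <- ncol(X)
  XtWX <- matrix(0, q, q)
  XtWy <- numeric(q)
  logdet_sum <- 0
  WX <- matrix(0, length(y), q)
  Wy <- numeric(length(y))
  for (p in patterns) {
    R <- rho^p$dist
    W <- lambda + R
    Winv <- solve(W)
    ld <- determinant(W, logarithm = TRUE)$modulus[1]
    logdet_sum <- logdet_sum + p$m * ld
    Ymat <- matrix(y[p$rows], p$n, p$m)
    Wy[p$rows] <- as.vector(Winv %*% Ymat)
    for (j in seq_len(q)) {
      WX[p$rows, j] <- as.vector(Winv %*% matrix(X[p$rows, j], p$n, p$m))
    }
  }
  XtWX <- crossprod(X, WX)
  XtWy <- crossprod(WX, y)
  beta <- solve(XtWX, XtWy)
  r <- y - X %*% beta
  # r' Winv r reuses Wy/WX: r'Winv r = y'Wy - 2 beta'X'Wy + beta'XtWX beta
  quad <- sum(y * Wy) - 2 * sum(beta * XtWy) + drop(t(beta) %*% XtWX %*% beta)
  list(beta = drop(beta), XtWX = XtWX, quad = drop(quad),
       logdet_sum = logdet_sum)
}

ar1_negloglik <- function(theta, y, X, patterns, reml) {
  lambda <- exp(theta[1])
  rho <- tanh(theta[2])
  pr <- ar1_profile(y, X, patterns, lambda, rho)
  N <- length(y)
  q <- ncol(X)
  if (reml) {
    s2 <- pr$quad / (N - q)
    ldX <- determinant(pr$XtWX, logarithm = TRUE)$modulus[1]
    0.5 * ((N - q) * log(2 * pi * s2) + pr$logdet_sum + ldX + (N - q))
  } else {
    s2 <- pr$quad / N
    0.5 * (N * log(2 * pi * s2) + pr$logdet_sum + N)
  }
}

#' Evaluate the structured LMM-AR(1) log-likelihood
#'
#' Computes the Gaussian log-likelihood of the random-intercept + AR(1)
#' model at the given parameter values using the structured per-person
#' computation (gap-pattern grouping). Primarily used to validate the
#' estimator against a dense multivariate-normal evaluation.
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix.
#' @param id Person identifier vector.
#' @param day Integer day index within person.
#' @param beta Fixed-effect coefficients.
#' @param sigma2_u Random-intercept variance.
#' @param sigma2_e Residual variance.
#' @param rho AR(1) correlation, |rho| < 1.
#' @return The log-likelihood (scalar).
#' @export
loglik_lmm_ar1 <- function(y, X, id, day, beta, sigma2_u, sigma2_e, rho) {
  ord <- order(id, day)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; id <- id[ord]; day <- day[ord]
  patterns <- ar1_patterns(id, day)
  lambda <- sigma2_u / sigma2_e
  r <- y - X %*% beta
  N <- length(y)
  ll <- -0.5 * N * log(2 * pi * sigma2_e)
  for (p in patterns) {
    W <- lambda + rho^p$dist
    Winv <- solve(W)
    ld <- determinant(W, logarithm = TRUE)$modulus[1]
    Rm <- matrix(r[p$rows], p$n, p$m)
    quad <- sum(Rm * (Winv %*% Rm))
    ll <- ll - 0.5 * (p$m * ld + quad / sigma2_e)
  }
  ll
}

#' Fit a two-level linear mixed model with AR(1) within-person errors
#'
#' Estimates `formula`'s fixed effects with a person random intercept and
#' AR(1) residual correlation over the scored-day index, by profiled
#' maximum likelihood (default) or REML. The variance profile is
#' optimised over `(log(sigma2_u/sigma2_e), atanh(rho))` by Nelder-Mead
#' with multiple AR(1) starting values to avoid boundary-adjacent local
#' optima; fixed-effect standard errors come from the GLS information
#' matrix and p-values are Wald z tests.
#'
#' @param data Model tibble (e.g. from [build_lagged_panel()]).
#' @param formula Fixed-effects formula, e.g.
#'   `onset_h ~ mvpa_min_bp + mvpa_min_wp + weekend`.
#' @param id,time Column names of the person identifier and the integer
#'   day index.
#' @param method `"ML"` (default) or `"REML"`.
#' @param rho_starts Starting AR(1) correlations for the multi-start.
#' @param fix_rho,fix_lambda Optionally fix rho and/or the variance ratio
#'   `lambda = sigma2_u/sigma2_e` (e.g. both 0 reduces the fit to OLS).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `"actisleep_lmm"` with a coefficient table,
#'   variance components (`sigma2_u`, `sigma2_e`, `rho`), log-likelihood
#'   and fit metadata. Supports [tidy()], [glance()], `print()` and
#'   [autoplot()].
#' @export
fit_lmm_ar1 <- function(data, formula, id = "participant_id", time = "day",
                        method = c("ML", "REML"),
                        rho_starts = c(-0.5, 0, 0.5),
                        fix_rho = NULL, fix_lambda = NULL, maxit = 500) {
  method <- match.arg(method)
  stopifnot_cols(data, c(id, time), "model data")
  vars <- all.vars(formula)
  stopifnot_cols(data, vars, "model data")
  df <- as.data.frame(data[, unique(c(id, time, vars))])
  df <- df[complete.cases(df), , drop = FALSE]
  mf <- stats::model.frame(formula, data = df)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  ids <- df[[id]]
  day <- as.integer(df[[time]])
  ord <- order(ids, day)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; ids <- ids[ord]; day <- day[ord]
  # drop aliased (rank-deficient) design columns, e.g. a constant weekend
  # indicator in a cohort without weekend days
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warn(sprintf("dropping aliased design column(s): %s",
                 paste(dropped, collapse = ", ")))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  n_per <- table(ids)
  if (sum(n_per >= 2) < 2) {
    abort("need at least 2 participants with at least 2 observations each.")
  }
  patterns <- ar1_patterns(ids, day)
  reml <- method == "REML"

  fixed_l <- !is.null(fix_lambda)
  fixed_r <- !is.null(fix_rho)
  nll_wrap <- function(par) {
    th <- c(if (fixed_l) log(max(fix_lambda, 1e-12)) else par[1],
            if (fixed_r) atanh(fix_rho) else par[if (fixed_l) 1 else 2])
    ar1_negloglik(th, y, X, patterns, reml)
  }

  if (fixed_l && fixed_r) {
    theta <- c(log(max(fix_lambda, 1e-12)), atanh(fix_rho))
    best <- list(value = ar1_negloglik(theta, y, X, patterns, reml),
                 convergence = 0)
  } else {
    starts <- if (fixed_r) list(0) else as.list(atanh(rho_starts))
    best <- NULL
    theta <- NULL
    for (r0 in starts) {
      par0 <- c(if (!fixed_l) log(0.5), if (!fixed_r) r0)
      opt <- if (length(par0) == 1) {
        o <- stats::optimize(function(v) nll_wrap(v), interval = c(-12, 12))
        list(par = o$minimum, value = o$objective, convergence = 0)
      } else {
        optim(par0, nll_wrap, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-10))
      }
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (best$convergence != 0) {
      abort(sprintf("LMM-AR(1) optimiser failed to converge (code %d, nll %.6f); try more iterations or simpler variance structure.",
                    best$convergence, best$value))
    }
    par <- best$par
    theta <- c(if (fixed_l) log(max(fix_lambda, 1e-12)) else par[1],
               if (fixed_r) atanh(fix_rho) else par[if (fixed_l) 1 else 2])
  }
  lambda <- exp(theta[1])
  rho <- tanh(theta[2])
  pr <- ar1_profile(y, X, patterns, lambda, rho)
  N <- length(y)
  q <- ncol(X)
  s2e <- if (reml) pr$quad / (N - q) else pr$quad / N
  s2u <- lambda * s2e
  vcov_beta <- s2e * solve(pr$XtWX)
  se <- sqrt(diag(vcov_beta))
  zval <- pr$beta / se
  pval <- 2 * pnorm(-abs(zval))
  if (!fixed_l && lambda < 1e-6) {
    warn("random-intercept variance estimated at the zero boundary.")
  }
  if (!fixed_r && abs(rho) > 0.99) {
    warn("AR(1) correlation estimated near the +/-1 boundary.")
  }
  coefs <- tibble(term = colnames(X), estimate = pr$beta, std.error = se,
                  statistic = zval, p.value = pval)
  structure(list(
    coefficients = coefs,
    sigma2_u = s2u, sigma2_e = s2e, rho = rho,
    logLik = -best$value,
    method = method,
    n_obs = N, n_participants = length(unique(ids)),
    formula = formula,
    vcov = vcov_beta,
    converged = TRUE
  ), class = "actisleep_lmm")
}

#' @export
print.actisleep_lmm <- function(x, ...) {
  cat(sprintf("Two-level LMM with AR(1) errors (%s)\n", x$method))
  cat(sprintf("  %d observations, %d participants\n", x$n_obs, x$n_participants))
  cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g, rho = %.3f, logLik = %.2f\n",
              x$sigma2_u, x$sigma2_e, x$rho, x$logLik))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @export
tidy.actisleep_lmm <- function(x, ...) x$coefficients

#' @export
glance.actisleep_lmm <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_participants = x$n_participants,
         sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e, rho = x$rho,
         logLik = x$logLik, method = x$method, converged = x$converged)
}

#' Convert a within-person coefficient to a per-hour effect
#'
#' A daily-scale coefficient `B` expresses outcome change per one
#' predictor *minute*; multiplying by 60 gives the change per additional
#' predictor hour. Outcomes on the hours scale (sleep onset/offset clock
#' hours) are additionally converted to minutes; outcomes already in
#' minutes or percent keep their unit.
#'
#' @param B Fitted coefficient (outcome units per predictor minute).
#' @param outcome_unit `"hours"`, `"minutes"` or `"percent"`.
#' @param digits Optional rounding of the returned effect.
#' @return Effect of a one-hour predictor increase: minutes for
#'   hour/minute outcomes, percentage points for percent outcomes.
#' @export
#' @examples
#' scale_coefficient(-0.005, "hours")   # -18 minutes per hour
#' scale_coefficient(0.17, "minutes")   # 10.2 minutes per hour
scale_coefficient <- function(B, outcome_unit = c("hours", "minutes", "percent"),
                              digits = NULL) {
  outcome_unit <- match.arg(outcome_unit)
  per_hour <- B * 60
  out <- switch(outcome_unit,
                hours = per_hour * 60,   # hours -> minutes
                minutes = per_hour,
                percent = per_hour)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

.sleep_outcomes <- c(onset_h = "hours", offset_h = "hours",
                     duration_min = "minutes", sme_pct = "percent")
.pa_outcomes <- c(mvpa_min = "minutes", sedentary_min = "minutes")
.covariate_terms <- c("sex", "age", "race", "mother_education",
                      "family_structure", "income_band", "bmi_pct")

#' Run the full bidirectional model suite
#'
#' Fits the sixteen two-level models: each of the four nightly sleep
#' measures (midnight-centered onset, 24-h offset, duration, maintenance
#' efficiency) regressed on each daily activity measure (MVPA, sedentary
#' minutes), and each activity measure regressed on each prior-night
#' sleep measure. Every focal predictor enters decomposed into its
#' between- and within-person components; covariates (sex, age, race,
#' mother's education, family structure, income band, BMI percentile) and
#' the direction-appropriate weekend indicator are included when
#' available.
#'
#' @param person_days Filtered person-day table.
#' @param covariates Participant covariate table, or NULL for the reduced
#'   intercept + focal + weekend specification.
#' @param method `"ML"` or `"REML"`.
#' @param ... Passed to [fit_lmm_ar1()].
#' @return An object of class `"actisleep_suite"`: a tibble with one row
#'   per model (`direction`, `outcome`, `predictor`, `outcome_unit`,
#'   `fit` list column, `error`), plus tidy coefficient tables.
#' @export
run_model_suite <- function(person_days, covariates = NULL,
                            method = "ML", ...) {
  panels <- list(
    pa_to_sleep = build_lagged_panel(person_days, covariates, "pa_to_sleep"),
    sleep_to_pa = build_lagged_panel(person_days, covariates, "sleep_to_pa")
  )
  cov_terms <- if (is.null(covariates)) character(0) else
    intersect(.covariate_terms, names(covariates))
  specs <- bind_rows(
    tidyr::expand_grid(direction = "pa_to_sleep",
                       outcome = names(.sleep_outcomes),
                       predictor = names(.pa_outcomes)),
    tidyr::expand_grid(direction = "sleep_to_pa",
                       outcome = names(.pa_outcomes),
                       predictor = names(.sleep_outcomes))
  )
  fits <- vector("list", nrow(specs))
  errors <- rep(NA_character_, nrow(specs))
  for (k in seq_len(nrow(specs))) {
    dir <- specs$direction[k]
    outc <- specs$outcome[k]
    pred <- specs$predictor[k]
    panel <- center_within_between(panels[[dir]], pred)
    rhs <- c(paste0(pred, "_bp"), paste0(pred, "_wp"), cov_terms, "weekend")
    fml <- reformulate(rhs, response = outc)
    fits[k] <- list(tryCatch(
      fit_lmm_ar1(panel, fml, method = method, ...),
      error = function(e) {
        errors[k] <<- conditionMessage(e)
        NULL
      }
    ))
  }
  units <- c(.sleep_outcomes, .pa_outcomes)
  res <- specs %>%
    mutate(outcome_unit = unname(units[.data$outcome]),
           fit = fits, error = errors)
  structure(list(models = res,
                 n_obs = vapply(panels, nrow, integer(1))),
            class = "actisleep_suite")
}

#' @export
print.actisleep_suite <- function(x, ...) {
  cat(sprintf("Bidirectional model suite: %d models (%d pa_to_sleep obs, %d sleep_to_pa obs)\n",
              nrow(x$models), x$n_obs[["pa_to_sleep"]], x$n_obs[["sleep_to_pa"]]))
  print(as.data.frame(tidy(x) %>%
                        filter(grepl("_wp$", .data$term))), digits = 3)
  invisible(x)
}

#' @export
tidy.actisleep_suite <- function(x, ...) {
  x$models %>%
    filter(!vapply(.data$fit, is.null, logical(1))) %>%
    mutate(coefs = map(.data$fit, tidy)) %>%
    select("direction", "outcome", "predictor", "outcome_unit", "coefs") %>%
    tidyr::unnest("coefs")
}

#' @export
glance.actisleep_suite <- function(x, ...) {
  x$models %>%
    filter(!vapply(.data$fit, is.null, logical(1))) %>%
    mutate(g = map(.data$fit, glance)) %>%
    select("direction", "outcome", "predictor") %>%
    dplyr::bind_cols(bind_rows(map(x$models$fit[!vapply(x$models$fit, is.null, logical(1))], glance)))
}

#' Headline within-person effects of a model suite
#'
#' Extracts each model's focal within-person coefficient and scales it to
#' a per-hour effect with [scale_coefficient()].
#'
#' @param suite An `"actisleep_suite"`.
#' @return Tibble with `direction`, `outcome`, `predictor`, `B`, `SE`,
#'   `p`, and `effect_per_hour` in the outcome's natural reporting unit.
#' @export
suite_headline <- function(suite) {
  tidy(suite) %>%
    filter(.data$term == paste0(.data$predictor, "_wp")) %>%
    mutate(effect_per_hour = purrr::map2_dbl(
      .data$estimate, .data$outcome_unit,
      function(b, u) scale_coefficient(b, u))) %>%
    select("direction", "outcome", "predictor",
           B = "estimate", SE = "std.error", p = "p.value",
           "effect_per_hour")
}
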