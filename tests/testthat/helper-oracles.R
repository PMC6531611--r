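# Independent brute-force oracles and small fixture builders. Every oracle
# here is a literal, loop-based transcription of the scoring rule it
# checks, deliberately sharing no code with the package implementation.

wrist_series <- function(counts, start = "2023-10-02 23:00:00",
                         offwrist = 0L, lux = 100, id = "P001") {
  n <- length(counts)
  tibble::tibble(
    participant_id = id,
    timestamp = lubridate::ymd_hms(start, tz = "UTC") + 30 * (seq_len(n) - 1L),
    counts = as.integer(counts),
    offwrist = as.integer(rep_len(offwrist, n)),
    lux = rep_len(lux, n)
  )
}

# forward scan: first active epoch followed by k quiet epochs
oracle_onset_idx <- function(counts, offwrist = rep(0L, length(counts)),
                             th = 10, k = 5, convention = "active") {
  n <- length(counts)
  worn <- offwrist == 0
  for (i in seq_len(n - k)) {
    if (!worn[i] || counts[i] <= th) next
    ok <- TRUE
    for (j in (i + 1):(i + k)) {
      if (!worn[j] || counts[j] > th) { ok <- FALSE; break }
    }
    if (ok) return(if (convention == "active") i else i + 1L)
  }
  NA_integer_
}

# backward scan: last active epoch preceded by k quiet epochs
oracle_offset_idx <- function(counts, offwrist = rep(0L, length(counts)),
                              th = 10, k = 5) {
  n <- length(counts)
  worn <- offwrist == 0
  hit <- NA_integer_
  for (i in (k + 1):n) {
    if (i > n) break
    if (!worn[i] || counts[i] <= th) next
    ok <- TRUE
    for (j in (i - k):(i - 1)) {
      if (!worn[j] || counts[j] > th) { ok <- FALSE; break }
    }
    if (ok) hit <- i
  }
  hit
}

# pointer-walk transcription of the 90/2/30 non-wear rule over a logical
# zero-minute indicator; returns start/end minute indices (inclusive)
oracle_nonwear_idx <- function(zero, min_len = 90, spike_max = 2, flank = 30) {
  n <- length(zero)
  res <- list()
  s <- 1L
  while (s <= n) {
    if (!zero[s]) { s <- s + 1L; next }
    e <- s
    while (TRUE) {
      while (e < n && zero[e + 1L]) e <- e + 1L
      # zero run ending at e; measure its length
      zs <- e
      while (zs > s && zero[zs - 1L]) zs <- zs - 1L
      prec <- e - zs + 1L
      # candidate spike after e
      sp_end <- e
      while (sp_end < n && !zero[sp_end + 1L]) sp_end <- sp_end + 1L
      sp_len <- sp_end - e
      if (sp_len == 0 || sp_len > spike_max || sp_end >= n || !zero[sp_end + 1L]) break
      # following zero run
      fe <- sp_end + 1L
      while (fe < n && zero[fe + 1L]) fe <- fe + 1L
      foll <- fe - sp_end
      if (prec >= flank && foll >= flank) e <- fe else break
    }
    if (e - s + 1L >= min_len) res[[length(res) + 1L]] <- c(s, e)
    s <- e + 1L
  }
  if (!length(res)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind.data.frame, lapply(res, function(v) data.frame(start = v[1], end = v[2])))
}

# exhaustive sliding-window scan for the densest MVPA cluster
oracle_cluster <- function(mvpa, W = 120) {
  L <- length(mvpa)
  if (L < W) return(list(start = NA_integer_, count = NA_real_))
  best <- -1; best_s <- NA_integer_
  for (s in 1:(L - W + 1)) {
    cnt <- sum(mvpa[s:(s + W - 1)])
    if (cnt > best) { best <- cnt; best_s <- s }
  }
  list(start = best_s, count = best)
}

# dense multivariate-normal log-likelihood over the whole cohort's
# block covariance, using only base solve()/determinant()
dense_loglik <- function(y, X, id, day, beta, s2u, s2e, rho) {
  N <- length(y)
  S <- matrix(0, N, N)
  for (a in 1:N) {
    for (b in 1:N) {
      if (id[a] == id[b]) {
        S[a, b] <- s2u + s2e * rho^abs(day[a] - day[b])
      }
    }
  }
  r <- y - X %*% beta
  drop(-0.5 * (N * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus[1] +
                 t(r) %*% solve(S, r)))
}

# simulate a toy random-intercept + AR(1) panel (independent of the
# package generator) for estimator checks
toy_panel <- function(m, n_i, beta = c(1, 0.5), s2u = 1, s2e = 1, rho = 0.3,
                      gaps = FALSE) {
  id <- rep(sprintf("p%02d", seq_len(m)), each = n_i)
  day <- rep(seq_len(n_i) - 1L, m)
  if (gaps && n_i > 2) {
    day <- as.integer(unlist(lapply(seq_len(m), function(i)
      sort(sample(0:(2 * n_i), n_i)))))
  }
  x <- rnorm(m * n_i)
  u <- rep(rnorm(m, 0, sqrt(s2u)), each = n_i)
  e <- unlist(lapply(seq_len(m), function(i) {
    d <- day[(i - 1) * n_i + seq_len(n_i)]
    z <- numeric(n_i)
    z[1] <- rnorm(1, 0, sqrt(s2e))
    for (t in 2:n_i) {
      r_t <- rho^(d[t] - d[t - 1])
      z[t] <- r_t * z[t - 1] + rnorm(1, 0, sqrt(s2e * (1 - r_t^2)))
    }
    z
  }))
  y <- beta[1] + beta[2] * x + u + e
  tibble::tibble(participant_id = id, day = day, x = x, y = y)
}

# lagged structural panel from generator truth: pairs day t-1 activity
# with night t sleep (the generating model's own alignment)
truth_lagged_panel <- function(truth) {
  truth$days |>
    dplyr::group_by(participant_id) |>
    dplyr::arrange(night, .by_group = TRUE) |>
    dplyr::mutate(mvpa_prev = dplyr::lag(mvpa_min),
                  sed_prev = dplyr::lag(sedentary_min),
                  day = night) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(mvpa_prev))
}
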