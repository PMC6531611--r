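# Internal helpers shared across modules. All timestamps in the package are
# naive local clock time stored as POSIXct in UTC (no DST, no timezone
# arithmetic): devices record wall-clock time.

.tz <- "UTC"

as_clock_time <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, .tz))
  lubridate::ymd_hms(x, tz = .tz)
}

# run-length encoding of a logical vector as index intervals
runs_of <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(
    start = starts[r$values %in% TRUE],
    end = ends[r$values %in% TRUE]
  ) %>% mutate(len = .data$end - .data$start + 1L)
}

# total overlap (in the units of the instants) between [a1,a2) and [b1,b2)
overlap_len <- function(a1, a2, b1, b2) {
  pmax(0, as.numeric(pmin(a2, b2)) - as.numeric(pmax(a1, b1)))
}

# type-7 (linear interpolation) quantiles computed row-wise on a matrix,
# vectorised across rows; equivalent to apply(m, 1, quantile, p) but fast
row_quantile7 <- function(m, probs) {
  n <- ncol(m)
  ms <- t(apply(m, 1L, sort.int, method = "radix"))
  h <- (n - 1) * probs + 1
  lo <- floor(h)
  frac <- h - lo
  out <- vapply(seq_along(probs), function(j) {
    lo_j <- lo[j]
    x_lo <- ms[, lo_j]
    if (frac[j] > 0) x_lo + frac[j] * (ms[, lo_j + 1L] - x_lo) else x_lo
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  colnames(out) <- paste0("p", round(probs * 100))
  out
}

# lag-1 sample autocorrelation per row; zero-variance rows return 0
row_lag1 <- function(m) {
  a <- m[, -ncol(m), drop = FALSE]
  b <- m[, -1L, drop = FALSE]
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  cov_ab <- rowMeans(a * b) - ma * mb
  # rowMeans uses 1/n; rescale to the n-1 convention used by var()
  k <- ncol(a)
  cov_ab <- cov_ab * k / (k - 1)
  r <- ifelse(va > 0 & vb > 0, cov_ab / sqrt(va * vb), 0)
  pmin(1, pmax(-1, r))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}
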