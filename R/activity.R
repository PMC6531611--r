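# Hip 1-s count stream processing: non-wear detection, 60-s window
# features, and minute-level activity-type classification behind a
# pluggable classifier interface.

.raw_classes <- c("sedentary", "light", "modvig", "walking", "running")
.mvpa_classes <- c("modvig", "walking", "running")

#' Aggregate a hip 1-s count stream to minute totals
#'
#' @param hip Tibble with `participant_id`, `timestamp` (1-s spacing) and
#'   `counts`. Partial leading/trailing minutes are dropped.
#' @return Tibble `participant_id`, `minute_start`, `counts` (minute sum).
#' @export
hip_minute_counts <- function(hip) {
  stopifnot_cols(hip, c("participant_id", "timestamp", "counts"), "hip")
  hip %>%
    mutate(minute_start = lubridate::floor_date(.data$timestamp, "minute")) %>%
    group_by(.data$participant_id, .data$minute_start) %>%
    summarise(counts = sum(.data$counts), n_sec = n(), .groups = "drop") %>%
    filter(.data$n_sec == 60L) %>%
    select(-"n_sec")
}

#' Detect non-wear intervals from sustained zero counts
#'
#' Implements the minute-level 90/2/30 rule: a non-wear interval is a
#' maximal span of zero-count minutes, allowing interior nonzero spikes of
#' at most 2 minutes when flanked on both sides by at least 30 consecutive
#' zero-count minutes; spans of at least 90 minutes qualify. "Zero count"
#' means the minute's summed 1-s counts equal zero.
#'
#' @param x Either a hip 1-s stream (aggregated internally) or a minute
#'   table from [hip_minute_counts()].
#' @param min_length_min Minimum qualifying span (90).
#' @param spike_max_min Maximum absorbable nonzero interruption (2).
#' @param flank_min Zero-minute run required on both sides of a spike (30).
#' @return Tibble `participant_id`, `start`, `end` (POSIXct, end
#'   exclusive) of qualifying non-wear intervals.
#' @export
detect_nonwear <- function(x, min_length_min = 90, spike_max_min = 2,
                           flank_min = 30) {
  mins <- if ("minute_start" %in% names(x)) x else hip_minute_counts(x)
  mins %>%
    group_by(.data$participant_id) %>%
    dplyr::group_split() %>%
    map(function(m) {
      m <- arrange(m, .data$minute_start)
      iv <- nonwear_intervals_idx(m$counts == 0, min_length_min,
                                  spike_max_min, flank_min)
      if (nrow(iv) == 0) {
        return(tibble(participant_id = character(),
                      start = as.POSIXct(character(), tz = .tz),
                      end = as.POSIXct(character(), tz = .tz)))
      }
      tibble(participant_id = m$participant_id[1],
             start = m$minute_start[iv$start],
             end = m$minute_start[iv$end] + 60)
    }) %>%
    list_rbind()
}

# index-level 90/2/30 scan over a zero/nonzero minute indicator
nonwear_intervals_idx <- function(zero, min_length, spike_max, flank) {
  r <- rle(as.logical(zero))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- length(r$lengths)
  zero_idx <- which(r$values)
  out <- list()
  used <- rep(FALSE, nz)
  for (zi in zero_idx) {
    if (used[zi]) next
    first <- zi
    last <- zi
    # absorb spike + next-zero pairs while the flanking rule holds
    while (last + 2 <= nz &&
           !r$values[last + 1] && r$lengths[last + 1] <= spike_max &&
           r$values[last + 2] &&
           r$lengths[last] >= flank && r$lengths[last + 2] >= flank) {
      last <- last + 2L
    }
    for (k in seq(first, last)) used[k] <- TRUE
    span <- ends[last] - starts[first] + 1L
    if (span >= min_length) {
      out[[length(out) + 1L]] <- tibble(start = starts[first], end = ends[last])
    }
  }
  if (!length(out)) return(tibble(start = integer(), end = integer()))
  bind_rows(out)
}

#' Extract 60-second window features from a hip count stream
#'
#' For every complete minute, computes the 10th/25th/50th/75th/90th
#' percentiles (type-7 linear interpolation) of the sixty 1-s counts and
#' their lag-1 sample autocorrelation (defined as 0 for a zero-variance
#' window). Partial trailing minutes are dropped with a notice.
#'
#' @param hip Hip 1-s stream tibble.
#' @return Tibble with `participant_id`, `minute_start`, `p10`, `p25`,
#'   `p50`, `p75`, `p90`, `lag1`.
#' @export
#' @examples
#' hip <- tibble::tibble(
#'   participant_id = "P1",
#'   timestamp = lubridate::ymd_hms("2023-10-02 10:00:00") + 0:59,
#'   counts = 1:60
#' )
#' extract_features(hip)$p50  # 30.5
extract_features <- function(hip) {
  stopifnot_cols(hip, c("participant_id", "timestamp", "counts"), "hip")
  hip %>%
    group_by(.data$participant_id) %>%
    dplyr::group_split() %>%
    map(extract_features_one) %>%
    list_rbind()
}

extract_features_one <- function(h) {
  h <- arrange(h, .data$timestamp)
  check_epoch_spacing(h$timestamp, 1, h$participant_id[1])
  start <- lubridate::ceiling_date(h$timestamp[1], "minute", change_on_boundary = FALSE)
  offset <- as.numeric(difftime(start, h$timestamp[1], units = "secs"))
  usable <- nrow(h) - offset
  n_min <- usable %/% 60
  dropped <- usable - n_min * 60
  if (dropped > 0 || offset > 0) {
    inform(sprintf("participant %s: dropping %d leading and %d trailing seconds (partial minutes)",
                   h$participant_id[1], as.integer(offset), as.integer(dropped)))
  }
  if (n_min == 0) {
    return(tibble(participant_id = character(),
                  minute_start = as.POSIXct(character(), tz = .tz),
                  p10 = numeric(), p25 = numeric(), p50 = numeric(),
                  p75 = numeric(), p90 = numeric(), lag1 = numeric()))
  }
  cm <- matrix(h$counts[(offset + 1):(offset + 60 * n_min)], ncol = 60, byrow = TRUE)
  q <- row_quantile7(cm, c(.10, .25, .50, .75, .90))
  tibble(
    participant_id = h$participant_id[1],
    minute_start = start + 60 * (seq_len(n_min) - 1L),
    p10 = as.numeric(q[, "p10"]), p25 = as.numeric(q[, "p25"]),
    p50 = as.numeric(q[, "p50"]), p75 = as.numeric(q[, "p75"]),
    p90 = as.numeric(q[, "p90"]),
    lag1 = as.numeric(row_lag1(cm))
  )
}

#' Train the reference minute-activity classifier
#'
#' Fits a small single-hidden-layer feed-forward network (via
#' \pkg{nnet}) mapping the 60-s window features to the five raw activity
#' classes (sedentary, light, moderate-to-vigorous games/sports, walking,
#' running). This is a trainable stand-in behind the pluggable classifier
#' interface: any function mapping a feature tibble to raw class labels
#' can replace it.
#'
#' @param labeled Tibble of features (`p10`..`p90`, `lag1`) plus a
#'   `class` column covering all five raw classes; at least 1,000 rows.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param size Hidden units (8).
#' @param decay,maxit Passed to [nnet::nnet()].
#' @return An object of class `"activity_classifier"`.
#' @export
train_reference_classifier <- function(labeled, seed = 1L, size = 8,
                                       decay = 1e-3, maxit = 300) {
  stopifnot_cols(labeled, c("p10", "p25", "p50", "p75", "p90", "lag1", "class"),
                 "labeled training data")
  if (nrow(labeled) < 1000) {
    abort("need at least 1,000 labeled minutes to train the reference classifier.")
  }
  present <- unique(as.character(labeled$class))
  missing <- setdiff(.raw_classes, present)
  if (length(missing)) {
    abort(sprintf("training data must span all five classes; missing: %s",
                  paste(missing, collapse = ", ")))
  }
  df <- labeled %>%
    mutate(class = factor(as.character(.data$class), levels = .raw_classes)) %>%
    select("class", "p10", "p25", "p50", "p75", "p90", "lag1") %>%
    as.data.frame()
  # scale features for stable optimisation; scaling stored with the model
  feats <- c("p10", "p25", "p50", "p75", "p90", "lag1")
  ctr <- vapply(df[feats], mean, numeric(1))
  scl <- vapply(df[feats], sd, numeric(1))
  scl[scl == 0] <- 1
  df[feats] <- sweep(sweep(df[feats], 2, ctr), 2, scl, "/")
  set.seed(seed)
  fit <- nnet::nnet(class ~ ., data = df, size = size, decay = decay,
                    maxit = maxit, trace = FALSE, MaxNWts = 5000)
  structure(list(fit = fit, center = ctr, scale = scl, classes = .raw_classes,
                 seed = seed),
            class = "activity_classifier")
}

#' @export
predict.activity_classifier <- function(object, newdata, ...) {
  feats <- c("p10", "p25", "p50", "p75", "p90", "lag1")
  nd <- as.data.frame(newdata[feats])
  nd <- sweep(sweep(nd, 2, object$center), 2, object$scale, "/")
  factor(as.character(predict(object$fit, nd, type = "class")),
         levels = object$classes)
}

#' Classify worn minutes into activity types
#'
#' Applies a classifier to the per-minute features of worn minutes and
#' collapses the five raw classes to the three analysed ones (`sedentary`,
#' `light`, `MVPA`, the latter comprising moderate-to-vigorous
#' games/sports, walking and running). Non-wear minutes are removed from
#' the output.
#'
#' @param features Feature tibble from [extract_features()] with a
#'   logical `nonwear` column.
#' @param classifier An `"activity_classifier"`, or any function taking
#'   the feature tibble and returning a vector of raw class labels.
#' @return Tibble `participant_id`, `minute_start`, `raw_class`,
#'   `class3`, `nonwear` (always `FALSE` here: non-wear minutes are
#'   excluded).
#' @export
classify_minutes <- function(features, classifier) {
  stopifnot_cols(features, c("participant_id", "minute_start", "nonwear"),
                 "features")
  worn <- features %>% filter(!.data$nonwear)
  if (nrow(worn) == 0) {
    return(tibble(participant_id = character(),
                  minute_start = as.POSIXct(character(), tz = .tz),
                  raw_class = character(), class3 = character(),
                  nonwear = logical()))
  }
  raw <- if (is.function(classifier)) classifier(worn) else
    predict(classifier, worn)
  raw <- as.character(raw)
  unknown <- setdiff(unique(raw), .raw_classes)
  if (length(unknown)) {
    abort(sprintf("classifier emitted unknown class(es): %s",
                  paste(unknown, collapse = ", ")))
  }
  worn %>%
    mutate(raw_class = raw,
           class3 = dplyr::case_when(
             raw %in% .mvpa_classes ~ "MVPA",
             raw == "light" ~ "light",
             TRUE ~ "sedentary"
           ),
           nonwear = FALSE) %>%
    select("participant_id", "minute_start", "raw_class", "class3", "nonwear")
}

#' Full hip-stream processing driver
#'
#' Aggregates the 1-s stream to minutes, detects non-wear (90/2/30 rule),
#' extracts 60-s features and classifies worn minutes. Returns the full
#' minute table: non-wear minutes are retained as rows with `nonwear =
#' TRUE` and `NA` classes so that accounting is conservative (labeled +
#' non-wear + dropped partial minutes = stream minutes).
#'
#' @param hip Hip 1-s stream tibble.
#' @param classifier Classifier passed to [classify_minutes()].
#' @return Minute table `participant_id`, `minute_start`, `raw_class`,
#'   `class3`, `nonwear`.
#' @export
classify_activity <- function(hip, classifier) {
  feats <- extract_features(hip)
  nw <- detect_nonwear(hip)
  feats$nonwear <- flag_in_windows(feats$participant_id, feats$minute_start, nw)
  labeled <- classify_minutes(feats, classifier)
  nonwear_rows <- feats %>%
    filter(.data$nonwear) %>%
    mutate(raw_class = NA_character_, class3 = NA_character_) %>%
    select("participant_id", "minute_start", "raw_class", "class3", "nonwear")
  bind_rows(labeled, nonwear_rows) %>%
    arrange(.data$participant_id, .data$minute_start)
}

# TRUE where instant falls in any [start, end) window of the same participant
flag_in_windows <- function(id, at, windows) {
  out <- rep(FALSE, length(at))
  if (nrow(windows) == 0) return(out)
  for (j in seq_len(nrow(windows))) {
    sel <- id == windows$participant_id[j] &
      at >= windows$start[j] & at < windows$end[j]
    out[sel] <- TRUE
  }
  out
}
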