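# End-to-end orchestration: generate (or load) -> score sleep -> classify
# activity -> align person-days -> fit the bidirectional model suite, with
# artifact writing and a human-readable report.

#' Run the full analysis pipeline
#'
#' Orchestrates every stage against a synthetic configuration (the
#' streams are generated with ground truth retained) or against on-disk
#' delimited streams. Same config and seed produce byte-identical
#' artifacts.
#'
#' @param config A [synth_config()] object, or a list with elements
#'   `wrist`, `hip`, `covariates` giving file paths of conforming CSVs.
#' @param classifier `"train"` (fit the reference network on the
#'   cohort's own ground-truth labels; synthetic input only), `"oracle"`
#'   (use the true minute labels directly; synthetic only), or a trained
#'   `"activity_classifier"` / function.
#' @param season Cohort season filter (`"all"`, `"school_year"`,
#'   `"summer"`).
#' @param sleep_options,align_options Threshold bundles ([sleep_opts()],
#'   [align_opts()]).
#' @param use_covariates Include the sociodemographic covariates in the
#'   models.
#' @param fit_models Fit the 16-model suite (disable for stage testing).
#' @param out_dir Optional directory for artifact files (streams are not
#'   re-written; the scored tables and model coefficient tables are).
#' @return A list bundle: `config`, `covariates`, `intervals`, `minutes`,
#'   `person_days` (unfiltered), `analysis_days` (after inclusion rules),
#'   `suite` (or NULL), `truth` (synthetic input only), `manifest`.
#' @export
run_pipeline <- function(config,
                         classifier = c("train", "oracle"),
                         season = "all",
                         sleep_options = sleep_opts(),
                         align_options = align_opts(),
                         use_covariates = TRUE,
                         fit_models = TRUE,
                         out_dir = NULL) {
  synthetic <- inherits(config, "synth_config")
  if (synthetic) {
    coh <- generate_cohort(config)
    wrist <- coh$wrist; hip <- coh$hip; covars <- coh$covariates
    truth <- coh$truth
  } else {
    stopifnot(all(c("wrist", "hip", "covariates") %in% names(config)))
    wrist <- read_wrist(config$wrist)
    hip <- read_hip(config$hip)
    covars <- read_covariates(config$covariates)
    truth <- NULL
  }

  intervals <- score_sleep(wrist, sleep_options)

  if (is.character(classifier)) {
    classifier <- match.arg(classifier)
    if (!synthetic) {
      abort("classifier = 'train'/'oracle' requires synthetic input with ground truth; pass a trained classifier for file input.")
    }
    minutes <- classify_activity_with_truth(hip, truth, classifier,
                                            seed = config$seed)
  } else {
    minutes <- classify_activity(hip, classifier)
  }

  person_days <- build_person_days(intervals, minutes, wrist, align_options)
  analysis_days <- filter_participants(person_days, intervals, season = season)

  suite <- NULL
  if (fit_models) {
    if (nrow(analysis_days) == 0) {
      inform("no valid participants after filtering; skipping the model suite.")
    } else {
      suite <- run_model_suite(analysis_days,
                               covariates = if (use_covariates) covars else NULL)
    }
  }

  manifest <- c(
    list(package_version = as.character(utils::packageVersion("actisleep")),
         synthetic = synthetic,
         season = season,
         classifier = if (is.character(classifier)) classifier else class(classifier)[1],
         n_participants = length(unique(wrist$participant_id))),
    if (synthetic) list(seed = config$seed, n_days = config$n_days),
    unclass(sleep_options), unclass(align_options)
  )

  bundle <- list(config = config, covariates = covars, intervals = intervals,
                 minutes = minutes, person_days = person_days,
                 analysis_days = analysis_days, suite = suite,
                 truth = truth, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# classify minutes using the cohort's ground truth: either directly
# (oracle) or via the reference network trained on those labels
classify_activity_with_truth <- function(hip, truth, mode, seed) {
  feats <- extract_features(hip)
  nw <- detect_nonwear(hip)
  feats$nonwear <- flag_in_windows(feats$participant_id, feats$minute_start, nw)
  lab <- feats %>%
    left_join(truth$minute_truth,
              by = c("participant_id", "minute_start"))
  worn_activity <- lab %>%
    filter(!.data$nonwear, .data$true_class %in% .raw_classes)
  if (mode == "train") {
    train_n <- min(nrow(worn_activity), 20000L)
    set.seed(seed)
    tr <- worn_activity %>% slice(sample(n(), train_n)) %>%
      rename(class = "true_class")
    clf <- train_reference_classifier(tr, seed = seed)
    labeled <- classify_minutes(lab %>% filter(.data$true_class %in% .raw_classes |
                                                 .data$nonwear), clf)
  } else {
    labeled <- lab %>%
      filter(!.data$nonwear, .data$true_class %in% .raw_classes) %>%
      mutate(raw_class = .data$true_class,
             class3 = dplyr::case_when(
               .data$true_class %in% .mvpa_classes ~ "MVPA",
               .data$true_class == "light" ~ "light",
               TRUE ~ "sedentary"),
             nonwear = FALSE) %>%
      select("participant_id", "minute_start", "raw_class", "class3", "nonwear")
  }
  nonwear_rows <- lab %>%
    filter(.data$nonwear) %>%
    mutate(raw_class = NA_character_, class3 = NA_character_, nonwear = TRUE) %>%
    select("participant_id", "minute_start", "raw_class", "class3", "nonwear")
  bind_rows(labeled, nonwear_rows) %>%
    arrange(.data$participant_id, .data$minute_start)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sleep_intervals(bundle$intervals, file.path(out_dir, "sleep_intervals.csv"))
  write_minutes(bundle$minutes, file.path(out_dir, "minute_labels.csv"))
  write_person_days(bundle$person_days, file.path(out_dir, "person_days.csv"))
  write_covariates(bundle$covariates, file.path(out_dir, "covariates.csv"))
  if (!is.null(bundle$suite)) {
    m <- bundle$suite$models
    for (k in seq_len(nrow(m))) {
      if (is.null(m$fit[[k]])) next
      tab <- tidy(m$fit[[k]]) %>%
        select(term = "term", B = "estimate", SE = "std.error", p = "p.value")
      readr::write_csv(tab, file.path(out_dir, sprintf(
        "model_%s_%s_by_%s.csv", m$direction[k], m$outcome[k], m$predictor[k])))
    }
  }
  mtxt <- vapply(names(bundle$manifest), function(nm) {
    sprintf("%s: %s", nm, paste(format(bundle$manifest[[nm]]), collapse = " "))
  }, character(1))
  writeLines(mtxt, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

fmt_clock <- function(h, centered = FALSE) {
  hh <- if (centered) (h + 24) %% 24 else h %% 24
  sprintf("%02d:%02d", floor(hh), round((hh - floor(hh)) * 60) %% 60)
}

#' Summarise a pipeline bundle
#'
#' Prints descriptive statistics of the analysis days (mean and SD of
#' sleep onset, offset, duration, maintenance efficiency, daily MVPA and
#' sedentary minutes) followed by each model's focal within-person
#' coefficient and its per-hour effect. Every number is taken from the
#' bundle's tables; nothing is recomputed from the streams.
#'
#' @param bundle A [run_pipeline()] result.
#' @return Invisibly, a list with `descriptives` and `headline` tibbles.
#' @export
report_bundle <- function(bundle) {
  ad <- bundle$analysis_days
  if (!is.null(ad) && nrow(ad) > 0) ad <- ad %>% filter(.data$valid_pa)
  if (is.null(ad) || nrow(ad) == 0) {
    cat("no valid participants in the analysis set\n")
    return(invisible(list(descriptives = tibble(), headline = tibble())))
  }
  desc <- tibble(
    measure = c("Sleep onset (clock)", "Sleep offset (clock)",
                "Sleep duration (min)", "Sleep maintenance efficiency (%)",
                "MVPA (min)", "Sedentary time (min)"),
    mean = c(fmt_clock(mean(ad$onset_h), centered = TRUE),
             fmt_clock(mean(ad$offset_h)),
             sprintf("%.1f", mean(ad$duration_min)),
             sprintf("%.1f", mean(ad$sme_pct)),
             sprintf("%.1f", mean(ad$mvpa_min)),
             sprintf("%.1f", mean(ad$sedentary_min))),
    sd = c(sprintf("%.2f h", sd(ad$onset_h)),
           sprintf("%.2f h", sd(ad$offset_h)),
           sprintf("%.1f", sd(ad$duration_min)),
           sprintf("%.1f", sd(ad$sme_pct)),
           sprintf("%.1f", sd(ad$mvpa_min)),
           sprintf("%.1f", sd(ad$sedentary_min)))
  )
  cat(sprintf("Analysis set: %d person-days, %d participants\n\n",
              nrow(ad), length(unique(ad$participant_id))))
  print(as.data.frame(desc), row.names = FALSE)
  headline <- tibble()
  if (!is.null(bundle$suite)) {
    headline <- suite_headline(bundle$suite)
    cat("\nFocal within-person effects (per additional predictor hour):\n")
    print(as.data.frame(headline), digits = 3, row.names = FALSE)
  }
  invisible(list(descriptives = desc, headline = headline))
}
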