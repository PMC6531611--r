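# ggplot2 visualisations for fitted objects and scored data.

#' @export
autoplot.actisleep_lmm <- function(object, ...) {
  d <- tidy(object) %>%
    filter(.data$term != "(Intercept)") %>%
    mutate(lo = .data$estimate - 1.96 * .data$std.error,
           hi = .data$estimate + 1.96 * .data$std.error)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = "coefficient (95% Wald CI)", y = NULL,
                  title = sprintf("LMM-AR(1): %s",
                                  deparse(object$formula[[2]]))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.actisleep_suite <- function(object, ...) {
  d <- tidy(object) %>%
    filter(.data$term == paste0(.data$predictor, "_wp")) %>%
    mutate(lo = .data$estimate - 1.96 * .data$std.error,
           hi = .data$estimate + 1.96 * .data$std.error,
           model = paste(.data$outcome, "~", .data$predictor))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(~ .data$direction, scales = "free") +
    ggplot2::labs(x = "within-person coefficient (95% Wald CI)", y = NULL,
                  title = "Bidirectional daily sleep-activity associations") +
    ggplot2::theme_minimal()
}

#' Plot a participant's scored days
#'
#' Timeline of person-days: sleep intervals as horizontal segments with
#' daily MVPA minutes as point size, one row per day.
#'
#' @param person_days Person-day tibble.
#' @param participant Participant id to plot (default: first).
#' @return A ggplot object.
#' @export
plot_person_days <- function(person_days, participant = NULL) {
  participant <- participant %||% person_days$participant_id[1]
  d <- person_days %>%
    filter(.data$participant_id == participant) %>%
    mutate(day = as.integer(.data$date - min(.data$date)))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$onset_h, xend = .data$offset_h,
                                       y = .data$day, yend = .data$day),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$offset_h + 2, y = .data$day,
                                     size = .data$mvpa_min), colour = "darkorange") +
    ggplot2::scale_y_reverse(breaks = d$day, labels = format(d$date, "%a %d")) +
    ggplot2::labs(x = "hours relative to midnight", y = NULL,
                  size = "MVPA (min)",
                  title = sprintf("Scored nights and daily MVPA: %s", participant)) +
    ggplot2::theme_minimal()
}
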