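# ggplot2 helpers for the main result types. Styling is intentionally
# plain; these are working plots, not publication figures.

#' Plot daily activity minutes by context category
#'
#' @param cells day cells from [summarize_day()] or a tidied cohort table
#' @return a ggplot
#' @export
plot_context_minutes <- function(cells) {
  df <- cells |>
    filter(.data$dimension == "context") |>
    pivot_longer(c("lpa_min", "mvpa_min"), names_to = "intensity",
                 values_to = "minutes") |>
    mutate(intensity = ifelse(.data$intensity == "lpa_min", "LPA", "MVPA"),
           level = factor(.data$level, levels = rev(context_levels())))
  ggplot(df, aes(x = .data$minutes, y = .data$level, fill = .data$intensity)) +
    geom_col(position = "dodge") +
    facet_wrap(~day_type) +
    labs(x = "minutes per day", y = NULL, fill = NULL,
         title = "Activity by integrated home-school context")
}

#' Plot the temporal distribution of MVPA
#'
#' @param cells day cells or a tidied cohort table containing `hour` rows
#' @return a ggplot
#' @export
plot_temporal_mvpa <- function(cells) {
  df <- filter(cells, .data$dimension == "hour")
  ggplot(df, aes(x = .data$level, y = .data$mvpa_min, group = .data$day_type,
                 colour = .data$day_type)) +
    geom_line() + geom_point() +
    labs(x = "hour of day", y = "MVPA minutes", colour = NULL,
         title = "Temporal distribution of MVPA")
}

#' @describeIn segment_trips plot fixes coloured by trip assignment
#' @param object a `trip_set`
#' @exportS3Method ggplot2::autoplot
autoplot.trip_set <- function(object, ...) {
  fx <- object$fixes |>
    mutate(state = ifelse(is.na(.data$trip_id), "stationary", .data$trip_mode))
  ggplot(fx, aes(x = .data$lon, y = .data$lat, colour = .data$state)) +
    geom_path(aes(group = 1), colour = "grey80") +
    geom_point(size = 0.8) +
    coord_quickmap() +
    labs(title = "GPS fixes by trip assignment", colour = NULL)
}

#' @describeIn aggregate_cohort plot cohort context cells
#' @param object a `cohort_summary`
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_summary <- function(object, ...) {
  plot_context_minutes(tidy(object))
}
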