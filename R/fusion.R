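#' Trip-state labels used in day summaries
#'
#' `trip_unclassified` keeps trips whose 90th-percentile speed fell below the
#' walking threshold inside the partition, so that trip-state minutes always
#' sum to total weartime.
#' @return character vector
#' @export
trip_state_levels <- function() {
  c("stationary", "pedestrian", "bicycle", "vehicle", "trip_unclassified")
}

#' Match accelerometer epochs with GPS fixes by timestamp
#'
#' Each epoch is paired with the nearest fix within `tolerance_s` of the
#' epoch timestamp (ties go to the earlier fix); epochs without such a fix
#' get `gps_present = FALSE`. All non-time columns of `fixes` (position,
#' speed, trip labels, context category, public-space flags) are carried onto
#' the matched epochs, so annotate the fixes before matching.
#'
#' @param epochs time-ordered tibble with `time` (plus wear/intensity columns)
#' @param fixes time-ordered tibble with `time` and any annotation columns
#' @param tolerance_s matching tolerance in seconds
#' @return a fused tibble: epochs plus `gps_present`, `fix_time` and the fix
#'   annotation columns
#' @export
match_epochs <- function(epochs, fixes, tolerance_s = 10) {
  n <- nrow(epochs)
  et <- as.numeric(epochs$time)
  ft <- as.numeric(fixes$time)
  idx <- rep(NA_integer_, n)
  if (length(ft) > 0) {
    lo <- findInterval(et, ft)          # last fix at or before the epoch
    hi <- lo + 1L                       # first fix after the epoch
    d_lo <- ifelse(lo >= 1L, et - ft[pmax(lo, 1L)], Inf)
    d_hi <- ifelse(hi <= length(ft), ft[pmin(hi, length(ft))] - et, Inf)
    use_lo <- d_lo <= d_hi  # tie -> earlier fix
    idx <- ifelse(use_lo, lo, hi)
    best <- pmin(d_lo, d_hi)
    idx[best > tolerance_s] <- NA_integer_
  }
  fused <- epochs
  fused$gps_present <- !is.na(idx)
  fused$fix_time <- fixes$time[idx]
  for (col in setdiff(names(fixes), "time")) {
    fused[[col]] <- fixes[[col]][idx]
  }
  fused
}

#' Apply the valid-day criterion to fused child-days
#'
#' Weartime of a day is the total duration of retained epochs, i.e. epochs
#' that are both worn and matched to a GPS fix. A weekday is valid with at
#' least `weekday_min_h` hours of such combined weartime, a weekend day with
#' at least `weekend_min_h` hours (both thresholds inclusive).
#'
#' @param fused a fused tibble from [match_epochs()] with a `wear` column;
#'   may span several days
#' @param weekday_min_h,weekend_min_h thresholds in hours
#' @param epoch_len_s epoch length in seconds
#' @return one row per day: `date`, `day_type`, `weartime_min`, `valid`
#' @export
apply_valid_day <- function(fused, weekday_min_h = 8, weekend_min_h = 6,
                            epoch_len_s = infer_epoch_len(fused$time)) {
  retained <- fused$wear & fused$gps_present
  tibble(date = date_of(fused$time), retained = retained) |>
    group_by(.data$date) |>
    summarise(weartime_min = sum(.data$retained) * epoch_len_s / 60, .groups = "drop") |>
    mutate(
      day_type = day_type_of(.data$date),
      valid = .data$weartime_min >=
        ifelse(.data$day_type == "weekday", weekday_min_h, weekend_min_h) * 60) |>
    select("date", "day_type", "weartime_min", "valid")
}

#' Weekday school schedule
#'
#' @param start school start clock time, `"HH:MM"`
#' @param bell regular end-of-school bell time
#' @param wednesday_bell,friday_bell optional shortened-day bell times; NULL
#'   means the regular bell applies
#' @return tibble with `weekday` (1 = Monday), `start_s`, `bell_s`
#' @export
school_schedule <- function(start = "08:30", bell = "14:30",
                            wednesday_bell = "12:15", friday_bell = NULL) {
  bells <- rep(hm_to_secs(bell), 5)
  if (!is.null(wednesday_bell)) bells[3] <- hm_to_secs(wednesday_bell)
  if (!is.null(friday_bell)) bells[5] <- hm_to_secs(friday_bell)
  tibble(weekday = 1:5, start_s = hm_to_secs(start), bell_s = bells)
}

# Assign each timestamp to before-school / school / after-school on
# weekdays; school time is the half-open interval [start, bell), so an epoch
# exactly at the bell is after school. NA on weekends; "schedule_unknown"
# when a weekday has no schedule row.
schedule_period <- function(time, schedule = NULL) {
  wd <- lubridate::wday(date_of(time), week_start = 1)
  s <- secs_of_day(time)
  out <- rep(NA_character_, length(time))
  wk <- wd <= 5
  if (is.null(schedule)) {
    out[wk] <- "schedule_unknown"
    return(out)
  }
  for (d in unique(wd[wk])) {
    row <- schedule[schedule$weekday == d, ]
    sel <- wd == d
    if (nrow(row) == 0) {
      out[sel] <- "schedule_unknown"
    } else {
      out[sel] <- ifelse(s[sel] < row$start_s[1], "before_school",
                         ifelse(s[sel] < row$bell_s[1], "school", "after_school"))
    }
  }
  out
}

# minutes of weartime/SB/LPA/MVPA per level of a factor key, with zero rows
# for unobserved levels
dim_cells <- function(intensity, key, levels, epoch_len_s, dimension) {
  tibble(level = factor(key, levels = levels), i = as.character(intensity)) |>
    group_by(.data$level, .drop = FALSE) |>
    summarise(
      weartime_min = n() * epoch_len_s / 60,
      sb_min = sum(.data$i == "SB", na.rm = TRUE) * epoch_len_s / 60,
      lpa_min = sum(.data$i == "LPA", na.rm = TRUE) * epoch_len_s / 60,
      mvpa_min = sum(.data$i %in% c("MPA", "VPA"), na.rm = TRUE) * epoch_len_s / 60,
      .groups = "drop") |>
    mutate(dimension = dimension, level = as.character(.data$level))
}

#' Temporal distribution of activity within a fused day
#'
#' Aggregates retained epochs into hourly bins over the recording window and,
#' on weekdays, into before-school/school/after-school periods from the
#' child's school schedule (shortened Wednesday or Friday schedules
#' supported). School time is half-open `[start, bell)`.
#'
#' @param fused fused epochs of a single day (see [match_epochs()])
#' @param schedule a [school_schedule()] or NULL (weekday epochs then fall in
#'   `schedule_unknown`)
#' @param epoch_len_s epoch length in seconds
#' @return cell tibble with dimensions `hour` and (weekdays) `schedule`
#' @export
summarize_temporal <- function(fused, schedule = NULL,
                               epoch_len_s = infer_epoch_len(fused$time)) {
  r <- fused[fused$wear & fused$gps_present, , drop = FALSE]
  hours <- sprintf("%02d", 6:21)
  hour_key <- sprintf("%02d", floor(secs_of_day(r$time) / 3600))
  cells <- dim_cells(r$intensity, hour_key, hours, epoch_len_s, "hour")
  if (nrow(r) > 0 && day_type_of(date_of(r$time[1])) == "weekday") {
    sched_levels <- c("before_school", "school", "after_school", "schedule_unknown")
    key <- schedule_period(r$time, schedule)
    cells <- bind_rows(cells,
                       dim_cells(r$intensity, key, sched_levels, epoch_len_s, "schedule"))
  }
  cells
}

#' Summarize one valid fused day into spatial, trip and temporal cells
#'
#' Produces a long table of minutes of weartime, sedentary, light (LPA) and
#' moderate-to-vigorous (MVPA) activity for each level of several dimensions:
#' `total` (whole day), `context` (integrated home-school categories),
#' `trip` (stationary or trip mode), `hour`, `schedule` (weekdays), and
#' `public_space` (one row per polygon label; non-exclusive, so not a
#' partition). Percentages are relative to weartime within the same cell.
#' Only retained epochs (worn and GPS-matched) are counted; retained epochs
#' without a context category land in `unclassified` with a warning.
#'
#' @param fused fused epochs of a single day, annotated with `category` and
#'   trip labels (see [match_epochs()])
#' @param child_id,date identifiers stamped onto the output (date inferred
#'   from the data by default)
#' @param schedule a [school_schedule()] or NULL
#' @param epoch_len_s epoch length in seconds
#' @return tibble with columns `child_id`, `date`, `day_type`, `dimension`,
#'   `level`, `weartime_min`, `sb_min`, `lpa_min`, `mvpa_min`, `lpa_pct`,
#'   `mvpa_pct`
#' @export
summarize_day <- function(fused, child_id = NA_character_, date = NULL,
                          schedule = NULL,
                          epoch_len_s = infer_epoch_len(fused$time)) {
  r <- fused[fused$wear & fused$gps_present, , drop = FALSE]
  date <- date %||% (if (nrow(r)) date_of(r$time[1]) else date_of(fused$time[1]))

  cat_key <- if ("category" %in% names(r)) as.character(r$category) else rep(NA, nrow(r))
  if (anyNA(cat_key) && nrow(r) > 0) {
    warn(sprintf("%d retained epochs without a context category counted as unclassified",
                 sum(is.na(cat_key))))
    cat_key[is.na(cat_key)] <- "unclassified"
  }
  trip_key <- if ("trip_id" %in% names(r)) {
    ifelse(is.na(r$trip_id), "stationary",
           ifelse(r$trip_mode == "unclassified", "trip_unclassified", r$trip_mode))
  } else {
    rep("stationary", nrow(r))
  }

  cells <- bind_rows(
    dim_cells(r$intensity, rep("all", nrow(r)), "all", epoch_len_s, "total"),
    dim_cells(r$intensity, cat_key, context_levels(), epoch_len_s, "context"),
    dim_cells(r$intensity, trip_key, trip_state_levels(), epoch_len_s, "trip"),
    summarize_temporal(r, schedule, epoch_len_s)
  )
  ps_cols <- grep("^ps_", names(r), value = TRUE)
  for (col in ps_cols) {
    sel <- !is.na(r[[col]]) & r[[col]]
    cells <- bind_rows(cells,
      dim_cells(r$intensity[sel], rep(sub("^ps_", "", col), sum(sel)),
                sub("^ps_", "", col), epoch_len_s, "public_space"))
  }
  cells |>
    mutate(
      child_id = child_id, date = date, day_type = day_type_of(date),
      lpa_pct = ifelse(.data$weartime_min > 0, 100 * .data$lpa_min / .data$weartime_min, NA_real_),
      mvpa_pct = ifelse(.data$weartime_min > 0, 100 * .data$mvpa_min / .data$weartime_min, NA_real_)) |>
    select("child_id", "date", "day_type", "dimension", "level",
           "weartime_min", "sb_min", "lpa_min", "mvpa_min", "lpa_pct", "mvpa_pct")
}

#' Aggregate valid child-days into a cohort table
#'
#' Days (not children) are the unit of analysis: each cell reports the
#' unweighted mean and sample standard deviation (n-1 denominator) over all
#' contributing valid days, split by day type. Cells contributed by a single
#' day report an SD of 0 and are flagged. Percentages are aggregate ratios:
#' mean minutes divided by mean weartime in the cell.
#'
#' @param cells row-bound day cell tables from [summarize_day()]
#' @return tibble of class `cohort_summary`
#' @export
aggregate_cohort <- function(cells) {
  if (nrow(cells) == 0) {
    warn("no valid days to aggregate; returning an empty table")
    out <- tibble(day_type = factor(character(), levels = c("weekday", "weekend")),
                  dimension = character(), level = character(), n_days = integer(),
                  weartime_min = numeric(), weartime_sd = numeric(),
                  lpa_min = numeric(), lpa_sd = numeric(), lpa_pct = numeric(),
                  mvpa_min = numeric(), mvpa_sd = numeric(), mvpa_pct = numeric(),
                  single_day = logical())
    class(out) <- c("cohort_summary", class(out))
    return(out)
  }
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  out <- cells |>
    group_by(.data$day_type, .data$dimension, .data$level) |>
    summarise(
      n_days = n(),
      weartime_sd = sd0(.data$weartime_min), weartime_min = mean(.data$weartime_min),
      lpa_sd = sd0(.data$lpa_min), lpa_min = mean(.data$lpa_min),
      mvpa_sd = sd0(.data$mvpa_min), mvpa_min = mean(.data$mvpa_min),
      .groups = "drop") |>
    mutate(
      lpa_pct = ifelse(.data$weartime_min > 0, 100 * .data$lpa_min / .data$weartime_min, NA_real_),
      mvpa_pct = ifelse(.data$weartime_min > 0, 100 * .data$mvpa_min / .data$weartime_min, NA_real_),
      single_day = .data$n_days == 1L) |>
    select("day_type", "dimension", "level", "n_days",
           "weartime_min", "weartime_sd", "lpa_min", "lpa_sd", "lpa_pct",
           "mvpa_min", "mvpa_sd", "mvpa_pct", "single_day")
  class(out) <- c("cohort_summary", class(out))
  out
}

#' @describeIn aggregate_cohort the table as a plain tibble
#' @param x a `cohort_summary`
#' @param ... unused
#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cohort_summary")
  out
}

#' @describeIn aggregate_cohort one-row overview (day counts, daily MVPA)
#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) {
  tot <- x[x$dimension == "total", ]
  tibble(
    n_weekdays = sum(tot$n_days[tot$day_type == "weekday"]),
    n_weekend_days = sum(tot$n_days[tot$day_type == "weekend"]),
    weekday_mvpa_min = mean(tot$mvpa_min[tot$day_type == "weekday"]),
    weekend_mvpa_min = mean(tot$mvpa_min[tot$day_type == "weekend"]))
}
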