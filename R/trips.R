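#' Speed bounds for travel-mode classification
#'
#' Trips are labelled by the 90th percentile of their member fix speeds:
#' below `walk_min` the trip stays unclassified, `[walk_min, bike_min)` is
#' pedestrian, `[bike_min, vehicle_min)` is bicycle and at or above
#' `vehicle_min` is vehicle. The bicycle/vehicle boundary is configurable
#' because both 35 km/h and 25 km/h are in circulation for motorized travel
#' in child cohorts; 35 is the default here.
#'
#' @param walk_min,bike_min,vehicle_min ordered speed thresholds in km/h
#' @return a named list of class `mode_bounds`
#' @export
mode_bounds <- function(walk_min = 1, bike_min = 10, vehicle_min = 35) {
  if (!(walk_min < bike_min && bike_min < vehicle_min)) {
    abort("mode bounds must be strictly increasing")
  }
  structure(list(walk_min = walk_min, bike_min = bike_min, vehicle_min = vehicle_min),
            class = "mode_bounds")
}

#' Travel-mode labels
#' @return character vector of mode labels used for trips
#' @export
mode_levels <- function() c("pedestrian", "bicycle", "vehicle", "unclassified")

#' Classify a trip's travel mode from its fix speeds
#'
#' The 90th percentile is computed with linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param speeds_kmph numeric vector of member fix speeds (pause fixes are
#'   conventionally excluded by the caller)
#' @param bounds a [mode_bounds()]
#' @return list with `mode` (character) and `p90_speed_kmph`
#' @export
#' @examples
#' classify_mode(c(rep(5, 8), 40, 40))
classify_mode <- function(speeds_kmph, bounds = mode_bounds()) {
  if (length(speeds_kmph) == 0 || all(is.na(speeds_kmph))) {
    abort("cannot classify a trip with no member speeds")
  }
  p90 <- unname(quantile(speeds_kmph, 0.9, type = 7, na.rm = TRUE))
  mode <- if (p90 < bounds$walk_min) "unclassified"
          else if (p90 < bounds$bike_min) "pedestrian"
          else if (p90 < bounds$vehicle_min) "bicycle"
          else "vehicle"
  list(mode = mode, p90_speed_kmph = p90)
}

#' Segment cleaned GPS fixes into transport trips
#'
#' A trip opens at the first fix of a run of `start_run` consecutive fixes
#' with speed at least `start_speed_kmph`. Once a trip is open, any spell of
#' sub-threshold fixes lasting at most `pause_max_s` (measured from the first
#' to the last still fix of the spell) is an internal pause, and a single
#' above-threshold fix resumes the trip; a spell longer than `pause_max_s`
#' closes the trip at the last above-threshold fix. Candidate trips are then
#' discarded when their summed great-circle path length is below
#' `min_dist_m`, their start-to-end duration is below `min_dur_s`, or any
#' time gap between consecutive member fixes exceeds `gap_max_s` (the gap
#' rule discards the whole trip rather than splitting it). Surviving trips
#' get a travel mode from [classify_mode()] applied to their non-pause fix
#' speeds; pause time counts toward trip duration.
#'
#' @param fixes cleaned, time-ordered tibble with `time`, `lat`, `lon`,
#'   `speed_kmph`
#' @param start_speed_kmph minimum speed counting as movement
#' @param start_run number of consecutive moving fixes that opens a trip
#' @param pause_max_s longest still spell kept inside a trip, seconds
#' @param gap_max_s largest tolerated gap between member fixes, seconds
#' @param min_dist_m,min_dur_s minimum surviving trip distance and duration
#' @param bounds a [mode_bounds()] for mode classification
#' @return a `trip_set`: list with `trips` (one row per surviving trip),
#'   `fixes` (input plus `trip_id`, `trip_role`, `trip_mode`), `pauses`, and
#'   a `dropped` count per filter
#' @export
segment_trips <- function(fixes, start_speed_kmph = 1, start_run = 3,
                          pause_max_s = 120, gap_max_s = 30,
                          min_dist_m = 100, min_dur_s = 60,
                          bounds = mode_bounds()) {
  n <- nrow(fixes)
  empty_trips <- tibble(
    trip_id = integer(), start_time = as.POSIXct(character(), tz = "UTC"),
    end_time = as.POSIXct(character(), tz = "UTC"), n_fixes = integer(),
    distance_m = numeric(), duration_s = numeric(),
    p90_speed_kmph = numeric(), mode = character(), n_pauses = integer())
  empty_pauses <- tibble(trip_id = integer(),
                         start_time = as.POSIXct(character(), tz = "UTC"),
                         end_time = as.POSIXct(character(), tz = "UTC"),
                         duration_s = numeric())
  dropped <- c(distance = 0L, duration = 0L, gap = 0L)
  fixes$trip_id <- rep(NA_integer_, n)
  fixes$trip_role <- rep("stationary", n)
  fixes$trip_mode <- rep(NA_character_, n)
  out <- structure(list(trips = empty_trips, fixes = fixes,
                        pauses = empty_pauses, dropped = dropped),
                   class = "trip_set")
  if (n == 0) return(out)
  if (is.unsorted(as.numeric(fixes$time))) abort("fixes must be time-ordered")

  t_num <- as.numeric(fixes$time)
  moving <- !is.na(fixes$speed_kmph) & fixes$speed_kmph >= start_speed_kmph
  r <- rle(moving)
  n_runs <- length(r$lengths)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L

  # chain moving runs across tolerable pauses
  chains <- list()
  open <- FALSE
  cur_first <- cur_last <- NA_integer_
  for (k in seq_len(n_runs)) {
    if (r$values[k]) {
      if (open) {
        cur_last <- k
      } else if (r$lengths[k] >= start_run) {
        open <- TRUE
        cur_first <- cur_last <- k
      }
    } else if (open) {
      spell_dur <- t_num[run_end[k]] - t_num[run_start[k]]
      if (spell_dur > pause_max_s) {
        chains[[length(chains) + 1L]] <- c(cur_first, cur_last)
        open <- FALSE
      }
    }
  }
  if (open) chains[[length(chains) + 1L]] <- c(cur_first, cur_last)
  if (length(chains) == 0) return(out)

  trips <- list()
  pauses <- list()
  trip_id <- 0L
  for (ch in chains) {
    i0 <- run_start[ch[1]]
    i1 <- run_end[ch[2]]
    idx <- i0:i1
    dur <- t_num[i1] - t_num[i0]
    dist <- sum(haversine_m(fixes$lon[idx[-length(idx)]], fixes$lat[idx[-length(idx)]],
                            fixes$lon[idx[-1]], fixes$lat[idx[-1]]))
    if (dist < min_dist_m) { dropped[["distance"]] <- dropped[["distance"]] + 1L; next }
    if (dur < min_dur_s)   { dropped[["duration"]] <- dropped[["duration"]] + 1L; next }
    if (any(diff(t_num[idx]) > gap_max_s)) { dropped[["gap"]] <- dropped[["gap"]] + 1L; next }

    trip_id <- trip_id + 1L
    pause_runs <- setdiff(seq(ch[1], ch[2]), seq(ch[1], ch[2])[r$values[seq(ch[1], ch[2])]])
    move_idx <- idx[moving[idx]]
    cl <- classify_mode(fixes$speed_kmph[move_idx], bounds)
    fixes$trip_id[idx] <- trip_id
    fixes$trip_role[idx] <- ifelse(moving[idx], "moving", "pause")
    fixes$trip_mode[idx] <- cl$mode
    for (pk in pause_runs) {
      pauses[[length(pauses) + 1L]] <- tibble(
        trip_id = trip_id,
        start_time = fixes$time[run_start[pk]],
        end_time = fixes$time[run_end[pk]],
        duration_s = t_num[run_end[pk]] - t_num[run_start[pk]])
    }
    trips[[length(trips) + 1L]] <- tibble(
      trip_id = trip_id, start_time = fixes$time[i0], end_time = fixes$time[i1],
      n_fixes = length(idx), distance_m = dist, duration_s = dur,
      p90_speed_kmph = cl$p90_speed_kmph, mode = cl$mode,
      n_pauses = length(pause_runs))
  }
  structure(list(
    trips = if (length(trips)) list_rbind(trips) else empty_trips,
    fixes = fixes,
    pauses = if (length(pauses)) list_rbind(pauses) else empty_pauses,
    dropped = dropped
  ), class = "trip_set")
}

#' @export
print.trip_set <- function(x, ...) {
  cat(sprintf("<trip_set> %d trips over %d fixes (%d candidate trips dropped)\n",
              nrow(x$trips), nrow(x$fixes), sum(x$dropped)))
  if (nrow(x$trips)) print(x$trips, ...)
  invisible(x)
}

#' @describeIn segment_trips one row per surviving trip
#' @param x a `trip_set`
#' @param ... unused
#' @exportS3Method generics::tidy
tidy.trip_set <- function(x, ...) x$trips

#' @describeIn segment_trips one-row overview of the segmentation
#' @exportS3Method generics::glance
glance.trip_set <- function(x, ...) {
  tibble(
    n_fixes = nrow(x$fixes),
    n_trips = nrow(x$trips),
    n_dropped = sum(x$dropped),
    total_distance_m = sum(x$trips$distance_m),
    total_duration_s = sum(x$trips$duration_s),
    n_pauses = nrow(x$pauses))
}
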