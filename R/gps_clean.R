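#' Remove outlier GPS fixes
#'
#' Applies three sequential outlier rules, in which "previous" always means
#' the previous *retained* fix:
#' 1. fixes with a missing speed estimate are removed;
#' 2. fixes faster than `max_speed_kmph` whose absolute speed difference from
#'    the previous retained fix exceeds `max_speed_diff_kmph` are removed;
#' 3. fixes whose absolute elevation change from the previous retained fix
#'    exceeds `max_elev_diff_m` are removed (skipped when elevation is
#'    missing).
#'
#' Cleaning is idempotent: running it on its own output changes nothing. Drop
#' counts per rule are attached as the `"dropped"` attribute for attrition
#' logging.
#'
#' @param fixes tibble with columns `time`, `lat`, `lon`, `speed_kmph` and
#'   optionally `ele`; must be time-ordered
#' @param max_speed_kmph,max_speed_diff_kmph,max_elev_diff_m rule thresholds
#' @return the retained fixes
#' @export
clean_gps <- function(fixes, max_speed_kmph = 130, max_speed_diff_kmph = 30,
                      max_elev_diff_m = 1000) {
  n <- nrow(fixes)
  dropped <- c(missing_speed = 0L, speed_jump = 0L, elev_jump = 0L)
  if (n == 0) {
    attr(fixes, "dropped") <- dropped
    return(fixes)
  }
  if (is.unsorted(as.numeric(fixes$time))) abort("fixes must be time-ordered")
  speed <- fixes$speed_kmph
  ele <- if ("ele" %in% names(fixes)) fixes$ele else rep(NA_real_, n)
  keep <- logical(n)
  prev_speed <- NA_real_
  prev_ele <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(speed[i])) {
      dropped[["missing_speed"]] <- dropped[["missing_speed"]] + 1L
      next
    }
    if (speed[i] > max_speed_kmph && !is.na(prev_speed) &&
        abs(speed[i] - prev_speed) > max_speed_diff_kmph) {
      dropped[["speed_jump"]] <- dropped[["speed_jump"]] + 1L
      next
    }
    if (!is.na(ele[i]) && !is.na(prev_ele) &&
        abs(ele[i] - prev_ele) > max_elev_diff_m) {
      dropped[["elev_jump"]] <- dropped[["elev_jump"]] + 1L
      next
    }
    keep[i] <- TRUE
    prev_speed <- speed[i]
    if (!is.na(ele[i])) prev_ele <- ele[i]
  }
  out <- fixes[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Derive speed from positions where the logger did not provide it
#'
#' Speed between consecutive fixes is the haversine distance divided by the
#' time difference, in km/h; the first fix gets 0. Fixes sharing a timestamp
#' with their predecessor are dropped as duplicates. By default only missing
#' speeds are filled (the logged speed is trusted); with
#' `overwrite = TRUE` every speed is recomputed.
#'
#' @param fixes tibble with `time`, `lat`, `lon` and optionally `speed_kmph`
#' @param overwrite recompute all speeds instead of filling missing ones
#' @return fixes with `speed_kmph` populated
#' @export
derive_speed <- function(fixes, overwrite = FALSE) {
  if (nrow(fixes) == 0) return(fixes)
  dt <- c(Inf, diff(as.numeric(fixes$time)))
  dup <- dt == 0
  if (any(dup)) {
    warn(sprintf("dropping %d duplicate-timestamp fixes", sum(dup)))
    fixes <- fixes[!dup, , drop = FALSE]
    dt <- c(Inf, diff(as.numeric(fixes$time)))
  }
  n <- nrow(fixes)
  step_m <- c(0, haversine_m(fixes$lon[-n], fixes$lat[-n], fixes$lon[-1], fixes$lat[-1]))
  derived <- ifelse(seq_len(n) == 1L, 0, step_m / dt * 3.6)
  if (overwrite || !"speed_kmph" %in% names(fixes)) {
    fixes$speed_kmph <- derived
  } else {
    fixes$speed_kmph <- ifelse(is.na(fixes$speed_kmph), derived, fixes$speed_kmph)
  }
  fixes
}
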