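# Timestamps are timezone-naive local clock time, represented as POSIXct with
# tz = "UTC" throughout (school bells and the 6-8 AM anchor window are local
# clock concepts; no DST transitions are modelled).

#' Parse "HH:MM" or "HH:MM:SS" clock time to seconds of day
#' @param x character vector of clock times
#' @return numeric seconds since midnight
#' @keywords internal
hm_to_secs <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    p[1] * 3600 + p[2] * 60 + if (length(p) > 2) p[3] else 0
  }, numeric(1))
}

#' Build a naive local timestamp from a date and seconds of day
#' @keywords internal
naive_time <- function(date, secs) {
  as.POSIXct(as.character(date), tz = "UTC") + secs
}

#' Seconds since local midnight of a naive timestamp
#' @keywords internal
secs_of_day <- function(time) {
  as.numeric(time) %% 86400
}

#' Local calendar date of a naive timestamp
#' @keywords internal
date_of <- function(time) {
  as.Date(time, tz = "UTC")
}

#' Classify calendar dates as weekday or weekend
#'
#' Saturdays and Sundays are weekend days; Monday to Friday are weekdays.
#'
#' @param date a `Date` vector
#' @return factor with levels `weekday`, `weekend`
#' @export
#' @examples
#' day_type_of(as.Date("2021-06-05")) # Saturday -> weekend
day_type_of <- function(date) {
  wd <- lubridate::wday(date, week_start = 1)
  factor(ifelse(wd >= 6, "weekend", "weekday"), levels = c("weekday", "weekend"))
}

#' Regular epoch timestamp grid for one recording day
#'
#' @param date calendar date
#' @param epoch_len_s epoch length in seconds
#' @param start_s,end_s recording window bounds as seconds of day
#'   (default 06:00-22:00, the GPS logging window)
#' @return POSIXct vector of epoch start times
#' @export
epoch_grid <- function(date, epoch_len_s = 10, start_s = 6 * 3600, end_s = 22 * 3600) {
  naive_time(date, seq(start_s, end_s - epoch_len_s, by = epoch_len_s))
}

#' Infer the epoch length of a regular stream (mode of time differences)
#' @keywords internal
infer_epoch_len <- function(time) {
  if (length(time) < 2) return(10)
  d <- as.numeric(diff(as.numeric(time)))
  as.numeric(names(sort(table(d), decreasing = TRUE))[1])
}
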