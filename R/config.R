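#' Pipeline configuration
#'
#' Gathers every numeric constant the pipeline applies: epoch length,
#' intensity cut-points at their reference epoch, non-wear window rule, GPS
#' cleaning thresholds, trip segmentation parameters and filters, mode speed
#' bounds, the 10/100/400/800 m distance bands and the 10 m public-space
#' buffer, valid-day thresholds, the epoch-fix matching tolerance, the
#' home-anchor morning window and the distance-provider settings. Values are
#' validated on construction and round-trip losslessly through
#' [write_config()] / [read_config()].
#'
#' @param epoch_len_s accelerometer epoch and GPS cadence, seconds
#' @param sed_max,mod_min,vig_min,reference_epoch_s intensity cut-points
#' @param nonwear_block_min,nonwear_window_min,nonwear_sd_mg,nonwear_range_mg,nonwear_min_window_min
#'   non-wear detection rule (see [detect_nonwear()])
#' @param max_speed_kmph,max_speed_diff_kmph,max_elev_diff_m GPS cleaning
#' @param derive_speed recompute speeds from positions when the logger speed
#'   is missing
#' @param start_speed_kmph,start_run,pause_max_s,gap_max_s,trip_min_dist_m,trip_min_dur_s
#'   trip segmentation (see [segment_trips()])
#' @param walk_min,bike_min,vehicle_min mode speed bounds, km/h
#' @param bands context distance band edges, metres
#' @param buffer_m public-space spatial-join buffer, metres
#' @param weekday_min_h,weekend_min_h valid-day thresholds, hours
#' @param match_tolerance_s epoch-fix matching tolerance, seconds
#' @param provider_mode,detour_factor distance provider for the wider bands
#' @param anchor_window morning window for home-anchor inference
#' @param seed default seed for any randomized step
#' @return a validated list of class `pipeline_config`
#' @export
pipeline_config <- function(epoch_len_s = 10,
                            sed_max = 25, mod_min = 574, vig_min = 1003,
                            reference_epoch_s = 15,
                            nonwear_block_min = 15, nonwear_window_min = 60,
                            nonwear_sd_mg = 13, nonwear_range_mg = 50,
                            nonwear_min_window_min = 30,
                            max_speed_kmph = 130, max_speed_diff_kmph = 30,
                            max_elev_diff_m = 1000,
                            derive_speed = FALSE,
                            start_speed_kmph = 1, start_run = 3,
                            pause_max_s = 120, gap_max_s = 30,
                            trip_min_dist_m = 100, trip_min_dur_s = 60,
                            walk_min = 1, bike_min = 10, vehicle_min = 35,
                            bands = c(10, 100, 400, 800), buffer_m = 10,
                            weekday_min_h = 8, weekend_min_h = 6,
                            match_tolerance_s = 10,
                            provider_mode = "euclidean", detour_factor = 1,
                            anchor_window = c("06:00", "08:00"),
                            seed = 1) {
  cfg <- as.list(environment())
  pos <- c(cfg$epoch_len_s, cfg$reference_epoch_s, cfg$nonwear_block_min,
           cfg$nonwear_window_min, cfg$nonwear_sd_mg, cfg$nonwear_range_mg,
           cfg$max_speed_kmph, cfg$max_speed_diff_kmph, cfg$max_elev_diff_m,
           cfg$start_speed_kmph, cfg$start_run, cfg$pause_max_s, cfg$gap_max_s,
           cfg$trip_min_dist_m, cfg$trip_min_dur_s, cfg$buffer_m,
           cfg$match_tolerance_s)
  if (any(pos <= 0)) abort("pipeline_config: thresholds must be positive")
  if (cfg$weekday_min_h < 0 || cfg$weekend_min_h < 0) {
    abort("pipeline_config: valid-day thresholds must be nonnegative")
  }
  if (length(cfg$bands) != 4 || any(diff(cfg$bands) <= 0)) {
    abort("pipeline_config: bands must be four strictly increasing distances")
  }
  if (!(cfg$sed_max < cfg$mod_min && cfg$mod_min < cfg$vig_min)) {
    abort("pipeline_config: cut-points must be ordered")
  }
  if (!(cfg$walk_min < cfg$bike_min && cfg$bike_min < cfg$vehicle_min)) {
    abort("pipeline_config: mode bounds must be ordered")
  }
  if (!cfg$provider_mode %in% c("euclidean", "detour")) {
    abort("pipeline_config: provider_mode must be 'euclidean' or 'detour' (plug a network provider in programmatically)")
  }
  if (cfg$detour_factor < 1) abort("pipeline_config: detour_factor must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

config_cutpoints <- function(config) {
  scale_cutpoints(
    cutpoint_set(config$sed_max, config$mod_min, config$vig_min,
                 config$reference_epoch_s),
    config$epoch_len_s)
}

config_provider <- function(config) {
  dist_provider(config$provider_mode, detour_factor = config$detour_factor)
}

config_bounds <- function(config) {
  mode_bounds(config$walk_min, config$bike_min, config$vehicle_min)
}
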