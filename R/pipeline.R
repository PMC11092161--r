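#' Process one child-day through the full pipeline
#'
#' Runs non-wear detection and intensity classification on the epoch stream,
#' cleaning, optional speed derivation and trip segmentation on the GPS
#' stream, context-category and public-space assignment on the annotated
#' fixes, epoch-fix matching, the valid-day criterion and, for valid days,
#' the day summary. Per-stage record counts are returned for attrition
#' logging.
#'
#' @param epochs tibble with `time`, `counts` and optional raw summary columns
#' @param fixes tibble with `time`, `lat`, `lon`, `ele`, `speed_kmph`
#' @param anchors an [anchor_set()]
#' @param polygons optional [polygon_set()] of public spaces
#' @param schedule optional [school_schedule()]
#' @param config a [pipeline_config()]
#' @param child_id identifier stamped on outputs
#' @return list with `day` (one-row validity tibble), `cells` (day summary,
#'   NULL when invalid), `trips`, `fused`, `counters`
#' @export
process_day <- function(epochs, fixes, anchors, polygons = NULL,
                        schedule = NULL, config = pipeline_config(),
                        child_id = NA_character_) {
  stopifnot(nrow(epochs) > 0)
  date <- date_of(epochs$time[1])
  dt <- as.character(day_type_of(date))

  epochs <- detect_nonwear(
    epochs, block_min = config$nonwear_block_min,
    window_min = config$nonwear_window_min, sd_thresh_mg = config$nonwear_sd_mg,
    range_thresh_mg = config$nonwear_range_mg,
    min_window_min = config$nonwear_min_window_min,
    epoch_len_s = config$epoch_len_s)
  epochs <- classify_intensity(epochs, config_cutpoints(config),
                               epoch_len_s = config$epoch_len_s)

  counters <- list(epochs_input = nrow(epochs),
                   epochs_nonwear = sum(!epochs$wear),
                   gps_input = nrow(fixes))
  cleaned <- clean_gps(fixes, config$max_speed_kmph, config$max_speed_diff_kmph,
                       config$max_elev_diff_m)
  dropped <- attr(cleaned, "dropped")
  counters$gps_removed_missing_speed <- unname(dropped[["missing_speed"]])
  counters$gps_removed_speed_jump <- unname(dropped[["speed_jump"]])
  counters$gps_removed_elev_jump <- unname(dropped[["elev_jump"]])
  counters$gps_retained <- nrow(cleaned)
  if (config$derive_speed) cleaned <- derive_speed(cleaned)

  ts <- segment_trips(cleaned, start_speed_kmph = config$start_speed_kmph,
                      start_run = config$start_run, pause_max_s = config$pause_max_s,
                      gap_max_s = config$gap_max_s, min_dist_m = config$trip_min_dist_m,
                      min_dur_s = config$trip_min_dur_s, bounds = config_bounds(config))
  counters$trips_kept <- nrow(ts$trips)
  counters$trips_removed_distance <- unname(ts$dropped[["distance"]])
  counters$trips_removed_duration <- unname(ts$dropped[["duration"]])
  counters$trips_removed_gap <- unname(ts$dropped[["gap"]])

  annot <- assign_category(ts$fixes, anchors, config_provider(config),
                           day_type = dt, bands = config$bands)
  if (!is.null(polygons)) {
    annot <- assign_public_space(annot, polygons, buffer_m = config$buffer_m)
  }

  fused <- match_epochs(epochs, annot, tolerance_s = config$match_tolerance_s)
  counters$epochs_unmatched <- sum(!fused$gps_present)
  counters$epochs_retained <- sum(fused$wear & fused$gps_present)

  day <- apply_valid_day(fused, config$weekday_min_h, config$weekend_min_h,
                         epoch_len_s = config$epoch_len_s)
  day$child_id <- child_id
  cells <- NULL
  if (day$valid[1]) {
    cells <- summarize_day(fused, child_id = child_id, date = date,
                           schedule = schedule, epoch_len_s = config$epoch_len_s)
  }
  list(day = day, cells = cells, trips = ts$trips, fused = fused,
       counters = counters)
}

#' Infer a child's anchors from their GPS days
#'
#' Infers the weekday and weekend home anchor from the early-morning fixes
#' across all the child's days ([infer_home_anchor()]); when a day type has
#' no qualifying fixes the postal-code centroid is used with a warning. The
#' postal validation distance is computed for inferred anchors.
#'
#' @param all_fixes row-bound GPS fixes across the child's days
#' @param school_point,school_polygon school anchor geometry
#' @param postal_centroid parent-reported postal-code centroid (fallback)
#' @param sleep_home_dates dates the child slept at home (NULL = all)
#' @param window morning clock window
#' @return list with the [anchor_set()] and an `anchor_log` tibble
#' @export
infer_anchors <- function(all_fixes, school_point, school_polygon = NULL,
                          postal_centroid = NULL, sleep_home_dates = NULL,
                          window = c("06:00", "08:00")) {
  get_anchor <- function(dtype) {
    tryCatch(
      infer_home_anchor(all_fixes, sleep_home_dates, dtype, window),
      error = function(e) {
        if (is.null(postal_centroid)) {
          abort(sprintf("no %s morning fixes and no postal centroid to fall back to", dtype))
        }
        warn(sprintf("no %s morning fixes; falling back to the postal-code centroid", dtype))
        tibble(day_type = dtype, lon = postal_centroid[1],
               lat = postal_centroid[2], n_fixes = 0L)
      })
  }
  wk <- get_anchor("weekday")
  we <- get_anchor("weekend")
  log <- bind_rows(wk, we)
  log$postal_dist_m <- if (is.null(postal_centroid)) NA_real_ else
    map_dbl(seq_len(nrow(log)),
            function(i) validate_home(c(log$lon[i], log$lat[i]), postal_centroid))
  anchors <- anchor_set(
    home_weekday = c(wk$lon, wk$lat), home_weekend = c(we$lon, we$lat),
    school_point = school_point, school_polygon = school_polygon,
    postal_centroid = postal_centroid)
  list(anchors = anchors, anchor_log = log)
}

#' Process all days of one child
#'
#' @param days list of `list(epochs = , fixes = )` per day
#' @param school_point,school_polygon,postal_centroid,sleep_home_dates anchor
#'   inputs (see [infer_anchors()])
#' @param polygons optional [polygon_set()]
#' @param schedule optional [school_schedule()]
#' @param config a [pipeline_config()]
#' @param child_id identifier
#' @return list with `days`, `cells`, `trips`, `anchor_log`, `counters`
#' @export
process_child <- function(days, school_point, school_polygon = NULL,
                          postal_centroid = NULL, sleep_home_dates = NULL,
                          polygons = NULL, schedule = NULL,
                          config = pipeline_config(), child_id = NA_character_) {
  all_fixes <- list_rbind(map(days, function(d) d$fixes[c("time", "lat", "lon")]))
  anch <- infer_anchors(all_fixes, school_point, school_polygon,
                        postal_centroid, sleep_home_dates,
                        window = config$anchor_window)
  day_rows <- list(); cell_rows <- list(); trip_rows <- list()
  counters <- NULL
  for (d in days) {
    if (is.null(d$fixes) || nrow(d$fixes) == 0 || nrow(d$epochs) == 0) {
      date <- date_of(d$epochs$time[1])
      day_rows[[length(day_rows) + 1L]] <- tibble(
        date = date, day_type = day_type_of(date), weartime_min = 0,
        valid = FALSE, child_id = child_id)
      next
    }
    res <- process_day(d$epochs, d$fixes, anch$anchors, polygons, schedule,
                       config, child_id = child_id)
    day_rows[[length(day_rows) + 1L]] <- res$day
    if (!is.null(res$cells)) cell_rows[[length(cell_rows) + 1L]] <- res$cells
    if (nrow(res$trips)) {
      trip_rows[[length(trip_rows) + 1L]] <-
        mutate(res$trips, child_id = child_id, date = res$day$date[1])
    }
    counters <- if (is.null(counters)) res$counters else
      map2(counters, res$counters, `+`)
  }
  list(days = list_rbind(day_rows),
       cells = if (length(cell_rows)) list_rbind(cell_rows) else NULL,
       trips = if (length(trip_rows)) list_rbind(trip_rows) else NULL,
       anchor_log = mutate(anch$anchor_log, child_id = child_id),
       counters = counters)
}

emit_seed <- function(base_seed, child_idx, day_idx) {
  as.integer(base_seed) + 100000L + child_idx * 1000L + day_idx
}

#' Write a simulated cohort to disk
#'
#' Generates a cohort with [generate_cohort()], emits sensor streams with
#' [emit_sensors()] and writes the documented file layout: per-child
#' ActiGraph-style and Qstarz-style CSVs per day, school and public-space
#' GeoJSON, per-child metadata JSON, per-day ground-truth JSON and a
#' manifest carrying the seed and a config hash. Rerunning with the same
#' arguments reproduces identical files.
#'
#' @param out_dir output directory (created if needed)
#' @param n_children,n_days,seed,config passed to [generate_cohort()]
#' @return the manifest, invisibly
#' @export
cmd_simulate <- function(out_dir, n_children = 20, n_days = 6, seed = 1,
                         config = sim_config()) {
  cohort <- generate_cohort(n_children, n_days, seed, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output dir %s", out_dir))
  write_geojson_polygons(
    polygon_set(cohort$schools$school_id, cohort$schools$polygon,
                feature_id = cohort$schools$school_id),
    file.path(out_dir, "schools.geojson"))
  write_geojson_polygons(cohort$public_spaces,
                         file.path(out_dir, "public_spaces.geojson"))
  files <- character()
  for (i in seq_len(nrow(cohort$profiles))) {
    prof <- cohort$profiles[i, ]
    cdir <- file.path(out_dir, "children", prof$child_id)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    rows <- which(cohort$days$child_id == prof$child_id)
    dates <- cohort$days$date[rows]
    jsonlite::write_json(list(
      child_id = prof$child_id, school_id = prof$school_id,
      postal_centroid = c(prof$postal_lon, prof$postal_lat),
      sleep_home_dates = as.character(dates),
      schedule = as.data.frame(cohort$schedule)),
      file.path(cdir, "meta.json"), auto_unbox = TRUE, digits = NA)
    anchors <- true_anchors(cohort, prof$child_id)
    for (k in seq_along(rows)) {
      truth <- cohort$days$truth[[rows[k]]]
      sens <- emit_sensors(truth, seed = emit_seed(seed, i, k), config = config)
      stamp <- format(dates[k], "%Y%m%d")
      acc <- file.path(cdir, sprintf("acc_%s.csv", stamp))
      gps <- file.path(cdir, sprintf("gps_%s.csv", stamp))
      gt <- file.path(cdir, sprintf("truth_%s.json", stamp))
      write_actigraph_csv(sens$epochs, acc)
      write_qstarz_csv(sens$fixes, gps)
      cells <- ground_truth_summary(truth, anchors, cohort$public_spaces,
                                    cohort$schedule, child_id = prof$child_id,
                                    epoch_len_s = config$epoch_len_s)
      write_ground_truth(cells, truth$trips, gt)
      files <- c(files, acc, gps, gt)
    }
  }
  manifest <- list(seed = as.integer(seed), n_children = n_children,
                   n_days = n_days, config_hash = rlang::hash(unclass(config)),
                   children = cohort$profiles$child_id,
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Process a simulated (or equally structured) dataset directory
#'
#' Reads the layout written by [cmd_simulate()], infers anchors per child,
#' runs every child-day through [process_day()] and writes `days.csv`,
#' `cells.csv`, `trips.csv`, `anchors.csv` and `attrition.json` into
#' `out_dir`. Days whose GPS file is missing or empty are marked invalid;
#' every dropped record is accounted for in the attrition counters.
#'
#' @param input_dir dataset directory
#' @param out_dir output directory
#' @param config a [pipeline_config()]
#' @return list of the output tables, invisibly
#' @export
cmd_process <- function(input_dir, out_dir, config = pipeline_config()) {
  if (!file.exists(file.path(input_dir, "manifest.json"))) {
    abort(sprintf("%s: no manifest.json; not a dataset directory", input_dir))
  }
  schools <- read_geojson_polygons(file.path(input_dir, "schools.geojson"))
  polygons <- read_geojson_polygons(file.path(input_dir, "public_spaces.geojson"))
  child_dirs <- list.dirs(file.path(input_dir, "children"), recursive = FALSE)
  all_days <- list(); all_cells <- list(); all_trips <- list()
  all_anchors <- list(); counters <- NULL
  for (cdir in child_dirs) {
    meta <- jsonlite::fromJSON(file.path(cdir, "meta.json"))
    sp_rings <- schools$rings[[which(schools$label == meta$school_id)[1]]]
    # parcel centroid; drop each ring's closing vertex so corners count once
    verts <- do.call(rbind, lapply(sp_rings, function(r) r[-nrow(r), , drop = FALSE]))
    school_point <- c(mean(verts[, 1]), mean(verts[, 2]))
    schedule <- as_tibble(meta$schedule)
    acc_files <- sort(list.files(cdir, "^acc_.*\\.csv$", full.names = TRUE))
    days <- map(acc_files, function(acc) {
      gps <- sub("acc_", "gps_", acc)
      list(epochs = read_actigraph_csv(acc),
           fixes = if (file.exists(gps)) read_qstarz_csv(gps) else NULL)
    })
    res <- process_child(days, school_point, school_polygon = sp_rings,
                         postal_centroid = as.numeric(meta$postal_centroid),
                         sleep_home_dates = as.Date(meta$sleep_home_dates),
                         polygons = polygons, schedule = schedule,
                         config = config, child_id = meta$child_id)
    all_days[[length(all_days) + 1L]] <- res$days
    if (!is.null(res$cells)) all_cells[[length(all_cells) + 1L]] <- res$cells
    if (!is.null(res$trips)) all_trips[[length(all_trips) + 1L]] <- res$trips
    all_anchors[[length(all_anchors) + 1L]] <- res$anchor_log
    counters <- if (is.null(counters)) res$counters else
      map2(counters, res$counters, `+`)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  days <- list_rbind(all_days)
  cells <- if (length(all_cells)) list_rbind(all_cells) else tibble()
  trips <- if (length(all_trips)) list_rbind(all_trips) else tibble()
  anchors <- list_rbind(all_anchors)
  readr::write_csv(days, file.path(out_dir, "days.csv"), progress = FALSE)
  readr::write_csv(cells, file.path(out_dir, "cells.csv"), progress = FALSE)
  readr::write_csv(trips, file.path(out_dir, "trips.csv"), progress = FALSE)
  readr::write_csv(anchors, file.path(out_dir, "anchors.csv"), progress = FALSE)
  jsonlite::write_json(counters, file.path(out_dir, "attrition.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(days = days, cells = cells, trips = trips, anchors = anchors,
                 counters = counters))
}

#' Aggregate processed day summaries into cohort tables
#'
#' Reads `cells.csv` from a [cmd_process()] output directory, aggregates with
#' [aggregate_cohort()] and writes three cohort tables — spatial contexts,
#' trips and public spaces, temporal bins — plus a data dictionary describing
#' every column.
#'
#' @param proc_dir directory holding `cells.csv`
#' @param out_dir output directory (defaults to `proc_dir`)
#' @return the cohort summary, invisibly
#' @export
cmd_summarize <- function(proc_dir, out_dir = proc_dir) {
  path <- file.path(proc_dir, "cells.csv")
  if (!file.exists(path)) abort(sprintf("%s not found; run cmd_process first", path))
  cells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cohort <- aggregate_cohort(cells)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(dims, file) {
    readr::write_csv(tidy(cohort) |> filter(.data$dimension %in% dims),
                     file.path(out_dir, file), progress = FALSE)
  }
  wr(c("total", "context"), "cohort_context.csv")
  wr(c("trip", "public_space"), "cohort_trips_public.csv")
  wr(c("hour", "schedule"), "cohort_temporal.csv")
  writeLines(c(
    "Cohort summary tables: one row per (day_type, dimension, level).",
    "",
    "day_type      weekday or weekend (Sat/Sun); days are the unit of analysis",
    "dimension     total | context | trip | public_space | hour | schedule",
    "level         dimension level: context category, trip state, polygon label,",
    "              hour of day (epoch start), or school-schedule period",
    "n_days        number of valid days contributing to the cell",
    "weartime_min  mean daily minutes of combined (worn + GPS-matched) weartime",
    "weartime_sd   sample SD over days (0 when a single day contributes)",
    "lpa_min/lpa_sd    mean (SD) daily minutes of light activity in the cell",
    "mvpa_min/mvpa_sd  mean (SD) daily minutes of moderate-to-vigorous activity",
    "lpa_pct/mvpa_pct  mean minutes / mean weartime in the cell, x 100",
    "single_day    TRUE when n_days == 1 (SD reported as 0)"),
    file.path(out_dir, "data_dictionary.txt"))
  invisible(cohort)
}

#' Print the default pipeline configuration as YAML
#' @return the default [pipeline_config()], invisibly
#' @export
cmd_show_config <- function() {
  cat(yaml::as.yaml(unclass(pipeline_config())))
  invisible(pipeline_config())
}
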