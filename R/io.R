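# Readers and writers for the device-style CSV formats, GeoJSON, GPX, the
# YAML pipeline config and ground-truth JSON. All timestamps are naive local
# time (represented as UTC-labelled POSIXct).

fmt_time <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")

parse_time <- function(x) as.POSIXct(x, tz = "UTC")

#' Write an ActiGraph-style epoch CSV
#'
#' Optionally prefixed by a 10-line device header block like the vendor
#' export; data columns are `timestamp`, `axis1` and, when present, the raw
#' signal summary columns used for non-wear detection.
#'
#' @param epochs tibble with `time`, `counts` and optional `raw_*` columns
#' @param path output file
#' @param device_header write the 10-line vendor-style preamble
#' @export
write_actigraph_csv <- function(epochs, path, device_header = TRUE) {
  cols <- c("counts", grep("^raw_", names(epochs), value = TRUE))
  df <- data.frame(timestamp = fmt_time(epochs$time))
  for (col in cols) df[[if (col == "counts") "axis1" else col]] <- epochs[[col]]
  con <- file(path, "w")
  on.exit(close(con))
  if (device_header) {
    writeLines(c(
      "------------ Data File Created By ActiGraph GT3X+ ActiLife v6.13.4 Firmware v3.2.1 date format yyyy-MM-dd ------------",
      paste0("Serial Number: SYN", substr(basename(path), 1, 8)),
      paste0("Start Time ", format(epochs$time[1], "%H:%M:%S")),
      paste0("Start Date ", format(epochs$time[1], "%Y-%m-%d")),
      "Epoch Period (hh:mm:ss) 00:00:10",
      "Download Time 00:00:00",
      paste0("Download Date ", format(epochs$time[nrow(epochs)], "%Y-%m-%d")),
      "Current Memory Address: 0",
      "Current Battery Voltage: 4.1     Mode = 13",
      "--------------------------------------------------"), con)
  }
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  invisible(path)
}

#' Read an ActiGraph-style epoch CSV
#'
#' Tolerates a vendor header block of arbitrary length by sniffing for the
#' line that starts with `timestamp`.
#'
#' @param path input file
#' @return tibble with `time`, `counts` and any raw summary columns
#' @export
read_actigraph_csv <- function(path) {
  lines <- readLines(path, n = 50)
  skip <- grep("^timestamp", lines)[1]
  if (is.na(skip)) abort(sprintf("%s: no 'timestamp' header line found", path))
  df <- readr::read_csv(path, skip = skip - 1, show_col_types = FALSE,
                        progress = FALSE)
  out <- tibble(time = parse_time(df$timestamp), counts = df$axis1)
  for (col in grep("^raw_", names(df), value = TRUE)) out[[col]] <- df[[col]]
  out
}

#' Write a Qstarz-style GPS log CSV
#'
#' Columns `INDEX, UTC DATE, UTC TIME, LATITUDE, LONGITUDE, HEIGHT, SPEED`
#' (speed in km/h). Despite the column names, timestamps are written as the
#' local clock time the pipeline operates on.
#'
#' @param fixes tibble with `time`, `lat`, `lon`, `ele`, `speed_kmph`
#' @param path output file
#' @export
write_qstarz_csv <- function(fixes, path) {
  df <- data.frame(
    INDEX = seq_len(nrow(fixes)),
    `UTC DATE` = format(fixes$time, "%Y/%m/%d", tz = "UTC"),
    `UTC TIME` = format(fixes$time, "%H:%M:%S", tz = "UTC"),
    LATITUDE = sprintf("%.8f", fixes$lat),
    LONGITUDE = sprintf("%.8f", fixes$lon),
    HEIGHT = if ("ele" %in% names(fixes)) fixes$ele else 0,
    SPEED = ifelse(is.na(fixes$speed_kmph), "", sprintf("%.4f", fixes$speed_kmph)),
    check.names = FALSE)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a Qstarz-style GPS log CSV
#' @param path input file
#' @return tibble with `time`, `lat`, `lon`, `ele`, `speed_kmph`, `valid`
#' @export
read_qstarz_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    return(tibble(time = as.POSIXct(character(), tz = "UTC"), lat = numeric(),
                  lon = numeric(), ele = numeric(), speed_kmph = numeric(),
                  valid = logical()))
  }
  tibble(
    time = parse_time(paste(gsub("/", "-", df$`UTC DATE`), df$`UTC TIME`)),
    lat = as.numeric(df$LATITUDE), lon = as.numeric(df$LONGITUDE),
    ele = as.numeric(df$HEIGHT),
    speed_kmph = suppressWarnings(as.numeric(df$SPEED)),
    valid = TRUE)
}

#' Read track points from a GPX file
#' @param path input file
#' @return tibble with `time`, `lat`, `lon`, `ele`, `speed_kmph` (NA unless
#'   the file carries a speed extension), `valid`
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, "//trkpt")
  get1 <- function(p, xp) {
    v <- as.character(xml2::xml_text(xml2::xml_find_first(p, xp)))
    if (length(v) == 0 || is.na(v) || v == "") NA_character_ else v
  }
  tm <- vapply(pts, get1, character(1), xp = "./time")
  tibble(
    time = parse_time(gsub("[TZ]", " ", tm)),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    ele = as.numeric(vapply(pts, get1, character(1), xp = "./ele")),
    speed_kmph = as.numeric(vapply(pts, get1, character(1), xp = ".//speed")),
    valid = TRUE)
}

ring_to_coords <- function(ring) {
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write a polygon set as GeoJSON
#' @param polygons a [polygon_set()]
#' @param path output file
#' @export
write_geojson_polygons <- function(polygons, path) {
  feats <- lapply(seq_len(nrow(polygons)), function(i) {
    list(type = "Feature",
         properties = list(label = polygons$label[i], id = polygons$feature_id[i]),
         geometry = list(type = "Polygon",
                         coordinates = lapply(polygons$rings[[i]], ring_to_coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read labelled polygons from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; the label is taken from the
#' `label` property. Geometry is validated (closed, simple rings); an invalid
#' feature is rejected with its id.
#'
#' @param path input file
#' @return a [polygon_set()]
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  labels <- character(); ids <- character(); rings <- list()
  to_ring <- function(coords) {
    do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  }
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    lab <- f$properties$label %||% "polygon"
    id <- as.character(f$properties$id %||% i)
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      abort(sprintf("feature '%s': unsupported geometry type %s", id, geom$type)))
    for (p in polys) {
      labels <- c(labels, lab); ids <- c(ids, id)
      rings <- c(rings, list(lapply(p, to_ring)))
    }
  }
  polygon_set(labels, rings, feature_id = ids, validate = TRUE)
}

#' Write / read per-day ground truth as JSON
#'
#' Stores the expected day-summary cells, the expected trips and the
#' simulated weartime for one child-day, for use as a recovery oracle by
#' downstream consumers of a simulated dataset.
#'
#' @param cells expected day cells (see [ground_truth_summary()])
#' @param trips expected trips tibble
#' @param path file path
#' @export
write_ground_truth <- function(cells, trips, path) {
  payload <- list(
    child_id = cells$child_id[1],
    date = as.character(cells$date[1]),
    weartime_min = cells$weartime_min[cells$dimension == "total"][1],
    cells = as.data.frame(cells |> mutate(date = as.character(date))),
    trips = as.data.frame(trips |> mutate(start_time = fmt_time(start_time),
                                          end_time = fmt_time(end_time))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @return `read_ground_truth()`: list with `cells` and `trips` tibbles
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  cells <- as_tibble(x$cells) |>
    mutate(date = as.Date(date),
           day_type = factor(day_type, levels = c("weekday", "weekend")))
  trips <- as_tibble(x$trips)
  if (nrow(trips)) {
    trips <- trips |> mutate(start_time = parse_time(start_time),
                             end_time = parse_time(end_time))
  }
  list(child_id = x$child_id, date = as.Date(x$date),
       weartime_min = x$weartime_min, cells = cells, trips = trips)
}

#' Save / load a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, f))` equals
#' `cfg`, and loading re-runs the same validation as [pipeline_config()].
#'
#' @param config a [pipeline_config()]
#' @param path file path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bands <- as.numeric(unlist(x$bands))
  x$anchor_window <- as.character(unlist(x$anchor_window))
  do.call(pipeline_config, x)
}
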