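#' Integrated home-school context categories
#'
#' The mutually exclusive categories built from banded distances
#' (10/100/400/800 m) to the home and school anchors, plus `unclassified`
#' for band combinations that do not correspond to a listed category (for
#' example either distance falling in 400-800 m without the other side
#' claiming the fix).
#'
#' @return character vector of category labels
#' @export
context_levels <- function() {
  c("at_home", "close_to_home", "home_nb_outside_school_nb",
    "at_school", "close_to_school", "school_nb_outside_home_nb",
    "overlap_home_school_nb", "outside_both", "unclassified")
}

#' Per-child reference geometry
#'
#' Holds the home anchor per day type (weekday/weekend morning centroids can
#' differ), the school point and parcel polygon, and the parent-reported
#' postal-code centroid used for validation and fallback.
#'
#' @param home_weekday,home_weekend,school_point,postal_centroid length-2
#'   numeric `c(lon, lat)`; `home_weekend` defaults to the weekday anchor and
#'   `postal_centroid` may be NULL
#' @param school_polygon optional list of closed two-column lon/lat ring
#'   matrices for the school parcel
#' @return an object of class `anchor_set`
#' @export
anchor_set <- function(home_weekday, home_weekend = home_weekday,
                       school_point, school_polygon = NULL,
                       postal_centroid = NULL) {
  chk <- function(p, what) {
    if (!is.numeric(p) || length(p) != 2 || abs(p[2]) > 90 || abs(p[1]) > 180) {
      abort(sprintf("%s must be c(lon, lat) with valid WGS84 coordinates", what))
    }
  }
  chk(home_weekday, "home_weekday"); chk(home_weekend, "home_weekend")
  chk(school_point, "school_point")
  if (!is.null(postal_centroid)) chk(postal_centroid, "postal_centroid")
  if (!is.null(school_polygon)) {
    stopifnot(is.list(school_polygon))
    for (ring in school_polygon) {
      stopifnot(is.matrix(ring), ncol(ring) == 2)
    }
  }
  structure(list(home_weekday = home_weekday, home_weekend = home_weekend,
                 school_point = school_point, school_polygon = school_polygon,
                 postal_centroid = postal_centroid),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("<anchor_set>\n")
  cat(sprintf("  home (weekday): %.6f, %.6f\n", x$home_weekday[1], x$home_weekday[2]))
  cat(sprintf("  home (weekend): %.6f, %.6f\n", x$home_weekend[1], x$home_weekend[2]))
  cat(sprintf("  school:         %.6f, %.6f (%s parcel polygon)\n",
              x$school_point[1], x$school_point[2],
              if (is.null(x$school_polygon)) "no" else "with"))
  if (!is.null(x$postal_centroid)) {
    cat(sprintf("  postal:         %.6f, %.6f\n", x$postal_centroid[1], x$postal_centroid[2]))
  }
  invisible(x)
}

#' Infer the home anchor from early-morning GPS
#'
#' The home point is the centroid (arithmetic mean in a local metric
#' projection) of all fixes recorded in the morning window (default
#' 06:00-08:00) on days of the requested day type when the child slept at
#' home.
#'
#' @param fixes tibble with `time`, `lat`, `lon` spanning the child's days
#' @param sleep_home_dates `Date` vector of nights slept at home; NULL means
#'   all dates qualify
#' @param day_type `"weekday"` or `"weekend"`
#' @param window character `c(from, to)` clock times, half-open
#' @return one-row tibble with `day_type`, `lon`, `lat`, `n_fixes`
#' @export
infer_home_anchor <- function(fixes, sleep_home_dates = NULL,
                              day_type = c("weekday", "weekend"),
                              window = c("06:00", "08:00")) {
  day_type <- match.arg(day_type)
  s <- secs_of_day(fixes$time)
  w <- hm_to_secs(window)
  d <- date_of(fixes$time)
  keep <- s >= w[1] & s < w[2] & day_type_of(d) == day_type
  if (!is.null(sleep_home_dates)) keep <- keep & d %in% as.Date(sleep_home_dates)
  if (!any(keep)) {
    abort(sprintf(
      "no %s fixes in the %s-%s window on qualifying days; fall back to the postal-code centroid",
      day_type, window[1], window[2]))
  }
  lon <- fixes$lon[keep]; lat <- fixes$lat[keep]
  center <- c(mean(lon), mean(lat))
  xy <- project_aeqd(lon, lat, center)
  pt <- unproject_aeqd(mean(xy[, 1]), mean(xy[, 2]), center)
  tibble(day_type = day_type, lon = unname(pt[1, 1]), lat = unname(pt[1, 2]),
         n_fixes = sum(keep))
}

#' Distance between an inferred home anchor and the postal-code centroid
#'
#' @param anchor length-2 `c(lon, lat)` or a one-row tibble from
#'   [infer_home_anchor()]
#' @param postal_centroid length-2 `c(lon, lat)`
#' @return great-circle distance in metres
#' @export
validate_home <- function(anchor, postal_centroid) {
  if (is.data.frame(anchor)) anchor <- c(anchor$lon[1], anchor$lat[1])
  haversine_m(anchor[1], anchor[2], postal_centroid[1], postal_centroid[2])
}

#' Distance provider for neighbourhood bands
#'
#' The sub-10 m bands always use straight-line (great-circle) distance; the
#' wider bands use this provider. `euclidean` is straight-line, `detour`
#' multiplies the straight line by a constant detour factor emulating street
#' networks, and `network` delegates to a user-supplied function
#' `f(lon, lat, point)` returning metres (for a road-graph backend).
#'
#' @param mode one of `"euclidean"`, `"detour"`, `"network"`
#' @param detour_factor multiplier at least 1 for `detour` mode
#' @param network_fun function for `network` mode
#' @return an object of class `dist_provider`
#' @export
dist_provider <- function(mode = c("euclidean", "detour", "network"),
                          detour_factor = 1, network_fun = NULL) {
  mode <- match.arg(mode)
  if (detour_factor < 1) abort("detour_factor must be >= 1")
  if (mode == "network" && !is.function(network_fun)) {
    abort("network mode requires a network_fun(lon, lat, point)")
  }
  structure(list(mode = mode, detour_factor = detour_factor,
                 network_fun = network_fun),
            class = "dist_provider")
}

#' Evaluate a distance provider
#' @param provider a [dist_provider()]
#' @param lon,lat coordinate vectors
#' @param point length-2 `c(lon, lat)` target
#' @return distances in metres
#' @export
provider_distance <- function(provider, lon, lat, point) {
  switch(provider$mode,
    euclidean = haversine_m(lon, lat, point[1], point[2]),
    detour = haversine_m(lon, lat, point[1], point[2]) * provider$detour_factor,
    network = provider$network_fun(lon, lat, point))
}

# Decision table over distance bands. Band index: 0 = <10 m, 1 = 10-100,
# 2 = 100-400, 3 = 400-800, 4 = >800. Band 0 and the home/school precedence
# use the band-relevant distance: when both sides fall in an anchor-adjacent
# band (<10 or 10-100 m), the smaller distance wins and a tie goes to the
# home side.
category_from_bands <- function(bh, bs, dh, ds) {
  n <- length(bh)
  out <- rep("unclassified", n)
  near_h <- bh <= 1L
  near_s <- bs <= 1L
  both <- near_h & near_s
  home_wins <- both & (dh <= ds)
  school_wins <- both & (dh > ds)
  only_h <- near_h & !near_s
  only_s <- near_s & !near_h
  out[(home_wins | only_h) & bh == 0L] <- "at_home"
  out[(home_wins | only_h) & bh == 1L] <- "close_to_home"
  out[(school_wins | only_s) & bs == 0L] <- "at_school"
  out[(school_wins | only_s) & bs == 1L] <- "close_to_school"
  far <- !near_h & !near_s
  out[far & bh == 2L & bs == 4L] <- "home_nb_outside_school_nb"
  out[far & bs == 2L & bh == 4L] <- "school_nb_outside_home_nb"
  out[far & bh == 2L & bs == 2L] <- "overlap_home_school_nb"
  out[far & bh == 4L & bs == 4L] <- "outside_both"
  out
}

band_of <- function(d_eu, d_prov, bands = c(10, 100, 400, 800)) {
  ifelse(d_eu < bands[1], 0L,
    ifelse(d_prov < bands[2], 1L,
      ifelse(d_prov < bands[3], 2L,
        ifelse(d_prov < bands[4], 3L, 4L))))
}

#' Context category from home and school distances
#'
#' The decision table behind [assign_category()], exposed directly on
#' distances: the sub-10 m band is judged on the straight-line distance, the
#' wider bands on the (possibly network) distance, the smaller distance wins
#' when both anchors claim the fix (ties to the home side), and unlisted band
#' combinations are `unclassified`.
#'
#' @param d_home_m,d_school_m straight-line distances in metres
#' @param d_home_net_m,d_school_net_m provider distances for the wider bands
#'   (default: same as straight-line)
#' @param bands distance band edges in metres
#' @return factor over [context_levels()]
#' @export
#' @examples
#' category_from_distances(250, 900)  # home neighbourhood, outside school's
category_from_distances <- function(d_home_m, d_school_m,
                                    d_home_net_m = d_home_m,
                                    d_school_net_m = d_school_m,
                                    bands = c(10, 100, 400, 800)) {
  bh <- band_of(d_home_m, d_home_net_m, bands)
  bs <- band_of(d_school_m, d_school_net_m, bands)
  dh_cmp <- ifelse(bh == 0L, d_home_m, d_home_net_m)
  ds_cmp <- ifelse(bs == 0L, d_school_m, d_school_net_m)
  factor(category_from_bands(bh, bs, dh_cmp, ds_cmp), levels = context_levels())
}

#' Assign each fix to an integrated home-school context category
#'
#' The at-home/at-school bands (<10 m) use straight-line distance; a fix
#' inside the school parcel polygon counts as at school regardless of the
#' distance to the school point. The wider bands (10-100, 100-400, >800 m)
#' use the distance provider. When both anchors place the fix in a listed
#' band, the smaller distance wins and ties go to the home side. Band
#' combinations without a listed category (including 400-800 m from both
#' anchors) are `unclassified`.
#'
#' @param fixes tibble with `lat`, `lon` (plus any other columns, preserved)
#' @param anchors an [anchor_set()]
#' @param provider a [dist_provider()] for the non-Euclidean bands
#' @param day_type which home anchor to use
#' @param bands distance band edges in metres
#' @return `fixes` with `d_home_m`, `d_school_m` (straight-line),
#'   `category` (factor over [context_levels()])
#' @export
assign_category <- function(fixes, anchors, provider = dist_provider(),
                            day_type = c("weekday", "weekend"),
                            bands = c(10, 100, 400, 800)) {
  day_type <- match.arg(day_type)
  if (!inherits(anchors, "anchor_set")) abort("anchors must be an anchor_set")
  home <- if (day_type == "weekday") anchors$home_weekday else anchors$home_weekend
  school <- anchors$school_point
  dh_eu <- haversine_m(fixes$lon, fixes$lat, home[1], home[2])
  ds_eu <- haversine_m(fixes$lon, fixes$lat, school[1], school[2])
  if (!is.null(anchors$school_polygon)) {
    xy <- project_aeqd(fixes$lon, fixes$lat, school)
    rings <- lapply(anchors$school_polygon, function(r) project_aeqd(r[, 1], r[, 2], school))
    inside <- point_in_rings(xy[, 1], xy[, 2], rings)
    ds_eu[inside] <- 0
  }
  dh_prov <- provider_distance(provider, fixes$lon, fixes$lat, home)
  ds_prov <- provider_distance(provider, fixes$lon, fixes$lat, school)
  ds_prov[ds_eu == 0] <- 0
  fixes$d_home_m <- dh_eu
  fixes$d_school_m <- ds_eu
  fixes$category <- category_from_distances(dh_eu, ds_eu, dh_prov, ds_prov, bands)
  fixes
}

#' Label fixes that fall within a buffer of public-space polygons
#'
#' A fix receives a label when it lies inside one of that label's polygons or
#' within `buffer_m` of a polygon boundary. Labels are non-exclusive (a fix
#' in overlapping park and playground buffers gets both) and independent of
#' the context category.
#'
#' @param fixes tibble with `lat`, `lon`
#' @param polygons a [polygon_set()] (labels such as park, sports_terrain,
#'   playground)
#' @param buffer_m buffer distance in metres
#' @return `fixes` with one logical `ps_<label>` column per label
#' @export
assign_public_space <- function(fixes, polygons, buffer_m = 10) {
  stopifnot(inherits(polygons, "polygon_set"))
  all_pts <- do.call(rbind, unlist(polygons$rings, recursive = FALSE))
  center <- c(mean(all_pts[, 1]), mean(all_pts[, 2]))
  xy <- project_aeqd(fixes$lon, fixes$lat, center)
  for (lab in unique(polygons$label)) {
    hit <- rep(FALSE, nrow(fixes))
    feats <- polygons$rings[polygons$label == lab]
    for (rings_ll in feats) {
      rings <- lapply(rings_ll, function(r) project_aeqd(r[, 1], r[, 2], center))
      inside <- point_in_rings(xy[, 1], xy[, 2], rings)
      near <- dist_to_rings(xy[, 1], xy[, 2], rings) <= buffer_m
      hit <- hit | inside | near
    }
    fixes[[paste0("ps_", lab)]] <- hit
  }
  fixes
}

#' Labelled polygon collection
#'
#' @param label character vector, one entry per feature (e.g. `"park"`)
#' @param feature_id identifiers, defaults to running numbers
#' @param rings list (one element per feature) of lists of closed two-column
#'   lon/lat ring matrices
#' @param validate check ring closure and simplicity (non-self-intersection);
#'   offending features are reported by id
#' @return tibble of class `polygon_set`
#' @export
polygon_set <- function(label, rings, feature_id = as.character(seq_along(label)),
                        validate = TRUE) {
  stopifnot(length(label) == length(rings))
  if (validate) {
    for (i in seq_along(rings)) {
      for (ring in rings[[i]]) {
        if (nrow(ring) < 4 || any(ring[1, ] != ring[nrow(ring), ])) {
          abort(sprintf("feature '%s': ring is not closed or has fewer than 3 vertices",
                        feature_id[i]))
        }
        pr <- project_aeqd(ring[, 1], ring[, 2], c(mean(ring[, 1]), mean(ring[, 2])))
        if (!ring_is_simple(pr)) {
          abort(sprintf("feature '%s': self-intersecting ring", feature_id[i]))
        }
      }
    }
  }
  out <- tibble(label = label, feature_id = feature_id, rings = rings)
  class(out) <- c("polygon_set", class(out))
  out
}

#' Axis-aligned rectangular polygon around a centre point
#'
#' Convenience constructor used by the synthetic generator for parcels.
#'
#' @param center length-2 `c(lon, lat)`
#' @param width_m,height_m extents in metres
#' @return a single closed lon/lat ring matrix
#' @export
rect_polygon <- function(center, width_m, height_m = width_m) {
  hw <- width_m / 2; hh <- height_m / 2
  xy <- rbind(c(-hw, -hh), c(hw, -hh), c(hw, hh), c(-hw, hh), c(-hw, -hh))
  unproject_aeqd(xy[, 1], xy[, 2], center)
}
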