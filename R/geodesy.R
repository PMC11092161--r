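# Spherical geodesy primitives. Distances use the haversine formula on a
# mean-radius sphere; the local planar frame is an azimuthal equidistant
# projection centred on a reference point (metre-true radially, and accurate
# to centimetres at the city scale this package operates on). The projection
# and its inverse are exact mutual inverses, which the synthetic generator
# relies on for zero-noise identifiability.

EARTH_RADIUS_M <- 6371008.8

#' Great-circle (haversine) distance in metres
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees WGS84; vectors recycle
#' @return numeric metres
#' @export
#' @examples
#' haversine_m(5.47, 51.44, 5.48, 51.44)
haversine_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = EARTH_RADIUS_M)
}

#' Project lon/lat to a local azimuthal equidistant frame
#'
#' @param lon,lat coordinates in degrees
#' @param center length-2 numeric `c(lon, lat)` of the projection centre
#' @return two-column matrix of x (east) and y (north) metres
#' @export
project_aeqd <- function(lon, lat, center) {
  rad <- pi / 180
  phi1 <- center[2] * rad
  lam1 <- center[1] * rad
  phi2 <- lat * rad
  dlam <- lon * rad - lam1
  a <- sin((phi2 - phi1) / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  c_ang <- 2 * asin(pmin(1, sqrt(a)))
  theta <- atan2(sin(dlam) * cos(phi2),
                 cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam))
  d <- EARTH_RADIUS_M * c_ang
  cbind(x = d * sin(theta), y = d * cos(theta))
}

#' Inverse of [project_aeqd()]
#'
#' @param x,y local coordinates in metres
#' @param center length-2 numeric `c(lon, lat)` of the projection centre
#' @return two-column matrix of lon and lat degrees
#' @export
unproject_aeqd <- function(x, y, center) {
  rad <- pi / 180
  phi1 <- center[2] * rad
  lam1 <- center[1] * rad
  d <- sqrt(x^2 + y^2) / EARTH_RADIUS_M
  theta <- atan2(x, y)
  phi2 <- asin(pmin(1, pmax(-1, sin(phi1) * cos(d) + cos(phi1) * sin(d) * cos(theta))))
  lam2 <- lam1 + atan2(sin(theta) * sin(d) * cos(phi1), cos(d) - sin(phi1) * sin(phi2))
  out <- cbind(lon = lam2 / rad, lat = phi2 / rad)
  zero <- d == 0
  if (any(zero)) {
    out[zero, 1] <- center[1]
    out[zero, 2] <- center[2]
  }
  out
}

#' Destination point along an initial bearing
#'
#' @param lon,lat start coordinates in degrees
#' @param bearing_deg initial bearing, degrees clockwise from north
#' @param dist_m great-circle distance in metres
#' @return two-column matrix of lon and lat degrees
#' @export
dest_point <- function(lon, lat, bearing_deg, dist_m) {
  rad <- pi / 180
  unproject_aeqd(dist_m * sin(bearing_deg * rad),
                 dist_m * cos(bearing_deg * rad),
                 c(lon[1], lat[1]))
}

#' Equally spaced points along the great circle between two points
#'
#' Returns `n` points at arc fractions `1/n, 2/n, ..., 1` (the end point is
#' included, the start point is not), matching a traveller who departs at the
#' start and is sampled once per epoch.
#' @keywords internal
gc_path_points <- function(from, to, n) {
  if (n < 1) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lon", "lat"))))
  xy <- project_aeqd(to[1], to[2], from)
  f <- seq_len(n) / n
  unproject_aeqd(f * xy[1, 1], f * xy[1, 2], from)
}

# --- planar polygon primitives (local frame) --------------------------------

#' Even-odd point-in-rings test in a planar frame
#'
#' @param px,py point coordinates
#' @param rings list of closed two-column matrices (first row == last row)
#' @return logical vector, one per point
#' @keywords internal
point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    nv <- nrow(ring) - 1L
    for (j in seq_len(nv)) {
      x1 <- ring[j, 1]; y1 <- ring[j, 2]
      x2 <- ring[j + 1, 1]; y2 <- ring[j + 1, 2]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Minimum distance from points to ring boundaries in a planar frame
#' @keywords internal
dist_to_rings <- function(px, py, rings) {
  dmin <- rep(Inf, length(px))
  for (ring in rings) {
    nv <- nrow(ring) - 1L
    for (j in seq_len(nv)) {
      x1 <- ring[j, 1]; y1 <- ring[j, 2]
      x2 <- ring[j + 1, 1]; y2 <- ring[j + 1, 2]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx^2 + dy^2
      t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
      dmin <- pmin(dmin, d)
    }
  }
  dmin
}

# Proper-intersection test between non-adjacent edges; used to reject
# self-intersecting rings at polygon load time.
ring_is_simple <- function(ring) {
  nv <- nrow(ring) - 1L
  if (nv < 3) return(FALSE)
  seg <- function(j) ring[c(j, j + 1L), , drop = FALSE]
  orient <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  for (i in seq_len(nv - 2L)) {
    jmax <- if (i == 1L) nv - 1L else nv
    for (j in (i + 2L):jmax) {
      a <- seg(i); b <- seg(j)
      if (orient(a[1, ], a[2, ], b[1, ]) * orient(a[1, ], a[2, ], b[2, ]) < 0 &&
          orient(b[1, ], b[2, ], a[1, ]) * orient(b[1, ], b[2, ], a[2, ]) < 0) {
        return(FALSE)
      }
    }
  }
  TRUE
}
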