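# Great-circle geometry on a spherical Earth, and a local equal-area
# projection used for kernel density estimation. All distances in km,
# coordinates in decimal degrees (WGS84 lon/lat).

#' Mean Earth radius (km) used for all great-circle calculations
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Great-circle (haversine) distance
#'
#' Distance in km between points on a sphere of radius 6371.0088 km.
#' Vectorised over all arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Numeric vector of distances (km).
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- p2 - p1
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' Bearing in radians (clockwise from north, in (-pi, pi]) from point 1
#' towards point 2 along the great circle.
#'
#' @inheritParams haversine_km
#' @return Numeric vector of bearings (radians).
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  atan2(sin(dlam) * cos(p2),
        cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam))
}

#' Destination point along a great circle
#'
#' @param lon,lat Start coordinates (degrees).
#' @param bearing_rad Initial bearing, radians clockwise from north.
#' @param dist_km Distance to travel (km).
#' @return Matrix with columns `lon`, `lat`.
#' @export
gc_destination <- function(lon, lat, bearing_rad, dist_km) {
  d <- dist_km / EARTH_RADIUS_KM
  p1 <- .deg2rad(lat); l1 <- .deg2rad(lon)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(bearing_rad))
  l2 <- l1 + atan2(sin(bearing_rad) * sin(d) * cos(p1),
                   cos(d) - sin(p1) * sin(p2))
  l2 <- ((l2 + pi) %% (2 * pi)) - pi
  cbind(lon = .rad2deg(l2), lat = .rad2deg(p2))
}

#' Interpolate points along a great-circle segment
#'
#' Spherical linear interpolation between two points at given fractions.
#'
#' @inheritParams haversine_km
#' @param frac Fractions in `[0, 1]` along the segment.
#' @return Matrix with columns `lon`, `lat`, one row per fraction.
#' @export
gc_interpolate <- function(lon1, lat1, lon2, lat2, frac) {
  v1 <- .lonlat_to_xyz(lon1, lat1)
  v2 <- .lonlat_to_xyz(lon2, lat2)
  omega <- acos(max(-1, min(1, sum(v1 * v2))))
  if (omega < 1e-12) {
    return(cbind(lon = rep(lon1, length(frac)), lat = rep(lat1, length(frac))))
  }
  a <- sin((1 - frac) * omega) / sin(omega)
  b <- sin(frac * omega) / sin(omega)
  xyz <- outer(a, v1) + outer(b, v2)
  .xyz_to_lonlat(xyz)
}

.lonlat_to_xyz <- function(lon, lat) {
  p <- .deg2rad(lat); l <- .deg2rad(lon)
  c(cos(p) * cos(l), cos(p) * sin(l), sin(p))
}

.xyz_to_lonlat <- function(xyz) {
  xyz <- xyz / sqrt(rowSums(xyz^2))
  cbind(lon = .rad2deg(atan2(xyz[, 2], xyz[, 1])),
        lat = .rad2deg(asin(pmin(1, pmax(-1, xyz[, 3])))))
}

#' Wrap angles to (-pi, pi]
#' @param x Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  y[y <= -pi] <- pi
  y
}

# ---- Local Lambert azimuthal equal-area projection (spherical form) -------

#' Project lon/lat to a local equal-area plane
#'
#' Lambert azimuthal equal-area projection (spherical form) centred at
#' `(lon0, lat0)`; output coordinates are km east/north of the centre.
#' Areas are preserved, which is what the kernel utilization distribution
#' needs; shape distortion is negligible at the sub-continental scales of a
#' single flyway.
#'
#' @param lon,lat Coordinates in degrees.
#' @param lon0,lat0 Projection centre in degrees.
#' @return Matrix with columns `x`, `y` (km).
#' @export
project_laea <- function(lon, lat, lon0, lat0) {
  p <- .deg2rad(lat); p0 <- .deg2rad(lat0)
  dl <- .deg2rad(lon - lon0)
  denom <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(dl)
  k <- sqrt(2 / pmax(denom, 1e-12))
  cbind(x = EARTH_RADIUS_KM * k * cos(p) * sin(dl),
        y = EARTH_RADIUS_KM * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(dl)))
}

#' Inverse of [project_laea()]
#'
#' @param x,y Projected coordinates (km).
#' @inheritParams project_laea
#' @return Matrix with columns `lon`, `lat` (degrees).
#' @export
unproject_laea <- function(x, y, lon0, lat0) {
  p0 <- .deg2rad(lat0); l0 <- .deg2rad(lon0)
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * EARTH_RADIUS_KM)))
  lat <- ifelse(rho < 1e-12, lat0,
                .rad2deg(asin(cos(cc) * sin(p0) + y * sin(cc) * cos(p0) / rho)))
  lon <- ifelse(rho < 1e-12, lon0,
                .rad2deg(l0 + atan2(x * sin(cc),
                                    rho * cos(p0) * cos(cc) - y * sin(p0) * sin(cc))))
  cbind(lon = lon, lat = lat)
}

# ---- Polyline (corridor) helpers -------------------------------------------

#' Corridor geometry queries
#'
#' A corridor is a polyline of waypoints (matrix or data.frame with columns
#' `lon`, `lat`) defining a flyway axis. `corridor_distance_km` returns the
#' distance from each query point to the polyline; `corridor_nearest` also
#' returns the arc-length position of the nearest point on the axis and the
#' local axis bearing there.
#'
#' @param lon,lat Query coordinates (degrees).
#' @param corridor Two-column matrix/data.frame of waypoints (`lon`, `lat`).
#' @return `corridor_distance_km`: numeric vector (km). `corridor_nearest`:
#'   data.frame with `dist_km`, `along_km` (arc position of nearest axis
#'   point) and `bearing_rad` (local axis bearing).
#' @export
corridor_nearest <- function(lon, lat, corridor) {
  corridor <- as.matrix(corridor)
  stopifnot(ncol(corridor) >= 2, nrow(corridor) >= 2)
  lon0 <- mean(corridor[, 1]); lat0 <- mean(corridor[, 2])
  W <- project_laea(corridor[, 1], corridor[, 2], lon0, lat0)
  P <- project_laea(lon, lat, lon0, lat0)
  seg_len <- sqrt(diff(W[, 1])^2 + diff(W[, 2])^2)
  cum0 <- c(0, cumsum(seg_len))
  n <- nrow(P)
  best_d2 <- rep(Inf, n); best_along <- numeric(n); best_seg <- integer(n)
  for (s in seq_len(nrow(W) - 1)) {
    ax <- W[s, 1]; ay <- W[s, 2]
    dx <- W[s + 1, 1] - ax; dy <- W[s + 1, 2] - ay
    L2 <- dx^2 + dy^2
    t <- pmin(1, pmax(0, ((P[, 1] - ax) * dx + (P[, 2] - ay) * dy) / L2))
    d2 <- (P[, 1] - (ax + t * dx))^2 + (P[, 2] - (ay + t * dy))^2
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_along[hit] <- cum0[s] + t[hit] * seg_len[s]
    best_seg[hit] <- s
  }
  bearing <- gc_bearing(corridor[best_seg, 1], corridor[best_seg, 2],
                        corridor[best_seg + 1, 1], corridor[best_seg + 1, 2])
  data.frame(dist_km = sqrt(best_d2), along_km = best_along,
             bearing_rad = bearing)
}

#' @rdname corridor_nearest
#' @export
corridor_distance_km <- function(lon, lat, corridor) {
  corridor_nearest(lon, lat, corridor)$dist_km
}

#' Total corridor length (km)
#' @param corridor Waypoint matrix (`lon`, `lat`).
#' @return Length in km along great-circle segments.
#' @export
corridor_length_km <- function(corridor) {
  corridor <- as.matrix(corridor)
  sum(haversine_km(corridor[-nrow(corridor), 1], corridor[-nrow(corridor), 2],
                   corridor[-1, 1], corridor[-1, 2]))
}

#' Point on the corridor axis at a given arc position
#' @param corridor Waypoint matrix (`lon`, `lat`).
#' @param along_km Arc-length positions (km) from the first waypoint.
#' @return Matrix with columns `lon`, `lat`.
#' @export
corridor_point_at <- function(corridor, along_km) {
  corridor <- as.matrix(corridor)
  seg_len <- haversine_km(corridor[-nrow(corridor), 1], corridor[-nrow(corridor), 2],
                          corridor[-1, 1], corridor[-1, 2])
  cum0 <- c(0, cumsum(seg_len))
  total <- cum0[length(cum0)]
  along_km <- pmin(pmax(along_km, 0), total)
  out <- matrix(NA_real_, length(along_km), 2, dimnames = list(NULL, c("lon", "lat")))
  for (i in seq_along(along_km)) {
    s <- max(1, min(length(seg_len), findInterval(along_km[i], cum0, rightmost.closed = TRUE)))
    f <- if (seg_len[s] > 0) (along_km[i] - cum0[s]) / seg_len[s] else 0
    out[i, ] <- gc_interpolate(corridor[s, 1], corridor[s, 2],
                               corridor[s + 1, 1], corridor[s + 1, 2], f)
  }
  out
}
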