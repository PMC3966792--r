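# Spherical geometry on the WGS84 mean-radius sphere. All angles in degrees
# at the interface, radians internally. Distances in km.

#' Mean Earth radius (km) used throughout
#'
#' WGS84 mean radius, 6371.0088 km. At study scale (< 500 km) the error
#' relative to ellipsoidal distances is far below the 0.1 km reporting
#' precision of trip metrics.
#' @export
EARTH_RADIUS_KM <- 6371.0088

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle distance (haversine)
#'
#' Vectorized haversine distance on a sphere of radius
#' [EARTH_RADIUS_KM]. Antimeridian-safe: longitudes enter only through
#' their difference inside trigonometric terms.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees; vectors are
#'   recycled to a common length.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dp <- p2 - p1
  dl <- deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial bearing from point 1 to point 2
#'
#' @inheritParams haversine_km
#' @return bearing in degrees clockwise from north, in [0, 360).
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dl <- deg2rad(lon2 - lon1)
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (rad2deg(th) + 360) %% 360
}

#' Destination point given start, bearing and distance
#'
#' @param lat,lon start in degrees.
#' @param bearing degrees clockwise from north.
#' @param dist_km great-circle distance in km.
#' @return list with `lat` and `lon` (degrees, lon in [-180, 180)).
#' @export
destination_point <- function(lat, lon, bearing, dist_km) {
  p1 <- deg2rad(lat); l1 <- deg2rad(lon)
  th <- deg2rad(bearing)
  d <- dist_km / EARTH_RADIUS_KM
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1),
                   cos(d) - sin(p1) * sin(p2))
  list(lat = rad2deg(p2), lon = normalize_lon(rad2deg(l2)))
}

#' Normalize longitudes to [-180, 180)
#' @param lon degrees, any convention.
#' @export
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Azimuthal-equidistant projection around a center
#'
#' Projects lat/lon to a planar (x, y) frame in km centered at
#' `center`: x east, y north, with great-circle distance from the center
#' preserved exactly. Used for trip simulation, KDE and null sampling so
#' bandwidths and covariances are in true km.
#'
#' @param lat,lon degrees.
#' @param center numeric `c(lat, lon)` of the projection origin.
#' @return matrix with columns `x`, `y` (km).
#' @export
aeqd_project <- function(lat, lon, center) {
  d <- haversine_km(center[1], center[2], lat, lon)
  th <- deg2rad(bearing_deg(center[1], center[2], lat, lon))
  out <- cbind(x = d * sin(th), y = d * cos(th))
  out[d == 0, ] <- 0
  out
}

#' Inverse azimuthal-equidistant projection
#'
#' @param xy matrix with columns x, y in km.
#' @inheritParams aeqd_project
#' @return data.frame with `lat`, `lon` in degrees.
#' @export
aeqd_unproject <- function(xy, center) {
  xy <- rbind(xy)
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  th <- rad2deg(atan2(xy[, 1], xy[, 2]))
  p <- destination_point(center[1], center[2], th, d)
  data.frame(lat = p$lat, lon = p$lon)
}

#' Intermediate points on a great circle
#'
#' Spherical linear interpolation between two points at fractional
#' positions `f` (0 at point 1, 1 at point 2).
#'
#' @inheritParams haversine_km
#' @param f numeric vector of fractions in [0, 1].
#' @return data.frame with `lat`, `lon`.
#' @export
gc_intermediate <- function(lat1, lon1, lat2, lon2, f) {
  p1 <- deg2rad(lat1); l1 <- deg2rad(lon1)
  p2 <- deg2rad(lat2); l2 <- deg2rad(lon2)
  d <- 2 * asin(pmin(1, sqrt(sin((p2 - p1) / 2)^2 +
                             cos(p1) * cos(p2) * sin((l2 - l1) / 2)^2)))
  if (d == 0) {
    return(data.frame(lat = rep(lat1, length(f)), lon = rep(lon1, length(f))))
  }
  A <- sin((1 - f) * d) / sin(d)
  B <- sin(f * d) / sin(d)
  x <- A * cos(p1) * cos(l1) + B * cos(p2) * cos(l2)
  y <- A * cos(p1) * sin(l1) + B * cos(p2) * sin(l2)
  z <- A * sin(p1) + B * sin(p2)
  data.frame(lat = rad2deg(atan2(z, sqrt(x^2 + y^2))),
             lon = normalize_lon(rad2deg(atan2(y, x))))
}

#' Local clock hour for a UTC timestamp
#'
#' The study region's clock hours are reported with a fixed UTC offset
#' (default -11 h); no daylight-saving logic is applied.
#'
#' @param t POSIXct (UTC).
#' @param utc_offset hours to add to UTC (default -11).
#' @return fractional hour in [0, 24).
#' @export
local_hour <- function(t, utc_offset = -11) {
  s <- as.numeric(t) %% 86400 / 3600 + utc_offset
  s %% 24
}
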