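# Geostrophic velocity anomalies and eddy kinetic energy from gridded
# sea-surface-height anomalies.
#
# Under geostrophy the surface velocity anomaly follows the anomaly
# slope rotated 90 degrees:
#   U'_g = -(g/f) * d(eta')/dy,   V'_g = (g/f) * d(eta')/dx
# with g gravity, f = 2*Omega*sin(lat) the Coriolis parameter, and the
# derivatives taken on the sphere (dx = R cos(lat) dlon, dy = R dlat).
# With eta' in cm the velocities come out directly in cm/s. EKE per
# unit mass is half the time-averaged squared speed of the anomaly
# flow, <U'^2 + V'^2>/2, in cm^2/s^2.

GRAVITY_MS2 <- 9.81
OMEGA_RADS <- 7.2921e-5

# central differences along one margin of a matrix, one-sided at edges;
# spacing may vary with the *other* margin's index (dx depends on lat).
fd_matrix <- function(z, spacing, margin) {
  n <- dim(z)[margin]
  if (margin == 1) {
    d <- (z[c(2:n, n), ] - z[c(1, 1:(n - 1)), ])
    steps <- matrix(c(1, rep(2, n - 2), 1), nrow(z), ncol(z))
    d / (steps * spacing)
  } else {
    d <- (z[, c(2:n, n)] - z[, c(1, 1:(n - 1))])
    steps <- matrix(c(1, rep(2, n - 2), 1), nrow(z), ncol(z), byrow = TRUE)
    d / (steps * spacing)
  }
}

#' Geostrophic velocity anomalies from SSHA
#'
#' Computes `U' = -(g/f) d(eta)/dy` and `V' = (g/f) d(eta)/dx` per
#' weekly snapshot with central differences (one-sided at grid edges).
#' The grid must stay away from the equator (|lat| > 5 degrees) so f is
#' well-conditioned.
#'
#' @param ssha an `ssha_grid` (eta in cm).
#' @return object of class `velocity_field`: list with `time`, `lon`,
#'   `lat`, and arrays `u`, `v` (`[lon, lat, time]`, cm/s).
#' @export
geostrophic_anomalies <- function(ssha) {
  stopifnot(inherits(ssha, "ssha_grid"))
  if (any(abs(ssha$lat) <= 5)) {
    stop("grid latitude must satisfy |lat| > 5 degrees (f ill-conditioned near the equator)",
         call. = FALSE)
  }
  R_m <- EARTH_RADIUS_KM * 1000
  nlon <- length(ssha$lon); nlat <- length(ssha$lat); nt <- length(ssha$time)
  dlon <- deg2rad(diff(ssha$lon)[1]); dlat <- deg2rad(diff(ssha$lat)[1])
  dy <- R_m * dlat
  dx_row <- R_m * cos(deg2rad(ssha$lat)) * dlon     # per-latitude spacing, m
  f <- 2 * OMEGA_RADS * sin(deg2rad(ssha$lat))
  f_mat <- matrix(f, nlon, nlat, byrow = TRUE)
  dx_mat <- matrix(dx_row, nlon, nlat, byrow = TRUE)
  u <- array(NA_real_, c(nlon, nlat, nt))
  v <- array(NA_real_, c(nlon, nlat, nt))
  gf <- GRAVITY_MS2 / f_mat
  for (k in seq_len(nt)) {
    eta <- ssha$eta[, , k]               # cm
    deta_dx <- fd_matrix(eta, 1, margin = 1) / dx_mat   # cm/m
    deta_dy <- fd_matrix(eta, 1, margin = 2) / dy
    u[, , k] <- -gf * deta_dy            # (m/s)*(cm/m) = cm/s
    v[, , k] <- gf * deta_dx
  }
  structure(list(time = ssha$time, lon = ssha$lon, lat = ssha$lat,
                 u = u, v = v),
            class = "velocity_field")
}

#' Eddy kinetic energy field
#'
#' `eke = 0.5 * <U'^2 + V'^2>`, the time average running over the
#' selected snapshots, per grid node, in cm^2/s^2.
#'
#' @param vel a `velocity_field`.
#' @param snapshots indices or Dates selecting the averaging window;
#'   default all.
#' @return object of class `eke_field`: list with `lon`, `lat`, `eke`
#'   matrix and the averaging `window` dates.
#' @export
eke_field <- function(vel, snapshots = NULL) {
  stopifnot(inherits(vel, "velocity_field"))
  idx <- if (is.null(snapshots)) {
    seq_along(vel$time)
  } else if (inherits(snapshots, "Date")) {
    which(vel$time %in% snapshots)
  } else {
    snapshots
  }
  if (length(idx) == 0) stop("empty averaging window", call. = FALSE)
  sq <- vel$u[, , idx, drop = FALSE]^2 + vel$v[, , idx, drop = FALSE]^2
  eke <- 0.5 * apply(sq, c(1, 2), mean)
  structure(list(lon = vel$lon, lat = vel$lat, eke = eke,
                 window = vel$time[idx]),
            class = "eke_field")
}

#' Minimum convex polygon of at-sea locations
#'
#' Convex hull computed in an azimuthal-equidistant plane centered on
#' the points' centroid, returned as a lat/lon ring.
#'
#' @param lat,lon location coordinates, degrees (at least 3 points, not
#'   all collinear).
#' @return object of class `study_polygon`: list with ring `lat`,
#'   `lon` (not closed), `area_km2` and the projection `center`.
#' @export
mcp <- function(lat, lon) {
  if (length(lat) < 3) stop("need at least 3 points", call. = FALSE)
  center <- c(mean(lat), mean(normalize_lon(lon)))
  xy <- aeqd_project(lat, lon, center)
  hull <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(hull) < 3) stop("points are collinear", call. = FALSE)
  area <- abs(pracma::polyarea(xy[hull, 1], xy[hull, 2]))
  structure(list(lat = lat[hull], lon = lon[hull],
                 area_km2 = area, center = center),
            class = "study_polygon")
}

#' @export
print.study_polygon <- function(x, ...) {
  cat(sprintf("<study_polygon> %d vertices, %.0f km^2\n",
              length(x$lat), x$area_km2))
  invisible(x)
}

#' Monthly mean EKE inside a study polygon
#'
#' Restricts the velocity snapshots to one calendar month, averages the
#' squared anomaly speed over them, and takes the cos(lat)-weighted
#' mean over grid nodes inside the polygon.
#'
#' @param vel a `velocity_field`.
#' @param polygon a `study_polygon`.
#' @param month,year calendar month (1-12) and year selecting the
#'   snapshots.
#' @return scalar mean EKE, cm^2/s^2.
#' @export
mean_eke <- function(vel, polygon, month = 7, year = NULL) {
  stopifnot(inherits(vel, "velocity_field"), inherits(polygon, "study_polygon"))
  mo <- as.integer(format(vel$time, "%m"))
  yr <- as.integer(format(vel$time, "%Y"))
  idx <- which(mo == month & (if (is.null(year)) TRUE else yr == year))
  if (length(idx) == 0) stop("no snapshot in the requested month", call. = FALSE)
  fld <- eke_field(vel, idx)
  nodes_lon <- rep(fld$lon, times = length(fld$lat))
  nodes_lat <- rep(fld$lat, each = length(fld$lon))
  inside <- as.logical(pracma::inpolygon(nodes_lon, nodes_lat,
                                         polygon$lon, polygon$lat))
  if (!any(inside)) stop("no grid node inside polygon", call. = FALSE)
  w <- cos(deg2rad(nodes_lat[inside]))
  sum(as.vector(fld$eke)[inside] * w) / sum(w)
}
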