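# Solar position (NOAA low-precision algorithm) and day/twilight/dark
# classification. Accuracy of the elevation is a few hundredths of a degree
# over 1950-2050, ample for a 6-degree twilight band.

#' Solar elevation angle
#'
#' Geometric (unrefracted) solar elevation from the NOAA solar-position
#' algorithm: Julian centuries from J2000, solar declination from the
#' apparent ecliptic longitude and corrected obliquity, and the hour
#' angle from the equation of time.
#'
#' @param t POSIXct timestamp(s), UTC.
#' @param lat,lon position in degrees (lon positive east).
#' @return elevation in degrees above the horizon.
#' @export
solar_elevation <- function(t, lat, lon) {
  jd <- as.numeric(t) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) +
    sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(eps)) * sin(deg2rad(lambda)))
  # equation of time, minutes
  y <- tan(deg2rad(eps / 2))^2
  L0r <- deg2rad(L0)
  eqtime <- 4 * rad2deg(y * sin(2 * L0r) - 2 * e * sin(Mr) +
                          4 * e * y * sin(Mr) * cos(2 * L0r) -
                          0.5 * y^2 * sin(4 * L0r) -
                          1.25 * e^2 * sin(2 * Mr))
  utc_min <- (as.numeric(t) %% 86400) / 60
  tst <- (utc_min + eqtime + 4 * lon) %% 1440
  ha <- deg2rad(tst / 4 - 180)
  latr <- deg2rad(lat)
  el <- asin(sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha))
  rad2deg(el)
}

#' Classify day, civil twilight or darkness
#'
#' Elevation > 0 deg is `daylight`; -6 to 0 deg (civil twilight) is
#' `twilight`; below -6 deg is `dark`.
#'
#' @inheritParams solar_elevation
#' @return character vector in {"daylight", "twilight", "dark"}.
#' @export
classify_light <- function(t, lat, lon) {
  el <- solar_elevation(t, lat, lon)
  out <- rep("dark", length(el))
  out[el >= -6] <- "twilight"
  out[el > 0] <- "daylight"
  out
}
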