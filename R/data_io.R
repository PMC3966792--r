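# Readers and writers for every tabular/gridded input. All tables are
# comma-separated UTF-8 with a header row and ISO-8601 UTC timestamps
# ("YYYY-MM-DDTHH:MM:SSZ"). Grids travel as long-format CSV
# (lon,lat[,time],value) and are validated into rectangular-axis objects
# on read. Readers never reorder silently: the documented sort order is
# applied and asserted by tests; dropped-row counts are attached as
# attributes.

TIME_FMT <- "%Y-%m-%dT%H:%M:%SZ"

parse_utc <- function(x, file = "<input>") {
  t <- as.POSIXct(x, tz = "UTC", format = TIME_FMT)
  alt <- is.na(t) & !is.na(x)
  if (any(alt)) {
    a1 <- as.POSIXct(x[alt], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    a2 <- as.POSIXct(x[alt], tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    t[alt] <- as.POSIXct(ifelse(is.na(a1), as.numeric(a2), as.numeric(a1)),
                         origin = "1970-01-01", tz = "UTC")
  }
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: unparseable timestamp '%s' at data row %d",
                 file, x[bad[1]], bad[1]), call. = FALSE)
  }
  t
}

format_utc <- function(t) format(t, TIME_FMT, tz = "UTC")

check_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 file, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

read_csv_base <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_csv_base <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read GPS tracks
#'
#' Reads a CSV of GPS fixes and returns a validated data.frame sorted by
#' `(bird_id, t)`. Duplicate timestamps within a bird are collapsed to
#' the first occurrence; the number of rows dropped this way is attached
#' as `attr(, "dropped")`. Longitudes are normalized to [-180, 180).
#'
#' @param path CSV file with columns `bird_id, t, lat, lon` (or as
#'   remapped through `schema`).
#' @param schema named list mapping canonical names (`bird_id`, `t`,
#'   `lat`, `lon`) to the file's column names.
#' @return data.frame `bird_id, t (POSIXct UTC), lat, lon`.
#' @export
read_tracks <- function(path, schema = list()) {
  canon <- list(bird_id = "bird_id", t = "t", lat = "lat", lon = "lon")
  canon[names(schema)] <- schema
  df <- read_csv_base(path)
  check_cols(df, unlist(canon), path)
  out <- data.frame(bird_id = as.character(df[[canon$bird_id]]),
                    t = parse_utc(df[[canon$t]], path),
                    lat = as.numeric(df[[canon$lat]]),
                    lon = normalize_lon(as.numeric(df[[canon$lon]])))
  if (any(out$lat < -90 | out$lat > 90, na.rm = TRUE)) {
    stop(sprintf("%s: latitude outside [-90, 90]", path), call. = FALSE)
  }
  out <- out[order(out$bird_id, out$t), , drop = FALSE]
  dup <- duplicated(out[, c("bird_id", "t")])
  dropped <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Write GPS tracks
#' @param tracks data.frame as returned by [read_tracks()].
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  df <- tracks
  df$t <- format_utc(df$t)
  write_csv_base(df[, c("bird_id", "t", "lat", "lon")], path)
}

#' Read immersion (wet/dry activity) records
#'
#' @param path CSV with columns `bird_id, t, state, sample_interval_s`;
#'   `state` must be `wet` or `dry`, the sampling interval 1 or 3 s.
#' @return data.frame sorted by `(bird_id, t)`.
#' @export
read_immersion <- function(path) {
  df <- read_csv_base(path)
  check_cols(df, c("bird_id", "t", "state", "sample_interval_s"), path)
  out <- data.frame(bird_id = as.character(df$bird_id),
                    t = parse_utc(df$t, path),
                    state = as.character(df$state),
                    sample_interval_s = as.integer(df$sample_interval_s))
  if (!all(out$state %in% c("wet", "dry"))) {
    stop(sprintf("%s: state must be 'wet' or 'dry'", path), call. = FALSE)
  }
  if (!all(out$sample_interval_s %in% c(1L, 3L))) {
    stop(sprintf("%s: sample_interval_s must be 1 or 3", path), call. = FALSE)
  }
  out <- out[order(out$bird_id, out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_immersion
#' @param immersion data.frame of immersion records.
#' @export
write_immersion <- function(immersion, path) {
  df <- immersion
  df$t <- format_utc(df$t)
  write_csv_base(df[, c("bird_id", "t", "state", "sample_interval_s")], path)
}

# Assemble a rectangular grid object from long-format columns; errors if
# the (lon, lat) combinations do not form a full grid or an axis is
# non-monotone after sorting (i.e. has duplicates).
grid_from_long <- function(lon, lat, val, file) {
  lons <- sort(unique(lon)); lats <- sort(unique(lat))
  if (length(lons) < 2 || length(lats) < 2) {
    stop(sprintf("%s: grid needs at least 2 x 2 nodes", file), call. = FALSE)
  }
  if (length(lon) != length(lons) * length(lats)) {
    stop(sprintf("%s: not a rectangular grid", file), call. = FALSE)
  }
  z <- matrix(NA_real_, length(lons), length(lats))
  z[cbind(match(lon, lons), match(lat, lats))] <- val
  if (anyNA(match(lon, lons))) stop(sprintf("%s: bad grid axes", file), call. = FALSE)
  list(lon = lons, lat = lats, z = z)
}

#' Read a bathymetry grid
#'
#' Long-format CSV with columns `lon, lat, depth_m` (depth positive
#' down, NA on land), validated to a rectangular grid with ascending
#' axes.
#'
#' @param path CSV path.
#' @return object of class `bathy_grid`: list with `lon`, `lat`
#'   (ascending degree axes) and `depth` matrix indexed `[lon, lat]`.
#' @export
read_bathymetry <- function(path) {
  df <- read_csv_base(path)
  check_cols(df, c("lon", "lat", "depth_m"), path)
  g <- grid_from_long(normalize_lon(df$lon), df$lat, as.numeric(df$depth_m), path)
  if (any(g$z < 0, na.rm = TRUE)) {
    stop(sprintf("%s: negative depth at sea", path), call. = FALSE)
  }
  structure(list(lon = g$lon, lat = g$lat, depth = g$z), class = "bathy_grid")
}

#' @rdname read_bathymetry
#' @param bathy a `bathy_grid`.
#' @export
write_bathymetry <- function(bathy, path) {
  df <- expand.grid(lon = bathy$lon, lat = bathy$lat)
  df$depth_m <- as.vector(bathy$depth)
  write_csv_base(df, path)
}

#' Read weekly sea-surface-height-anomaly snapshots
#'
#' Long-format CSV with columns `time, lon, lat` and an anomaly column
#' named either `eta_cm` or `eta_m`; values are normalized to cm on read
#' (`eta_m` is multiplied by 100). Any other anomaly column name is an
#' error -- units are never guessed. Snapshots must be spaced a uniform
#' 7 days apart.
#'
#' @param path CSV path.
#' @return object of class `ssha_grid`: list with `time` (Date vector),
#'   `lon`, `lat` axes and `eta` array `[lon, lat, time]` in cm.
#' @export
read_ssha <- function(path) {
  df <- read_csv_base(path)
  check_cols(df, c("time", "lon", "lat"), path)
  if ("eta_cm" %in% names(df)) {
    val <- as.numeric(df$eta_cm)
  } else if ("eta_m" %in% names(df)) {
    val <- as.numeric(df$eta_m) * 100
  } else {
    stop(sprintf(
      "%s: anomaly column must be 'eta_cm' or 'eta_m' (units are not guessed)",
      path), call. = FALSE)
  }
  times <- sort(unique(as.Date(df$time)))
  if (length(times) > 1 && !all(diff(as.numeric(times)) == 7)) {
    stop(sprintf("%s: snapshots must be 7 days apart", path), call. = FALSE)
  }
  tm <- as.Date(df$time)
  lon <- normalize_lon(df$lon)
  first <- tm == times[1]
  g1 <- grid_from_long(lon[first], df$lat[first], val[first], path)
  eta <- array(NA_real_, c(length(g1$lon), length(g1$lat), length(times)))
  for (k in seq_along(times)) {
    sel <- tm == times[k]
    gk <- grid_from_long(lon[sel], df$lat[sel], val[sel], path)
    if (!identical(gk$lon, g1$lon) || !identical(gk$lat, g1$lat)) {
      stop(sprintf("%s: snapshot grids differ", path), call. = FALSE)
    }
    eta[, , k] <- gk$z
  }
  structure(list(time = times, lon = g1$lon, lat = g1$lat, eta = eta),
            class = "ssha_grid")
}

#' @rdname read_ssha
#' @param ssha an `ssha_grid`.
#' @export
write_ssha <- function(ssha, path) {
  nlon <- length(ssha$lon); nlat <- length(ssha$lat); nt <- length(ssha$time)
  df <- data.frame(
    time = rep(as.character(ssha$time), each = nlon * nlat),
    lon = rep(rep(ssha$lon, times = nlat), times = nt),
    lat = rep(rep(ssha$lat, each = nlon), times = nt),
    eta_cm = as.vector(ssha$eta))
  write_csv_base(df, path)
}

#' Read an eddy-trajectory table
#'
#' One row per eddy per week. Eddies with lifetimes below
#' `min_lifetime_weeks` (default 16 weeks, i.e. four months) are removed
#' on read; the number of removed rows is attached as
#' `attr(, "removed")`.
#'
#' @param path CSV with columns `eddy_id, week, center_lat, center_lon,
#'   radius_km, polarity, amplitude_cm, lifetime_weeks`.
#' @param min_lifetime_weeks lifetime filter threshold in weeks.
#' @return data.frame sorted by `(week, eddy_id)`.
#' @export
read_eddy_table <- function(path, min_lifetime_weeks = 16) {
  df <- read_csv_base(path)
  check_cols(df, c("eddy_id", "week", "center_lat", "center_lon",
                   "radius_km", "polarity", "amplitude_cm", "lifetime_weeks"),
             path)
  bad <- which(!df$polarity %in% c("cyclonic", "anticyclonic"))
  if (length(bad)) {
    stop(sprintf("%s: invalid polarity '%s' at data row %d",
                 path, df$polarity[bad[1]], bad[1]), call. = FALSE)
  }
  if (any(df$radius_km <= 0)) {
    stop(sprintf("%s: radius_km must be positive", path), call. = FALSE)
  }
  out <- data.frame(eddy_id = as.character(df$eddy_id),
                    week = as.Date(df$week),
                    center_lat = as.numeric(df$center_lat),
                    center_lon = normalize_lon(as.numeric(df$center_lon)),
                    radius_km = as.numeric(df$radius_km),
                    polarity = as.character(df$polarity),
                    amplitude_cm = as.numeric(df$amplitude_cm),
                    lifetime_weeks = as.integer(df$lifetime_weeks))
  keep <- out$lifetime_weeks >= min_lifetime_weeks
  removed <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$week, out$eddy_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' @rdname read_eddy_table
#' @param eddies eddy table data.frame.
#' @export
write_eddy_table <- function(eddies, path) {
  df <- eddies
  df$week <- as.character(df$week)
  write_csv_base(df[, c("eddy_id", "week", "center_lat", "center_lon",
                        "radius_km", "polarity", "amplitude_cm",
                        "lifetime_weeks")], path)
}

#' Read diet samples
#'
#' `prey` holds a semicolon-separated list of prey categories; an empty
#' string marks an empty sample. The `empty` flag is derived, and a
#' non-empty prey list on a row flagged empty is an error.
#'
#' @param path CSV with columns `sample_id, colony, year, prey`.
#' @return data.frame with list-column `prey_present` and logical
#'   `empty`.
#' @export
read_diet_samples <- function(path) {
  df <- read_csv_base(path)
  check_cols(df, c("sample_id", "colony", "year", "prey"), path)
  prey <- strsplit(ifelse(is.na(df$prey), "", as.character(df$prey)), ";",
                   fixed = TRUE)
  prey <- lapply(prey, function(p) p[nzchar(p)])
  out <- data.frame(sample_id = as.character(df$sample_id),
                    colony = as.character(df$colony),
                    year = as.integer(df$year))
  out$prey_present <- prey
  out$empty <- lengths(prey) == 0
  out
}

#' @rdname read_diet_samples
#' @param samples diet sample data.frame.
#' @export
write_diet_samples <- function(samples, path) {
  df <- data.frame(sample_id = samples$sample_id,
                   colony = samples$colony,
                   year = samples$year,
                   prey = vapply(samples$prey_present, paste,
                                 character(1), collapse = ";"))
  write_csv_base(df, path)
}

#' Read productivity plots
#'
#' @param path CSV with columns `plot_id, colony, year,
#'   nests_with_chicks, nests_with_fledglings`; fledgling counts may not
#'   exceed chick counts.
#' @export
read_productivity <- function(path) {
  df <- read_csv_base(path)
  check_cols(df, c("plot_id", "colony", "year", "nests_with_chicks",
                   "nests_with_fledglings"), path)
  if (any(df$nests_with_fledglings > df$nests_with_chicks |
            df$nests_with_fledglings < 0)) {
    stop(sprintf("%s: need 0 <= fledglings <= chicks", path), call. = FALSE)
  }
  df$year <- as.integer(df$year)
  df
}

#' Read baseline corticosterone samples
#'
#' Adds the derived `log10_cort` column; non-positive concentrations are
#' an error.
#'
#' @param path CSV with columns `bird_id, colony, year, cort_ng_ml`.
#' @export
read_cort <- function(path) {
  df <- read_csv_base(path)
  check_cols(df, c("bird_id", "colony", "year", "cort_ng_ml"), path)
  bad <- which(!(df$cort_ng_ml > 0))
  if (length(bad)) {
    stop(sprintf("%s: non-positive CORT at data row %d", path, bad[1]),
         call. = FALSE)
  }
  df$year <- as.integer(df$year)
  df$log10_cort <- log10(df$cort_ng_ml)
  df
}

#' Read a data-logger deployment table
#'
#' @param path CSV with columns `colony, year, deployed, recovered,
#'   failed_nests, usable, trips`; requires
#'   `usable <= recovered <= deployed` per row.
#' @export
read_deployments <- function(path) {
  df <- read_csv_base(path)
  check_cols(df, c("colony", "year", "deployed", "recovered",
                   "failed_nests", "usable", "trips"), path)
  if (any(df$usable > df$recovered | df$recovered > df$deployed)) {
    stop(sprintf("%s: need usable <= recovered <= deployed", path),
         call. = FALSE)
  }
  df$year <- as.integer(df$year)
  df
}
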