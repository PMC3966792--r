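# Trip segmentation, interpolation, metrics, habitat assignment and
# habitat-preference scores.

#' Segment a track into colony-based foraging trips
#'
#' A trip is a maximal run of fixes farther than `radius_km` from the
#' colony that lasts at least `min_duration_min`. The at-colony fixes
#' bracketing the run define the trip's start and end times and are
#' included in the trip's fixes; a run missing a bracket (track starts
#' or ends at sea, e.g. battery failure) is flagged `incomplete`. A trip
#' containing an internal fix gap of 30 min or more is flagged `gappy`.
#'
#' @param track data.frame of fixes for one bird (`bird_id, t, lat,
#'   lon`), time-sorted.
#' @param colony `c(lat, lon)`.
#' @param radius_km at-colony radius (default 1 km).
#' @param min_duration_min minimum trip duration (default 15 min).
#' @return list of objects of class `trip`: lists with `bird_id`,
#'   `fixes`, `start_t`, `end_t`, `complete`, `gappy`.
#' @export
segment_trips <- function(track, colony, radius_km = 1, min_duration_min = 15) {
  if (nrow(track) == 0) return(list())
  stopifnot(!is.unsorted(track$t))
  d <- haversine_km(colony[1], colony[2], track$lat, track$lon)
  away <- d > radius_km
  if (!any(away)) return(list())
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  trips <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    pre <- if (i0 > 1) i0 - 1L else NA_integer_
    post <- if (i1 < nrow(track)) i1 + 1L else NA_integer_
    complete <- !is.na(pre) && !is.na(post)
    start_t <- track$t[if (is.na(pre)) i0 else pre]
    end_t <- track$t[if (is.na(post)) i1 else post]
    if (as.numeric(end_t) - as.numeric(start_t) < min_duration_min * 60) next
    idx <- seq(if (is.na(pre)) i0 else pre, if (is.na(post)) i1 else post)
    fixes <- track[idx, , drop = FALSE]
    rownames(fixes) <- NULL
    gappy <- any(diff(as.numeric(fixes$t)) >= 30 * 60)
    trips[[length(trips) + 1]] <- structure(
      list(bird_id = track$bird_id[i0], fixes = fixes,
           start_t = start_t, end_t = end_t,
           complete = complete, gappy = gappy),
      class = "trip")
  }
  trips
}

#' @export
print.trip <- function(x, ...) {
  cat(sprintf("<trip> %s: %s to %s, %d fixes%s%s\n", x$bird_id,
              format_utc(x$start_t), format_utc(x$end_t), nrow(x$fixes),
              if (!x$complete) " [incomplete]" else "",
              if (isTRUE(x$gappy)) " [gappy]" else ""))
  invisible(x)
}

#' Interpolate a trip at 10-m spatial intervals
#'
#' Between each pair of consecutive fixes separated by less than
#' `max_gap_min` (default 30 min), points are inserted every
#' `spacing_m` (default 10 m) along the great-circle segment, endpoints
#' kept, with timestamps interpolated linearly along the segment. Pairs
#' at or beyond the gap threshold are left unfilled and the trip is
#' flagged `gappy`.
#'
#' @param trip a `trip` object.
#' @param spacing_m spacing of inserted points, metres.
#' @param max_gap_min gaps at or above this many minutes are not
#'   interpolated.
#' @return the trip with resampled `fixes` and updated `gappy` flag.
#' @export
interpolate_trip <- function(trip, spacing_m = 10, max_gap_min = 30) {
  fx <- trip$fixes
  n <- nrow(fx)
  if (n < 2) return(trip)
  out <- vector("list", n - 1)
  gap_seen <- FALSE
  for (i in seq_len(n - 1)) {
    dt <- as.numeric(fx$t[i + 1]) - as.numeric(fx$t[i])
    dm <- haversine_km(fx$lat[i], fx$lon[i], fx$lat[i + 1], fx$lon[i + 1]) * 1000
    if (dt >= max_gap_min * 60) {
      gap_seen <- TRUE
      out[[i]] <- fx[i, , drop = FALSE]
      next
    }
    if (dm <= spacing_m) {
      out[[i]] <- fx[i, , drop = FALSE]
      next
    }
    k <- floor(dm / spacing_m)
    # endpoint supplied by the next pair; tolerance guards float roundoff
    if (k * spacing_m >= dm - 1e-6) k <- k - 1
    f <- (seq_len(k) * spacing_m) / dm
    mid <- gc_intermediate(fx$lat[i], fx$lon[i], fx$lat[i + 1], fx$lon[i + 1],
                           f)
    out[[i]] <- rbind(
      fx[i, c("bird_id", "t", "lat", "lon")],
      data.frame(bird_id = fx$bird_id[i],
                 t = fx$t[i] + f * dt,
                 lat = mid$lat, lon = mid$lon))
  }
  res <- rbind(do.call(rbind, out), fx[n, c("bird_id", "t", "lat", "lon")])
  rownames(res) <- NULL
  trip$fixes <- res
  trip$gappy <- isTRUE(trip$gappy) | gap_seen
  trip
}

#' Maximum distance and duration of a trip
#'
#' Maximum great-circle distance from the colony over the trip's fixes,
#' and the duration between the bracketing start and end times.
#'
#' @param trip a `trip`.
#' @param colony `c(lat, lon)`.
#' @return list with `max_distance_km`, `duration_h` and
#'   `furthest_fix` (one-row data.frame).
#' @export
trip_metrics <- function(trip, colony) {
  d <- haversine_km(colony[1], colony[2], trip$fixes$lat, trip$fixes$lon)
  i <- which.max(d)
  list(max_distance_km = d[i],
       duration_h = (as.numeric(trip$end_t) - as.numeric(trip$start_t)) / 3600,
       furthest_fix = trip$fixes[i, , drop = FALSE])
}

# Bilinear interpolation of a grid object's matrix z[lon, lat] at
# (lat, lon); NA outside the grid hull.
bilinear <- function(lon_ax, lat_ax, z, lat, lon) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  out <- rep(NA_real_, n)
  ix <- findInterval(lon, lon_ax)
  iy <- findInterval(lat, lat_ax)
  ok <- ix >= 1 & ix < length(lon_ax) & iy >= 1 & iy < length(lat_ax)
  ix <- pmax(ix, 1); iy <- pmax(iy, 1)
  wx <- (lon - lon_ax[ix]) / (lon_ax[pmin(ix + 1, length(lon_ax))] - lon_ax[ix])
  wy <- (lat - lat_ax[iy]) / (lat_ax[pmin(iy + 1, length(lat_ax))] - lat_ax[iy])
  v <- (1 - wx) * (1 - wy) * z[cbind(ix, iy)] +
    wx * (1 - wy) * z[cbind(pmin(ix + 1, length(lon_ax)), iy)] +
    (1 - wx) * wy * z[cbind(ix, pmin(iy + 1, length(lat_ax)))] +
    wx * wy * z[cbind(pmin(ix + 1, length(lon_ax)), pmin(iy + 1, length(lat_ax)))]
  out[ok] <- v[ok]
  out
}

#' Bilinearly interpolated water depth
#'
#' @param bathy a `bathy_grid`.
#' @param lat,lon query coordinates, degrees.
#' @return depth in metres (positive down); NA outside the grid.
#' @export
bilinear_depth <- function(bathy, lat, lon) {
  bilinear(bathy$lon, bathy$lat, bathy$depth, lat, lon)
}

#' Assign shelf or basin habitat to a trip
#'
#' Bilinear water depth at the furthest fix: depth of 200 m or less is
#' `shelf`, greater than 200 m is `basin` (the shelf break is merged
#' into basin). A furthest fix outside the grid or on land returns NA
#' with the reason in `attr(, "reason")`.
#'
#' @param trip a `trip`.
#' @param bathy a `bathy_grid`.
#' @param colony `c(lat, lon)`.
#' @param basin_depth_m habitat boundary depth (default 200).
#' @return "shelf", "basin" or NA.
#' @export
assign_habitat <- function(trip, bathy, colony, basin_depth_m = 200) {
  ff <- trip_metrics(trip, colony)$furthest_fix
  depth <- bilinear(bathy$lon, bathy$lat, bathy$depth, ff$lat, ff$lon)
  if (is.na(depth)) {
    return(structure(NA_character_, reason = "outside grid or on land"))
  }
  if (depth > basin_depth_m) "basin" else "shelf"
}

#' Per-bird habitat-preference scores
#'
#' Each bird is scored by the fraction of its classified trips to each
#' habitat: a bird with 1 basin and 2 shelf trips scores 0.33 basin and
#' 0.67 shelf. Scores are reported rounded to two decimals with the
#' full-precision fractions retained alongside. Birds with no
#' classified trips are excluded (count in `attr(, "excluded")`).
#'
#' @param trips_df data.frame with columns `bird_id` and `habitat`
#'   ("shelf"/"basin"/NA).
#' @return data.frame `bird_id, n_trips, basin_fraction,
#'   shelf_fraction, basin_score, shelf_score`.
#' @export
habitat_preference_scores <- function(trips_df) {
  ok <- trips_df[!is.na(trips_df$habitat), , drop = FALSE]
  excluded <- length(setdiff(unique(trips_df$bird_id), unique(ok$bird_id)))
  out <- do.call(rbind, lapply(split(ok, ok$bird_id), function(d) {
    nb <- sum(d$habitat == "basin"); ns <- sum(d$habitat == "shelf")
    data.frame(bird_id = d$bird_id[1], n_trips = nb + ns,
               basin_fraction = nb / (nb + ns),
               shelf_fraction = ns / (nb + ns))
  }))
  rownames(out) <- NULL
  out$basin_score <- round(out$basin_fraction, 2)
  out$shelf_score <- round(out$shelf_fraction, 2)
  attr(out, "excluded") <- excluded
  out
}

#' Flag nearshore trips
#'
#' TRUE when the trip's furthest fix lies within `threshold_km`
#' (default 3 km) of the shore, with the shore modelled as a circular
#' island.
#'
#' @param trip a `trip`.
#' @param colony `c(lat, lon)`.
#' @param shore list with `lat`, `lon` (island center) and `radius_km`.
#' @param threshold_km nearshore distance threshold.
#' @export
nearshore_flag <- function(trip, colony, shore, threshold_km = 3) {
  ff <- trip_metrics(trip, colony)$furthest_fix
  d_shore <- haversine_km(shore$lat, shore$lon, ff$lat, ff$lon) - shore$radius_km
  d_shore <= threshold_km
}

#' Process raw tracks into a trip table
#'
#' Convenience wrapper over [segment_trips()], [trip_metrics()] and
#' [assign_habitat()] for a multi-bird track table.
#'
#' @param tracks data.frame of fixes for any number of birds.
#' @param colony `c(lat, lon)`.
#' @param bathy a `bathy_grid` (optional; habitat NA when absent).
#' @param interpolate logical; resample fixes at 10-m spacing before
#'   computing metrics (default FALSE: interpolation along great-circle
#'   segments cannot change a trip's furthest point or duration).
#' @param ... passed to [segment_trips()].
#' @return list with `trips` (list of `trip` objects) and `table`
#'   (one row per trip: bird_id, trip, start, end, duration_h, max_km,
#'   habitat, complete, gappy).
#' @export
process_trips <- function(tracks, colony, bathy = NULL, interpolate = FALSE,
                          ...) {
  trips <- list()
  for (tr in split(tracks, tracks$bird_id)) {
    trips <- c(trips, segment_trips(tr, colony, ...))
  }
  if (interpolate) trips <- lapply(trips, interpolate_trip)
  rows <- lapply(seq_along(trips), function(i) {
    tp <- trips[[i]]
    m <- trip_metrics(tp, colony)
    hab <- if (is.null(bathy)) NA_character_ else
      as.character(assign_habitat(tp, bathy, colony))
    data.frame(bird_id = tp$bird_id, trip = i,
               start = tp$start_t, end = tp$end_t,
               duration_h = m$duration_h, max_km = m$max_distance_km,
               habitat = hab, complete = tp$complete, gappy = tp$gappy)
  })
  list(trips = trips, table = do.call(rbind, rows))
}
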