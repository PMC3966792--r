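# GPS x immersion fusion: 10-minute matched windows, wet fractions,
# foraging/resting classification and hour-of-day collation.

#' Build 10-minute matched GPS/immersion windows
#'
#' GPS fixes are subsampled to one per `window_min` minutes (the fix
#' nearest each grid time, within half a window). Each retained fix is
#' matched to the immersion samples in the asymmetric window from
#' `lag_before_min` before to `lag_after_min` after the fix (defaults 8
#' and 2 min), and the wet fraction is the count of wet samples over
#' all samples in the window -- samples are counted, not seconds, so
#' 1-s and 3-s loggers are handled alike. Windows holding fewer than
#' `min_sample_frac` of the expected sample count are dropped (their
#' number is in `attr(, "dropped")`): a wet fraction on a sparse window
#' is unstable.
#'
#' @param fixes data.frame of GPS fixes for one bird (`bird_id, t, lat,
#'   lon`), time-sorted.
#' @param immersion immersion records (see [read_immersion()]); only
#'   this bird's rows are used.
#' @param window_min,lag_before_min,lag_after_min window geometry,
#'   minutes.
#' @param min_sample_frac minimum fraction of expected immersion
#'   samples for a window to be kept.
#' @return data.frame `bird_id, t, lat, lon, wet_fraction, n_samples`.
#' @export
build_windows <- function(fixes, immersion, window_min = 10,
                          lag_before_min = 8, lag_after_min = 2,
                          min_sample_frac = 0.5) {
  stopifnot(nrow(fixes) > 0)
  imm <- immersion[immersion$bird_id == fixes$bird_id[1], , drop = FALSE]
  if (!all(imm$sample_interval_s %in% c(1L, 3L))) {
    stop("immersion sampling interval must be 1 or 3 s", call. = FALSE)
  }
  ft <- as.numeric(fixes$t)
  grid <- seq(ft[1], ft[length(ft)], by = window_min * 60)
  pick <- vapply(grid, function(g) {
    i <- which.min(abs(ft - g))
    if (abs(ft[i] - g) <= window_min * 30) i else NA_integer_
  }, integer(1))
  pick <- unique(pick[!is.na(pick)])
  it <- as.numeric(imm$t)
  wet <- imm$state == "wet"
  interval <- if (nrow(imm)) imm$sample_interval_s[1] else 3L
  expected <- (lag_before_min + lag_after_min) * 60 / interval
  ord <- order(it); it <- it[ord]; wet <- wet[ord]
  cum_wet <- c(0, cumsum(wet))
  rows <- lapply(pick, function(i) {
    lo <- ft[i] - lag_before_min * 60; hi <- ft[i] + lag_after_min * 60
    # inclusive [lo, hi]; the half-second shift keeps the lower endpoint in
    # despite double rounding at POSIXct magnitudes (timestamps are whole s)
    a <- findInterval(lo - 0.5, it) + 1L
    b <- findInterval(hi, it)
    n <- b - a + 1L
    if (n <= 0) n <- 0L
    wf <- if (n > 0) (cum_wet[b + 1] - cum_wet[a]) / n else NA_real_
    data.frame(bird_id = fixes$bird_id[i], t = fixes$t[i],
               lat = fixes$lat[i], lon = fixes$lon[i],
               wet_fraction = wf, n_samples = n)
  })
  out <- do.call(rbind, rows)
  keep <- !is.na(out$wet_fraction) & out$n_samples >= min_sample_frac * expected
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Classify matched windows as foraging, resting or not wet
#'
#' A window is `resting` when its wet fraction is at least
#' `rest_threshold` (default 0.9) and the previous or next window of
#' the same bird is also at or above the threshold -- a lone
#' high-wet window with drier neighbours still counts as foraging.
#' Any other window with a positive wet fraction is `foraging`; dry
#' windows are `not_wet`. Adjacency is positional in the bird's
#' time-ordered window sequence.
#'
#' @param windows data.frame from [build_windows()] (may hold several
#'   birds), time-sorted within bird.
#' @param rest_threshold wet fraction at or above which a window can be
#'   resting.
#' @return `windows` with a `behavior` column added.
#' @export
classify_windows <- function(windows, rest_threshold = 0.9) {
  res <- lapply(split(windows, windows$bird_id), function(d) {
    wf <- d$wet_fraction
    n <- length(wf)
    high <- wf >= rest_threshold
    prev_high <- c(FALSE, high[-n])
    next_high <- c(high[-1], FALSE)
    resting <- high & (prev_high | next_high)
    beh <- ifelse(resting, "resting",
                  ifelse(wf > 0, "foraging", "not_wet"))
    d$behavior <- beh
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$bird_id, out$t), , drop = FALSE]
}

#' Extract foraging locations from classified windows
#'
#' Keeps the foraging windows and attaches the light class (see
#' [classify_light()]).
#'
#' @param windows classified windows from [classify_windows()].
#' @return data.frame of foraging locations with a `light` column.
#' @export
foraging_locations <- function(windows) {
  out <- windows[windows$behavior == "foraging", , drop = FALSE]
  out$light <- classify_light(out$t, out$lat, out$lon)
  rownames(out) <- NULL
  out
}

#' Hour-of-day histogram of foraging locations
#'
#' Counts and within-group fractions of locations per local clock hour
#' (0-23), split by an optional grouping column (typically habitat).
#'
#' @param locations data.frame with `t` and optionally the `by` column.
#' @param by name of a grouping column, or NULL for a single group.
#' @param utc_offset hours added to UTC to obtain local clock time.
#' @return data.frame `group, hour, count, fraction`; fractions sum to
#'   1 within each group.
#' @export
hourly_histogram <- function(locations, by = NULL, utc_offset = -11) {
  grp <- if (is.null(by)) rep("all", nrow(locations)) else locations[[by]]
  hr <- floor(local_hour(locations$t, utc_offset))
  out <- do.call(rbind, lapply(split(seq_along(hr), grp), function(idx) {
    counts <- tabulate(hr[idx] + 1, nbins = 24)
    data.frame(group = grp[idx[1]], hour = 0:23, count = counts,
               fraction = counts / sum(counts))
  }))
  rownames(out) <- NULL
  out
}
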