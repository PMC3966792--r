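# Eddy association: temporal matching of foraging locations to weekly
# eddy observations, inside/near/outside categories with signed
# perimeter distances, a normally-distributed randomization null, and
# the contingency test against it.

#' Match foraging locations to weekly eddy observations
#'
#' Each location is paired with the eddy week minimizing the absolute
#' time offset (required at most `max_offset_days`, default 7, matching
#' a weekly cadence). Among that week's eddies the one with the
#' smallest absolute perimeter distance wins. The signed distance is
#' the great-circle distance to the eddy center minus its radius
#' (negative inside the perimeter), and the category is `inside`
#' (signed < 0), `near` (0 to < 20 km) or `outside` (20 to 200 km);
#' locations beyond 200 km from every perimeter are left uncategorized
#' (NA). Locations with no eddy week in range get NA matches; their
#' count is in `attr(, "unmatched")`.
#'
#' @param locations data.frame with `t`, `lat`, `lon`.
#' @param eddies eddy table (already lifetime-filtered, see
#'   [read_eddy_table()]).
#' @param near_km,outer_km category boundaries (defaults 20 and
#'   200 km).
#' @param max_offset_days maximum |time offset| to a weekly field.
#' @return `locations` with columns `eddy_id, polarity,
#'   signed_distance_km, category, time_offset_days` appended.
#' @export
match_to_eddies <- function(locations, eddies, near_km = 20, outer_km = 200,
                            max_offset_days = 7) {
  weeks <- sort(unique(eddies$week))
  n <- nrow(locations)
  out <- data.frame(eddy_id = rep(NA_character_, n),
                    polarity = NA_character_,
                    signed_distance_km = NA_real_,
                    category = NA_character_,
                    time_offset_days = NA_real_)
  loc_day <- as.numeric(as.Date(locations$t))
  offsets <- abs(outer(loc_day, as.numeric(weeks), "-"))
  unmatched <- 0L
  by_week <- split(eddies, eddies$week)
  for (i in seq_len(n)) {
    k <- which.min(offsets[i, ])
    if (offsets[i, k] > max_offset_days) {
      unmatched <- unmatched + 1L
      next
    }
    ew <- by_week[[as.character(weeks[k])]]
    sd_km <- haversine_km(locations$lat[i], locations$lon[i],
                          ew$center_lat, ew$center_lon) - ew$radius_km
    j <- which.min(abs(sd_km))
    out$eddy_id[i] <- ew$eddy_id[j]
    out$polarity[i] <- ew$polarity[j]
    out$signed_distance_km[i] <- sd_km[j]
    out$time_offset_days[i] <- offsets[i, k]
    out$category[i] <- if (sd_km[j] < 0) "inside"
      else if (sd_km[j] < near_km) "near"
      else if (sd_km[j] <= outer_km) "outside"
      else NA_character_
  }
  res <- cbind(locations, out)
  attr(res, "unmatched") <- unmatched
  res
}

#' Normally distributed random locations within the foraging perimeter
#'
#' Draws the same number of points as observed from the bivariate
#' normal with the observed locations' mean and covariance (in a
#' projected km plane), rejection-sampled to lie inside the convex hull
#' of the observed locations. Each null point inherits the timestamp of
#' its observed counterpart so temporal eddy matching applies alike.
#'
#' @param locations data.frame with `t`, `lat`, `lon` (at least 3
#'   distinct points).
#' @param seed integer seed; the draw is deterministic given it.
#' @return data.frame `t, lat, lon` of null locations.
#' @export
random_null <- function(locations, seed) {
  n <- nrow(locations)
  stopifnot(n >= 3)
  center <- c(mean(locations$lat), mean(normalize_lon(locations$lon)))
  xy <- aeqd_project(locations$lat, locations$lon, center)
  mu <- colMeans(xy)
  S <- stats::cov(xy)
  ch <- tryCatch(chol(S), error = function(e)
    stop("degenerate covariance of observed locations", call. = FALSE))
  hull <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  set.seed(as.integer(seed))
  pts <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  while (length(need)) {
    z <- matrix(stats::rnorm(2 * length(need)), ncol = 2) %*% ch
    cand <- sweep(z, 2, mu, "+")
    ok <- as.logical(pracma::inpolygon(cand[, 1], cand[, 2], hx, hy,
                                       boundary = TRUE))
    pts[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  ll <- aeqd_unproject(pts, center)
  data.frame(t = locations$t, lat = ll$lat, lon = ll$lon)
}

#' Chi-square test of eddy association against the null
#'
#' Pearson chi-square (df = 2) on the 2 x 3 contingency of sample
#' (observed vs null) by category (inside / near / outside), optionally
#' restricted to one eddy polarity. Uncategorized matches are dropped.
#' If any expected cell falls below 1 a warning is raised and a Fisher
#' exact p-value is attached as a flagged fallback.
#'
#' @param observed,null match tables from [match_to_eddies()].
#' @param polarity optional `"cyclonic"` or `"anticyclonic"` filter.
#' @return list with `chi2`, `df`, `p`, the contingency `table`,
#'   `expected_ok`, and `fisher_p` (NA unless flagged).
#' @export
association_test <- function(observed, null, polarity = NULL) {
  pick <- function(m) {
    cat_ <- m$category
    if (!is.null(polarity)) cat_[m$polarity != polarity] <- NA
    factor(cat_[!is.na(cat_)], levels = c("inside", "near", "outside"))
  }
  tab <- rbind(observed = table(pick(observed)), null = table(pick(null)))
  nonzero <- colSums(tab) > 0
  tab_t <- tab[, nonzero, drop = FALSE]
  ts <- suppressWarnings(stats::chisq.test(tab_t, correct = FALSE))
  expected_ok <- all(ts$expected >= 1)
  fisher_p <- NA_real_
  if (!expected_ok) {
    warning("expected cell count below 1; Fisher exact fallback flagged")
    fisher_p <- stats::fisher.test(tab_t)$p.value
  }
  list(chi2 = unname(ts$statistic), df = unname(ts$parameter),
       p = unname(ts$p.value), table = tab,
       expected_ok = expected_ok, fisher_p = fisher_p)
}

#' Histogram of signed perimeter distances
#'
#' Bins the signed distance to the nearest eddy perimeter (negative
#' inside the eddy); the perimeter sits at 0.
#'
#' @param matches match table from [match_to_eddies()].
#' @param polarity optional polarity filter.
#' @param breaks bin breaks in km, or a bin width (scalar).
#' @return data.frame `bin_lo, bin_hi, mid, count`.
#' @export
signed_distance_histogram <- function(matches, polarity = NULL, breaks = 20) {
  d <- matches$signed_distance_km
  if (!is.null(polarity)) d[matches$polarity != polarity] <- NA
  d <- d[!is.na(d) & !is.na(matches$category)]
  if (length(breaks) == 1) {
    lo <- floor(min(d) / breaks) * breaks
    hi <- ceiling(max(d) / breaks) * breaks
    breaks <- seq(lo, hi, by = breaks)
  }
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = utils::head(h$breaks, -1),
             bin_hi = utils::tail(h$breaks, -1),
             mid = h$mids, count = h$counts)
}
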