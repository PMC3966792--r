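# Kernel density estimation of foraging locations in a projected km
# plane: LSCV bandwidth selection, mass-calibrated core-area contours
# and contour overlap.

#' Least-squares cross-validation bandwidth
#'
#' Minimizes the exact LSCV score for a bivariate isotropic Gaussian
#' kernel,
#' `CV(h) = int fhat^2 - (2/n) sum_i fhat_{-i}(x_i)`,
#' over a search interval (default 1-100 km) with golden-section /
#' parabolic search ([stats::optimize()]).
#'
#' @param xy two-column matrix of projected locations (km).
#' @param interval search interval for h, km.
#' @return list with `h` (km) and `score` (the achieved CV value).
#' @export
lscv_bandwidth <- function(xy, interval = c(1, 100)) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  stopifnot(n >= 10)
  d2 <- as.vector(stats::dist(xy))^2
  if (all(d2 == 0)) stop("degenerate input: all locations identical", call. = FALSE)
  score <- function(h) {
    h2 <- h^2
    int_f2 <- (n + 2 * sum(exp(-d2 / (4 * h2)))) / (n^2 * 4 * pi * h2)
    loo <- 2 * sum(exp(-d2 / (2 * h2))) / (n * (n - 1) * 2 * pi * h2)
    int_f2 - 2 * loo
  }
  opt <- stats::optimize(score, interval = interval)
  list(h = opt$minimum, score = opt$objective)
}

#' Bivariate Gaussian kernel density surface
#'
#' Evaluates the KDE with bandwidth `h` on a regular grid (default 1-km
#' cells, extent the bounding box of the data padded by `3 h`), then
#' renormalizes so the cell masses sum to exactly 1.
#'
#' @param xy two-column matrix of projected locations (km).
#' @param h bandwidth, km.
#' @param cell_km grid cell size, km.
#' @param pad padding around the bounding box, km; default `3 * h`.
#' @return object of class `kde_surface`: list with grid axes `x`,
#'   `y`, density matrix `z` (`[x, y]`, integrates to 1), `h` and
#'   `cell_km`.
#' @export
kde_surface <- function(xy, h, cell_km = 1, pad = 3 * h) {
  xy <- as.matrix(xy)
  stopifnot(h > 0, nrow(xy) >= 1)
  gx <- seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad, by = cell_km)
  gy <- seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad, by = cell_km)
  # separable kernel: z = A B^T with A[i,k] = phi(gx_i - x_k) etc.
  A <- exp(-outer(gx, xy[, 1], "-")^2 / (2 * h^2))
  B <- exp(-outer(gy, xy[, 2], "-")^2 / (2 * h^2))
  z <- (A %*% t(B)) / (nrow(xy) * 2 * pi * h^2)
  z <- z / (sum(z) * cell_km^2)
  structure(list(x = gx, y = gy, z = z, h = h, cell_km = cell_km),
            class = "kde_surface")
}

#' @export
print.kde_surface <- function(x, ...) {
  cat(sprintf("<kde_surface> %d x %d grid, cell %.2g km, h = %.3g km\n",
              length(x$x), length(x$y), x$cell_km, x$h))
  invisible(x)
}

#' Mass-calibrated density contour (core area)
#'
#' Finds the density threshold whose superlevel set encloses
#' probability mass `level` (the home-range convention: the 50%
#' contour is the smallest region holding half the use), and extracts
#' the contour polygons at that threshold.
#'
#' @param surface a `kde_surface`.
#' @param level probability mass to enclose, in (0, 1).
#' @return object of class `core_area`: list with `level`,
#'   `threshold`, `mask` (logical cell matrix), `polygons` (list of
#'   `x`/`y` rings from [grDevices::contourLines()]), `area_km2`,
#'   `enclosed_mass`, and the grid axes.
#' @export
core_contour <- function(surface, level = 0.5) {
  stopifnot(inherits(surface, "kde_surface"))
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  cell2 <- surface$cell_km^2
  m <- as.vector(surface$z) * cell2
  ord <- order(m, decreasing = TRUE)
  cum <- cumsum(m[ord])
  k <- which(cum >= level)[1]
  threshold <- as.vector(surface$z)[ord[k]]
  mask <- surface$z >= threshold
  polys <- grDevices::contourLines(surface$x, surface$y, surface$z,
                                   levels = threshold)
  structure(list(level = level, threshold = threshold, mask = mask,
                 polygons = polys,
                 area_km2 = sum(mask) * cell2,
                 enclosed_mass = sum(m[mask]),
                 x = surface$x, y = surface$y, cell_km = surface$cell_km),
            class = "core_area")
}

#' @export
print.core_area <- function(x, ...) {
  cat(sprintf("<core_area> %.0f%% isopleth: %.1f km^2 in %d polygon(s), mass %.3f\n",
              100 * x$level, x$area_km2, length(x$polygons), x$enclosed_mass))
  invisible(x)
}

#' Percent overlap of one core area on another
#'
#' `area(a intersect b) / area(a) * 100`. Note the asymmetry:
#' `contour_overlap(a, b)` and `contour_overlap(b, a)` differ whenever
#' the two areas differ in size. Areas on the same grid intersect cell
#' masks directly; otherwise `a`'s cell centers are tested against
#' `b`'s polygons.
#'
#' @param a,b `core_area` objects in the same projection.
#' @return overlap percentage of `a`'s area.
#' @export
contour_overlap <- function(a, b) {
  stopifnot(inherits(a, "core_area"), inherits(b, "core_area"))
  if (sum(a$mask) == 0 || sum(b$mask) == 0) {
    warning("empty core area; overlap 0")
    return(0)
  }
  if (identical(a$x, b$x) && identical(a$y, b$y)) {
    return(100 * sum(a$mask & b$mask) / sum(a$mask))
  }
  centers <- cbind(rep(a$x, times = length(a$y))[as.vector(a$mask)],
                   rep(a$y, each = length(a$x))[as.vector(a$mask)])
  inside <- rep(FALSE, nrow(centers))
  for (p in b$polygons) {
    inside <- inside | as.logical(
      pracma::inpolygon(centers[, 1], centers[, 2], p$x, p$y))
  }
  100 * sum(inside) / sum(a$mask)
}
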