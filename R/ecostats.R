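# Diet, productivity, stress and deployment summary statistics, plus
# the generic contingency/correlation operations used throughout.

#' Frequency of occurrence of prey categories
#'
#' Per colony-year: the percentage of samples with prey remains
#' (non-empty samples) in which each prey category occurred. Empty
#' samples never enter the denominator. A colony-year with zero
#' non-empty samples is reported with NA percentages.
#'
#' @param samples diet samples (see [read_diet_samples()]).
#' @return data.frame `colony, year, prey, n_samples, n_occurrence,
#'   percent`.
#' @export
frequency_of_occurrence <- function(samples) {
  key <- interaction(samples$colony, samples$year, drop = TRUE)
  out <- lapply(split(samples, key), function(d) {
    nonempty <- d[!d$empty, , drop = FALSE]
    prey_all <- sort(unique(unlist(d$prey_present)))
    if (length(prey_all) == 0) prey_all <- character(0)
    n <- nrow(nonempty)
    occ <- vapply(prey_all, function(p)
      sum(vapply(nonempty$prey_present, function(s) p %in% s, logical(1))),
      integer(1))
    data.frame(colony = d$colony[1], year = d$year[1],
               prey = prey_all, n_samples = n, n_occurrence = occ,
               percent = if (n > 0) 100 * occ / n else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' 2 x 2 chi-square test
#'
#' Pearson chi-square on a 2 x 2 count table, with or without the Yates
#' continuity correction, df = 1. A zero row or column marginal is an
#' error.
#'
#' @param counts 2 x 2 matrix (or vector of length 4, filled by row).
#' @param yates apply the continuity correction (default TRUE).
#' @return list with `chi2` and `p`.
#' @export
chi_square_2x2 <- function(counts, yates = TRUE) {
  m <- matrix(as.numeric(counts), 2, 2, byrow = !is.matrix(counts))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ts <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(chi2 = unname(ts$statistic), p = unname(ts$p.value))
}

#' Reconstruct a count from a printed percentage
#'
#' Nearest-integer count corresponding to `pct` percent of `n`.
#'
#' @param pct percentage (0-100).
#' @param n group size.
#' @export
percent_count <- function(pct, n) round(pct / 100 * n)

#' Pearson correlation with one- or two-tailed p
#'
#' Wraps [stats::cor.test()]; `tail = "one"` tests the one-sided
#' alternative of a positive correlation (p is halved relative to the
#' two-sided value when r > 0, and 1 minus that when r < 0).
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param tail `"two"` or `"one"` (positive alternative).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  ts <- stats::cor.test(x, y, alternative = alt, method = "pearson")
  list(r = unname(ts$estimate), p = ts$p.value, n = length(x))
}

#' EKE vs diet/productivity correlation table
#'
#' Per colony and pooled: one-tailed (positive) Pearson correlations of
#' July-mean EKE against each oceanic prey's percent occurrence, and a
#' two-tailed correlation against fledging success. Years in which
#' myctophids account for less than `myctophid_min_pct` percent of prey
#' (default 4) are excluded first -- such years indicate negligible
#' basin use, so an EKE signal could not register in diets. Cells with
#' fewer than 3 retained years are reported as NA.
#'
#' @param series data.frame with columns `colony, year, eke`, one
#'   column per prey category (percent occurrence) and optionally
#'   `fledging`.
#' @param prey_cols names of the prey columns.
#' @param myctophid_col column used for the exclusion rule.
#' @param myctophid_min_pct exclusion threshold, percent.
#' @return data.frame `colony, variable, r, p, n, tail`, including a
#'   pooled `"total"` block; `attr(, "excluded")` holds the dropped
#'   colony-years.
#' @export
eke_diet_correlations <- function(series, prey_cols,
                                  myctophid_col = "myctophid",
                                  myctophid_min_pct = 4) {
  keep <- series[[myctophid_col]] >= myctophid_min_pct
  excluded <- series[!keep, c("colony", "year"), drop = FALSE]
  s <- series[keep, , drop = FALSE]
  groups <- c(split(s, s$colony), list(total = s))
  vars <- c(prey_cols, if ("fledging" %in% names(s)) "fledging")
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (v in vars) {
      tail <- if (v == "fledging") "two" else "one"
      if (nrow(d) < 3 || stats::sd(d[[v]]) == 0 || stats::sd(d$eke) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          colony = g, variable = v, r = NA_real_, p = NA_real_,
          n = nrow(d), tail = tail)
      } else {
        ct <- pearson_correlation(d$eke, d[[v]], tail = tail)
        rows[[length(rows) + 1]] <- data.frame(
          colony = g, variable = v, r = ct$r, p = ct$p, n = ct$n, tail = tail)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Fledging success from productivity plots
#'
#' Per-plot ratio of nests with fledglings to nests with chicks; the
#' colony-year value is the mean of plot ratios (plot-averaged to
#' reduce variance, not pooled over nests). Plots with zero chick
#' nests are excluded and counted.
#'
#' @param plots productivity table (see [read_productivity()]).
#' @return list with `plots` (ratios added) and `summary` (per
#'   colony-year mean and n); `attr(, "excluded")` counts dropped
#'   plots.
#' @export
fledging_success <- function(plots) {
  ok <- plots$nests_with_chicks > 0
  excluded <- sum(!ok)
  p <- plots[ok, , drop = FALSE]
  p$success <- p$nests_with_fledglings / p$nests_with_chicks
  key <- interaction(p$colony, p$year, drop = TRUE)
  summary <- do.call(rbind, lapply(split(p, key), function(d) {
    data.frame(colony = d$colony[1], year = d$year[1],
               mean_success = mean(d$success), n_plots = nrow(d))
  }))
  rownames(summary) <- NULL
  out <- list(plots = p, summary = summary)
  attr(out, "excluded") <- excluded
  out
}

#' Baseline CORT summary
#'
#' Mean log10 concentration per colony-year and the fraction of birds
#' above the non-return risk threshold (default 0.90 ng/mL, applied on
#' the raw scale).
#'
#' @param samples CORT table (see [read_cort()]).
#' @param threshold ng/mL threshold for the risk flag.
#' @return data.frame `colony, year, n, mean_log10, frac_above`.
#' @export
cort_summary <- function(samples, threshold = 0.90) {
  if (any(!(samples$cort_ng_ml > 0))) {
    stop("non-positive CORT concentration", call. = FALSE)
  }
  lg <- log10(samples$cort_ng_ml)
  key <- interaction(samples$colony, samples$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(samples)), key), function(i) {
    data.frame(colony = samples$colony[i[1]], year = samples$year[i[1]],
               n = length(i), mean_log10 = mean(lg[i]),
               frac_above = mean(samples$cort_ng_ml[i] > threshold))
  }))
  rownames(out) <- NULL
  out
}

#' Deployment summary roll-up
#'
#' Totals a per-colony-year deployment table and derives the headline
#' percentages: logger recovery (recovered/deployed), post-deployment
#' nest failure (failed/deployed) -- both rounded to the nearest
#' integer percent -- and the total trip count.
#'
#' @param deployments table from [read_deployments()].
#' @return list with the input `table` and `totals` (deployed,
#'   recovered, recovery_pct, failed, failure_pct, usable, trips).
#' @export
deployment_summary <- function(deployments) {
  tot <- list(deployed = sum(deployments$deployed),
              recovered = sum(deployments$recovered),
              failed = sum(deployments$failed_nests),
              usable = sum(deployments$usable),
              trips = sum(deployments$trips))
  tot$recovery_pct <- round(100 * tot$recovered / tot$deployed)
  tot$failure_pct <- round(100 * tot$failed / tot$deployed)
  list(table = deployments, totals = tot)
}
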