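mk_samples <- function(prey_lists, colony = "C", year = 2010) {
  df <- data.frame(sample_id = sprintf("S%d", seq_along(prey_lists)),
                   colony = colony, year = year)
  df$prey_present <- prey_lists
  df$empty <- lengths(prey_lists) == 0
  df
}

test_that("frequency of occurrence uses non-empty samples as denominator", {
  fo <- frequency_of_occurrence(mk_samples(list("myctophid")))
  expect_equal(fo$percent, 100)
  # 2 of 4 non-empty with squid; one empty sample excluded from denominator
  s <- mk_samples(list(c("squid", "offal"), "squid", "pollock", "offal",
                       character(0)))
  fo <- frequency_of_occurrence(s)
  expect_equal(fo$percent[fo$prey == "squid"], 50)
  expect_equal(unique(fo$n_samples), 4)
  # order invariance and brute-force agreement on random samples
  set.seed(20)
  prey_pool <- c("myctophid", "squid", "pollock", "sandlance", "offal")
  rand <- lapply(1:500, function(i)
    sample(prey_pool, rbinom(1, 5, 0.4)))
  s2 <- mk_samples(rand)
  fo2 <- frequency_of_occurrence(s2)
  s3 <- s2[sample(nrow(s2)), ]
  expect_equal(frequency_of_occurrence(s3), fo2)
  nonempty <- rand[lengths(rand) > 0]
  for (p in unique(fo2$prey)) {
    expect_equal(fo2$percent[fo2$prey == p],
                 100 * sum(vapply(nonempty, function(x) p %in% x, logical(1))) /
                   length(nonempty))
  }
  expect_true(all(fo2$percent <= 100 & fo2$percent >= 0))
})

test_that("2x2 chi-square reproduces the printed colony-by-habitat statistic", {
  counts <- matrix(c(percent_count(46, 82), 82 - percent_count(46, 82),
                     percent_count(24, 75), 75 - percent_count(24, 75)),
                   2, 2, byrow = TRUE)
  unc <- chi_square_2x2(counts, yates = FALSE)
  expect_equal(unc$chi2, 8.521, tolerance = 0.001)
  expect_lt(abs(unc$p - 0.0035), 2e-4)
  # identical rows give zero
  expect_equal(chi_square_2x2(matrix(c(10, 20, 10, 20), 2, 2), yates = FALSE)$chi2, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "marginal")
})

test_that("chi-square matches the ad-bc closed form and Yates never exceeds uncorrected", {
  set.seed(21)
  for (i in 1:1000) {
    m <- matrix(rpois(4, 20) + 1, 2, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    closed <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
    unc <- chi_square_2x2(m, yates = FALSE)$chi2
    expect_equal(unc, closed, tolerance = 1e-10)
    expect_lte(chi_square_2x2(m, yates = TRUE)$chi2, unc + 1e-12)
  }
})

test_that("pearson correlation handles tails and extremes", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 3)$r, 1)
  opp <- pearson_correlation(x, -x, tail = "one")
  expect_equal(opp$r, -1)
  expect_gt(opp$p, 0.99)
  # one-tailed p is half the two-tailed p when r > 0
  set.seed(22)
  a <- rnorm(12); b <- a + rnorm(12)
  expect_equal(pearson_correlation(a, b, tail = "one")$p,
               pearson_correlation(a, b, tail = "two")$p / 2)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
})

test_that("one-tailed p agrees with a permutation oracle at n = 8", {
  set.seed(3)
  x <- rnorm(8); y <- 0.5 * x + rnorm(8)
  got <- pearson_correlation(x, y, tail = "one")
  set.seed(99)
  perm <- replicate(10000, cor(x, sample(y)))
  p_perm <- mean(perm >= got$r)
  expect_lt(abs(got$p - p_perm), 0.02)
})

test_that("EKE-diet correlations apply the myctophid exclusion and pool correctly", {
  set.seed(23)
  mkser <- function(colony, n, rho_plant = TRUE) {
    eke <- runif(n, 20, 80)
    myct <- pmax(0, 0.5 * eke + rnorm(n, 0, 6))
    data.frame(colony = colony, year = 2000 + seq_len(n), eke = eke,
               myctophid = myct, squid = runif(n, 0, 30),
               fledging = runif(n, 0.2, 0.8))
  }
  s1 <- mkser("STP", 9); s2 <- mkser("STG", 8)
  s2$myctophid <- pmax(s2$myctophid, 5)  # STG stays above threshold
  # plant two below-threshold years at STP
  s1$myctophid[c(2, 5)] <- c(1, 3.5)
  ser <- rbind(s1, s2)
  tab <- eke_diet_correlations(ser, prey_cols = c("myctophid", "squid"))
  excl <- attr(tab, "excluded")
  expect_equal(nrow(excl), 2)
  expect_setequal(excl$year, c(2002, 2005))
  # pooled n equals the sum of retained colony-years
  n_tot <- tab$n[tab$colony == "total"][1]
  expect_equal(n_tot, sum(ser$myctophid >= 4))
  # planted positive EKE-myctophid link is detected one-tailed
  myct_row <- tab[tab$colony == "total" & tab$variable == "myctophid", ]
  expect_gt(myct_row$r, 0)
  expect_lt(myct_row$p, 0.05)
  expect_equal(myct_row$tail, "one")
  expect_equal(unique(tab$tail[tab$variable == "fledging"]), "two")
  # < 3 retained years: undefined cell
  tiny <- mkser("X", 3); tiny$myctophid[1] <- 0
  t2 <- eke_diet_correlations(tiny, prey_cols = "myctophid")
  expect_true(is.na(t2$r[t2$colony == "X"][1]))
})

test_that("fledging success is plot-averaged, not nest-pooled", {
  plots <- data.frame(plot_id = c("P1", "P2"), colony = "C", year = 2010,
                      nests_with_chicks = c(10, 100),
                      nests_with_fledglings = c(4, 60))
  fs <- fledging_success(plots)
  expect_equal(fs$plots$success, c(0.4, 0.6))
  expect_equal(fs$summary$mean_success, 0.5)  # plot mean
  pooled <- 64 / 110
  expect_false(isTRUE(all.equal(fs$summary$mean_success, pooled)))
  # zero-chick plots are excluded and counted
  plots0 <- rbind(plots, data.frame(plot_id = "P3", colony = "C", year = 2010,
                                    nests_with_chicks = 0,
                                    nests_with_fledglings = 0))
  fs0 <- fledging_success(plots0)
  expect_equal(attr(fs0, "excluded"), 1)
  expect_equal(fs0$summary$mean_success, 0.5)
})

test_that("CORT summary transforms and thresholds on the right scales", {
  s <- data.frame(bird_id = c("a", "b", "c"), colony = "C", year = 2010,
                  cort_ng_ml = c(1.0, 0.5, 2.0))
  cs <- cort_summary(s)
  expect_equal(cs$mean_log10, mean(log10(c(1, 0.5, 2))))
  expect_equal(cs$frac_above, 2 / 3)  # 1.0 and 2.0 exceed 0.90 ng/mL
  expect_equal(cort_summary(transform(s, cort_ng_ml = 0.5))$frac_above, 0)
  # brute-force count on simulated values
  cfg <- sim_config(seed = 29, cort = list(n = 1000L, mean_log10 = -0.05,
                                           sd_log10 = 0.25))
  sim <- simulate_cort(cfg)
  cs2 <- cort_summary(sim)
  expect_equal(cs2$frac_above, sum(sim$cort_ng_ml > 0.90) / 1000)
  expect_error(cort_summary(transform(s, cort_ng_ml = c(1, -1, 1))),
               "non-positive")
})

test_that("deployment roll-ups reproduce the published summary table", {
  dep <- read_deployments(system.file("extdata", "deployments.csv",
                                      package = "eddyforage"))
  ds <- deployment_summary(dep)
  expect_equal(ds$totals$trips, 310)
  expect_equal(ds$totals$deployed, 161)
  expect_equal(ds$totals$recovered, 154)
  expect_equal(ds$totals$recovery_pct, 96)
  expect_equal(ds$totals$failed, 16)
  expect_equal(ds$totals$failure_pct, 10)
  expect_equal(ds$totals$usable, 133)
})
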