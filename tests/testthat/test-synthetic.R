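test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_birds = 3)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a, b)
  expect_identical(simulate_ssha(cfg)$eddies, simulate_ssha(cfg)$eddies)
  expect_identical(simulate_cort(cfg), simulate_cort(cfg))
})

test_that("p_basin = 0 yields only shelf trips; empirical basin fraction tracks p_basin", {
  t0 <- simulate_tracks(sim_config(seed = 4, n_birds = 5, p_basin = 0))
  expect_true(all(t0$truth$trips$habitat == "shelf"))

  tr <- simulate_tracks(sim_config(seed = 12, n_birds = 40, p_basin = 0.46))
  n <- nrow(tr$truth$trips)
  phat <- mean(tr$truth$trips$habitat == "basin")
  ci <- 1.96 * sqrt(0.46 * 0.54 / n)
  expect_lt(abs(phat - 0.46), ci + 1e-12)
})

test_that("every bird makes at least one trip and all records carry truth labels", {
  sim <- small_sim()
  expect_setequal(unique(sim$tracks$bird_id), sim$truth$birds$bird_id)
  expect_true(all(sim$truth$birds$n_trips >= 1))
  # every GPS fix and immersion sample falls inside a labelled segment
  seg <- sim$truth$segments
  for (b in unique(sim$tracks$bird_id)) {
    s <- seg[seg$bird_id == b, ]
    tt <- as.numeric(sim$tracks$t[sim$tracks$bird_id == b])
    covered <- vapply(tt, function(x)
      any(x >= as.numeric(s$start) - 1 & x <= as.numeric(s$end) + 1), logical(1))
    expect_true(all(covered))
  }
  # basin trips span local night (some fix between 23:00 and 06:00 local)
  basin <- sim$truth$trips[sim$truth$trips$habitat == "basin", ]
  for (i in seq_len(nrow(basin))) {
    hrs <- local_hour(seq(basin$start[i], basin$end[i], by = 600))
    expect_true(any(hrs >= 23 | hrs < 6))
  }
})

test_that("immersion structure matches behavior archetypes", {
  sim <- small_sim()
  seg <- sim$truth$segments
  imm <- sim$immersion
  pick_seg <- function(beh) {
    s <- seg[seg$behavior == beh & as.numeric(seg$end) - as.numeric(seg$start) > 300, ][1, ]
    imm[imm$bird_id == s$bird_id & imm$t >= s$start & imm$t <= s$end, ]
  }
  expect_true(all(pick_seg("flight")$state == "dry"))
  expect_true(all(pick_seg("rest")$state == "wet"))
  fo <- pick_seg("forage")
  wf <- mean(fo$state == "wet")
  expect_gt(wf, 0.05); expect_lt(wf, 0.9)  # alternating, never rest-like
})

test_that("synthetic bathymetry has a shelf plateau and monotone break transect", {
  cfg <- sim_config(seed = 1)
  b <- simulate_bathymetry(cfg)
  d_colony <- bilinear_depth(b, cfg$colony[1], cfg$colony[2])
  expect_gte(d_colony, 100); expect_lte(d_colony, 200)
  # depth beyond the break exceeds 200 m at any planted basin destination
  p <- destination_point(cfg$colony[1], cfg$colony[2], 132, 150)
  expect_gt(bilinear_depth(b, p$lat, p$lon), 200)
  # radial transect is nondecreasing
  dd <- seq(0, 400, by = 5)
  pp <- destination_point(cfg$colony[1], cfg$colony[2], 77, dd)
  prof <- bilinear_depth(b, pp$lat, pp$lon)
  expect_true(all(diff(prof) >= -1e-9))
})

test_that("planted eddies appear in SSHA with exact center amplitude and superpose", {
  base <- sim_config(seed = 2)
  ax <- simulate_ssha(base)$ssha
  # center an eddy exactly on a grid node: its snapshot-1 maximum is the amplitude
  cfg1 <- sim_config(seed = 2, eddies = data.frame(
    eddy_id = "A", center_lat = ax$lat[30], center_lon = ax$lon[40],
    radius_km = 50, polarity = "anticyclonic", amplitude_cm = 21,
    lifetime_weeks = 20L))
  s1 <- simulate_ssha(cfg1)
  expect_equal(max(s1$ssha$eta[, , 1]), 21, tolerance = 1e-12)
  expect_equal(s1$ssha$eta[40, 30, 1], 21, tolerance = 1e-12)
  # cyclonic bump is negative
  cfgc <- cfg1; cfgc$eddies$polarity <- "cyclonic"
  expect_equal(min(simulate_ssha(cfgc)$ssha$eta[, , 1]), -21, tolerance = 1e-12)
  # zero eddies: flat field
  cfg0 <- sim_config(seed = 2, eddies = data.frame(
    eddy_id = character(), center_lat = numeric(), center_lon = numeric(),
    radius_km = numeric(), polarity = character(), amplitude_cm = numeric(),
    lifetime_weeks = integer()))
  expect_true(all(simulate_ssha(cfg0)$ssha$eta == 0))
  # two distant eddies superpose additively
  cfg2 <- sim_config(seed = 2, eddies = data.frame(
    eddy_id = c("A", "B"), center_lat = c(ax$lat[10], ax$lat[30]),
    center_lon = c(ax$lon[20], ax$lon[55]), radius_km = c(40, 50),
    polarity = c("anticyclonic", "cyclonic"), amplitude_cm = c(17, 9.7),
    lifetime_weeks = c(20L, 20L)))
  cfgA <- cfg2; cfgA$eddies <- cfg2$eddies[1, ]
  cfgB <- cfg2; cfgB$eddies <- cfg2$eddies[2, ]
  expect_equal(simulate_ssha(cfg2)$ssha$eta,
               simulate_ssha(cfgA)$ssha$eta + simulate_ssha(cfgB)$ssha$eta,
               tolerance = 1e-12)
  # eddy-table rows agree with planted centers/polarities each week
  et <- simulate_ssha(cfg2)$eddies
  expect_equal(nrow(et), 2 * length(ax$time))
  expect_setequal(unique(et$polarity), c("anticyclonic", "cyclonic"))
})

test_that("overlapping planted eddies warn rather than error", {
  cfg <- sim_config(seed = 2, eddies = data.frame(
    eddy_id = c("A", "B"), center_lat = c(56.2, 56.3),
    center_lon = c(-172.5, -172.4), radius_km = c(50, 50),
    polarity = c("anticyclonic", "cyclonic"), amplitude_cm = c(10, 10),
    lifetime_weeks = c(20L, 20L)))
  expect_warning(simulate_ssha(cfg), "overlap")
})

test_that("diets are drawn from the furthest-trip habitat distribution", {
  sim <- small_sim()
  cfg <- sim$cfg
  cfg$diet_probs$basin["myctophid"] <- 1.0
  diets <- simulate_diets(cfg, sim$truth)
  basin_birds <- diets$true_habitat == "basin"
  has_myct <- vapply(diets$prey_present, function(p) "myctophid" %in% p, logical(1))
  expect_true(all(has_myct[basin_birds]))
  # shelf birds never receive prey absent from the shelf distribution
  shelf_prey <- names(cfg$diet_probs$shelf)
  expect_true(all(unlist(diets$prey_present[!basin_birds]) %in% shelf_prey))
  expect_true(all(diets$empty == (lengths(diets$prey_present) == 0)))
})

test_that("productivity and CORT generators reproduce configured levels", {
  cfg <- sim_config(seed = 30,
                    productivity = list(n_plots = 40L, nests_range = c(8L, 12L),
                                        success = 0.5),
                    cort = list(n = 500L, mean_log10 = -0.05, sd_log10 = 0.25))
  pl <- simulate_productivity(cfg)
  pooled <- sum(pl$nests_with_fledglings) / sum(pl$nests_with_chicks)
  n_nests <- sum(pl$nests_with_chicks)
  expect_lt(abs(pooled - 0.5), 1.96 * sqrt(0.25 / n_nests))
  ct <- simulate_cort(cfg)
  se <- 0.25 / sqrt(500)
  expect_lt(abs(mean(log10(ct$cort_ng_ml)) - (-0.05)), 3 * se)
})

test_that("simulate_dataset writes a complete readable bundle", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 5, n_birds = 2)
  simulate_dataset(cfg, d)
  expect_true(all(c("tracks.csv", "immersion.csv", "bathymetry.csv", "ssha.csv",
                    "eddies.csv", "diets.csv", "plots.csv", "cort.csv",
                    "truth_trips.csv", "truth_birds.csv", "truth_segments.csv")
                  %in% list.files(d)))
  expect_s3_class(read_ssha(file.path(d, "ssha.csv")), "ssha_grid")
  expect_gt(nrow(read_tracks(file.path(d, "tracks.csv"))), 0)
  expect_gt(nrow(read_eddy_table(file.path(d, "eddies.csv"))), 0)
})
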