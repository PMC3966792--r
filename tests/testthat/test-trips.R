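colony <- c(57.125, -170.285)

test_that("segmentation finds planted excursions and respects the rules", {
  # never beyond 0.5 km: no trips
  t0 <- as.POSIXct("2010-07-10 00:00:00", tz = "UTC")
  near <- destination_point(colony[1], colony[2], 90, 0.4)
  tr <- data.frame(bird_id = "B", t = t0 + (0:20) * 180,
                   lat = rep(c(colony[1], near$lat), length.out = 21),
                   lon = rep(c(colony[2], near$lon), length.out = 21))
  expect_length(segment_trips(tr, colony), 0)

  # empty track: empty list, not an error
  expect_length(segment_trips(tr[0, ], colony), 0)

  # two excursions separated by 5 min at the colony stay distinct
  mk_leg <- function(t_start, dist) {
    tt <- seq(0, 3600, by = 180)
    d <- pmin(tt, 3600 - tt) / 1800 * dist
    p <- destination_point(colony[1], colony[2], 120, d)
    data.frame(bird_id = "B", t = t_start + tt, lat = p$lat, lon = p$lon)
  }
  two <- rbind(mk_leg(t0, 20), mk_leg(t0 + 3900, 25))
  two <- two[!duplicated(two$t), ]
  trips <- segment_trips(two, colony)
  expect_length(trips, 2)
  expect_true(all(vapply(trips, function(x) x$complete, logical(1))))

  # planted excursions on synthetic birds recover truth start/end
  sim <- small_sim()
  for (b in unique(sim$tracks$bird_id)) {
    tt <- segment_trips(sim$tracks[sim$tracks$bird_id == b, ], sim$cfg$colony)
    truth_b <- sim$truth$trips[sim$truth$trips$bird_id == b, ]
    expect_equal(length(tt), nrow(truth_b))
    for (k in seq_along(tt)) {
      expect_lt(abs(as.numeric(tt[[k]]$start_t) - as.numeric(truth_b$start[k])),
                2 * sim$cfg$gps_interval_s)
      expect_lt(abs(as.numeric(tt[[k]]$end_t) - as.numeric(truth_b$end[k])),
                2 * sim$cfg$gps_interval_s)
    }
  }
})

test_that("10-m interpolation fills short gaps and flags long ones", {
  t0 <- as.POSIXct("2010-07-10 00:00:00", tz = "UTC")
  p2 <- destination_point(57.0, -170.0, 90, 0.1)  # 100 m east
  trip <- structure(list(
    bird_id = "B",
    fixes = data.frame(bird_id = "B", t = c(t0, t0 + 300),
                       lat = c(57.0, p2$lat), lon = c(-170.0, p2$lon)),
    start_t = t0, end_t = t0 + 300, complete = TRUE, gappy = FALSE),
    class = "trip")
  out <- interpolate_trip(trip)
  expect_equal(nrow(out$fixes), 11)  # 10-m spacing incl. endpoints
  gaps <- haversine_km(out$fixes$lat[-11], out$fixes$lon[-11],
                       out$fixes$lat[-1], out$fixes$lon[-1]) * 1000
  expect_true(all(gaps <= 10 + 1e-6))
  expect_true(!is.unsorted(out$fixes$t))
  expect_false(out$gappy)

  # >= 30 min gap: no insertion, flag set
  trip45 <- trip
  trip45$fixes$t[2] <- t0 + 45 * 60
  out45 <- interpolate_trip(trip45)
  expect_equal(nrow(out45$fixes), 2)
  expect_true(out45$gappy)

  # path length is conserved by resampling
  sim <- small_sim()
  tp <- segment_trips(sim$tracks[sim$tracks$bird_id == sim$tracks$bird_id[1], ],
                      sim$cfg$colony)[[1]]
  seg_len <- function(f) sum(haversine_km(f$lat[-nrow(f)], f$lon[-nrow(f)],
                                          f$lat[-1], f$lon[-1]))
  before <- seg_len(tp$fixes)
  after <- seg_len(interpolate_trip(tp)$fixes)
  expect_lt(abs(after - before) / before, 0.001)
})

test_that("trip metrics: distance at the basin trip scale, reversal invariance", {
  tr <- planted_track(201.4)
  trips <- segment_trips(tr, colony)
  expect_length(trips, 1)
  m <- trip_metrics(trips[[1]], colony)
  expect_lt(abs(m$max_distance_km - 201.4), 0.5)
  expect_gt(m$duration_h, 0)
  # single fix at the colony: distance 0
  one <- structure(list(bird_id = "B", fixes = data.frame(
    bird_id = "B", t = tr$t[1], lat = colony[1], lon = colony[2]),
    start_t = tr$t[1], end_t = tr$t[1] + 60, complete = FALSE, gappy = FALSE),
    class = "trip")
  expect_equal(trip_metrics(one, colony)$max_distance_km, 0)
  # reversing fix order leaves the maximum unchanged
  rev_trip <- trips[[1]]
  rev_trip$fixes <- rev_trip$fixes[nrow(rev_trip$fixes):1, ]
  expect_equal(trip_metrics(rev_trip, colony)$max_distance_km,
               m$max_distance_km)
})

test_that("max distance is monotone as fixes accumulate", {
  tr <- planted_track(160)
  trips <- segment_trips(tr, colony)
  fx <- trips[[1]]$fixes
  d <- haversine_km(colony[1], colony[2], fx$lat, fx$lon)
  expect_true(all(diff(cummax(d)) >= 0))
})

test_that("habitat assignment follows the 200-m rule with shelf-break in basin", {
  sim <- small_sim()
  b <- sim$bathy
  mk_trip_at <- function(dist) {
    tr <- planted_track(dist, colony = sim$cfg$colony)
    segment_trips(tr, sim$cfg$colony)[[1]]
  }
  expect_equal(assign_habitat(mk_trip_at(30), b, sim$cfg$colony), "shelf")
  expect_equal(assign_habitat(mk_trip_at(200), b, sim$cfg$colony), "basin")
  # depth exactly at the boundary is shelf (only > 200 m is basin)
  flat <- structure(list(lon = b$lon, lat = b$lat,
                         depth = matrix(200, length(b$lon), length(b$lat))),
                    class = "bathy_grid")
  expect_equal(assign_habitat(mk_trip_at(100), flat, sim$cfg$colony), "shelf")
  # outside the grid is unclassified with a reason
  off <- structure(list(lon = b$lon[1:2], lat = b$lat[1:2],
                        depth = b$depth[1:2, 1:2]), class = "bathy_grid")
  h <- assign_habitat(mk_trip_at(100), off, sim$cfg$colony)
  expect_true(is.na(h))
  expect_match(attr(h, "reason"), "outside")

  # over the full synthetic set, assignment equals planted truth (complete trips)
  pt <- process_trips(sim$tracks, sim$cfg$colony, b)
  tab <- pt$table[pt$table$complete, ]
  truth <- sim$truth$trips
  expect_equal(nrow(tab), nrow(truth))
  expect_equal(tab$habitat[order(tab$bird_id, tab$start)],
               truth$habitat[order(truth$bird_id, truth$start)])
})

test_that("preference scores match the worked example and are invariants", {
  df <- data.frame(bird_id = "B1", habitat = c("basin", "shelf", "shelf"))
  sc <- habitat_preference_scores(df)
  expect_equal(sc$basin_score, 0.33)
  expect_equal(sc$shelf_score, 0.67)
  expect_equal(habitat_preference_scores(
    data.frame(bird_id = "B", habitat = rep("shelf", 4)))$basin_score, 0)
  # trip order does not matter; fractions always sum to 1
  set.seed(8)
  big <- data.frame(bird_id = rep(sprintf("B%03d", 1:200), each = 4),
                    habitat = sample(c("shelf", "basin"), 800, replace = TRUE))
  s1 <- habitat_preference_scores(big)
  s2 <- habitat_preference_scores(big[sample(nrow(big)), ])
  expect_equal(s1, s2, ignore_attr = TRUE)
  expect_true(all(abs(s1$basin_fraction + s1$shelf_fraction - 1) < 1e-12))
  # a bird with no classified trips is excluded and counted
  withna <- rbind(big, data.frame(bird_id = "BX", habitat = NA))
  expect_equal(attr(habitat_preference_scores(withna), "excluded"), 1)
})

test_that("nearshore flag compares the furthest fix to the 3-km band", {
  shore <- list(lat = colony[1], lon = colony[2], radius_km = 5)
  near <- segment_trips(planted_track(7), colony)[[1]]   # 2 km offshore
  far <- segment_trips(planted_track(55), colony)[[1]]   # 50 km offshore
  expect_true(nearshore_flag(near, colony, shore))
  expect_false(nearshore_flag(far, colony, shore))
})
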