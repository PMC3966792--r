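# Shared small synthetic dataset, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(seed = 21, n_birds = 8)
    tr <- simulate_tracks(cfg)
    .sim_cache$small <- list(cfg = cfg, tracks = tr$tracks,
                             immersion = tr$immersion, truth = tr$truth,
                             bathy = simulate_bathymetry(cfg))
  }
  .sim_cache$small
}

# a deterministic hand-built single-bird track: colony dwell, one
# excursion to `dist_km` at `bearing`, colony dwell
planted_track <- function(dist_km, bearing = 240, colony = c(57.125, -170.285),
                          speed_kmh = 40, interval_s = 180,
                          t0 = as.POSIXct("2010-07-10 04:00:00", tz = "UTC"),
                          bird_id = "T1") {
  leg_s <- round(dist_km / speed_kmh * 3600 / interval_s) * interval_s
  tt <- seq(0, 2 * leg_s + 2 * 1800, by = interval_s)
  d <- pmax(0, pmin(pmin(tt - 1800, (2 * leg_s + 1800) - tt) / leg_s, 1)) * dist_km
  p <- destination_point(colony[1], colony[2], bearing, d)
  data.frame(bird_id = bird_id, t = t0 + tt, lat = p$lat, lon = p$lon)
}
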