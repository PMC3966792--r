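# Synthetic central-place foraging data with planted ground truth.
#
# The generator emulates the study system: birds commute from a colony on a
# shallow shelf (100-200 m) either to nearby shelf waters (trips averaging
# ~27 km) or far into the deep basin (> 200 m, trips of 120-465 km that stay
# out overnight). Immersion loggers alternate short wet/dry bouts while birds
# forage at the surface, run continuously wet while they rest on the water,
# and stay dry in flight. Sea-surface-height anomalies carry Gaussian-bump
# mesoscale eddies (anticyclonic positive, cyclonic negative) listed in a
# weekly trajectory table. Diets are drawn conditionally on the habitat of a
# bird's furthest trip. Every record is covered by a truth label.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by all `simulate_*`
#' functions. Defaults are the study conditions: a Pribilof-like colony
#' at 57.1N 170.3W, 46% of trips targeting the basin, shelf trips
#' averaging 27.2 km, basin trips averaging ~180 km (maximum 465 km)
#' with overnight stays, 180-s GPS fixes, and 3-s immersion sampling.
#'
#' @param seed integer RNG seed; fixed seed implies byte-identical
#'   output.
#' @param n_birds number of tracked birds.
#' @param colony `c(lat, lon)` of the colony.
#' @param colony_name,year labels stamped on generated samples.
#' @param p_basin probability a trip targets the basin.
#' @param shelf_km,basin_km `c(mean, sd, min, max)` of maximum trip
#'   distance (km) per habitat.
#' @param flight_speed_kmh commuting flight speed.
#' @param gps_interval_s GPS fix interval, seconds.
#' @param immersion_interval_s immersion sampling interval (1 or 3 s).
#' @param trips_per_bird `c(min, lambda)`: trips per bird are
#'   `min + rpois(lambda)`.
#' @param gap_p,gap_min probability that a trip's outbound transit has a
#'   recording gap, and the gap length in minutes.
#' @param shelf_break_km distance from the colony at which depth starts
#'   increasing beyond the shelf plateau.
#' @param slope_width_km width of the shelf break ramp.
#' @param shelf_depth_m,basin_depth_m plateau and abyssal depths.
#' @param grid_res_deg grid resolution for bathymetry and SSHA fields.
#' @param week0,n_weeks first weekly SSHA snapshot date and number of
#'   snapshots.
#' @param eddies optional data.frame of planted eddies (`eddy_id,
#'   center_lat, center_lon, radius_km, polarity, amplitude_cm,
#'   lifetime_weeks`); by default two anticyclones (21 and 17 cm) and
#'   one cyclone (9.7 cm) in the basin.
#' @param diet_probs named list `shelf`/`basin` of per-prey presence
#'   probabilities.
#' @param productivity list `n_plots`, `nests_range`, `success`.
#' @param cort list `n`, `mean_log10`, `sd_log10`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_birds = 20L,
                       colony = c(lat = 57.125, lon = -170.285),
                       colony_name = "COL1",
                       year = 2010L,
                       p_basin = 0.46,
                       shelf_km = c(mean = 27.2, sd = 9, min = 6, max = 60),
                       basin_km = c(mean = 180, sd = 40, min = 120, max = 465),
                       flight_speed_kmh = 40,
                       gps_interval_s = 180L,
                       immersion_interval_s = 3L,
                       trips_per_bird = c(min = 1, lambda = 1),
                       gap_p = 0.1,
                       gap_min = 45,
                       shelf_break_km = 80,
                       slope_width_km = 30,
                       shelf_depth_m = 150,
                       basin_depth_m = 3000,
                       grid_res_deg = 0.25,
                       week0 = as.Date("2010-07-01"),
                       n_weeks = 4L,
                       eddies = NULL,
                       diet_probs = list(
                         shelf = c(pollock = 0.50, sandlance = 0.35,
                                   offal = 0.45, euphausiid = 0.20,
                                   amphipod = 0.15),
                         basin = c(myctophid = 0.85, squid = 0.40,
                                   euphausiid = 0.30, amphipod = 0.20,
                                   offal = 0.15)),
                       productivity = list(n_plots = 10L,
                                           nests_range = c(6L, 15L),
                                           success = 0.5),
                       cort = list(n = 30L, mean_log10 = -0.05,
                                   sd_log10 = 0.25)) {
  stopifnot(p_basin >= 0, p_basin <= 1, n_birds >= 1,
            shelf_km["min"] > 0, basin_km["min"] > 0,
            immersion_interval_s %in% c(1L, 3L),
            seed == as.integer(seed), abs(seed) < 2^31 - 10)
  if (basin_km["min"] <= shelf_break_km) {
    stop("infeasible geometry: minimum basin trip distance must exceed the shelf-break distance",
         call. = FALSE)
  }
  if (shelf_km["max"] > shelf_break_km) {
    stop("infeasible geometry: shelf trips must stay inside the shelf break",
         call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_birds = as.integer(n_birds),
              colony = colony, colony_name = colony_name,
              year = as.integer(year),
              p_basin = p_basin, shelf_km = shelf_km, basin_km = basin_km,
              flight_speed_kmh = flight_speed_kmh,
              gps_interval_s = as.integer(gps_interval_s),
              immersion_interval_s = as.integer(immersion_interval_s),
              trips_per_bird = trips_per_bird,
              gap_p = gap_p, gap_min = gap_min,
              shelf_break_km = shelf_break_km,
              slope_width_km = slope_width_km,
              shelf_depth_m = shelf_depth_m, basin_depth_m = basin_depth_m,
              grid_res_deg = grid_res_deg,
              week0 = week0, n_weeks = as.integer(n_weeks),
              eddies = eddies, diet_probs = diet_probs,
              productivity = productivity, cort = cort)
  class(cfg) <- "sim_config"
  cfg
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  left <- seq_len(n)
  while (length(left)) {
    x <- stats::rnorm(length(left), mean, sd)
    ok <- x >= lo & x <= hi
    out[left[ok]] <- x[ok]
    left <- left[!ok]
  }
  out
}

# Next POSIXct after `t` whose local clock hour (UTC-11) equals `hour_local`.
next_local_hour <- function(t, hour_local, utc_offset = -11) {
  utc_hour <- (hour_local - utc_offset) %% 24
  day0 <- as.numeric(t) - as.numeric(t) %% 86400
  cand <- day0 + utc_hour * 3600
  while (cand <= as.numeric(t)) cand <- cand + 86400
  as.POSIXct(cand, origin = "1970-01-01", tz = "UTC")
}

#' Simulate a radial shelf/basin bathymetry
#'
#' Depth is a nondecreasing function of distance from the colony: a
#' shelf plateau (default 150 m) out to the shelf break, a linear ramp
#' across the slope, and a flat basin floor (default 3000 m). The grid
#' is sized to contain the longest configured trip.
#'
#' @param cfg a [sim_config()].
#' @return a `bathy_grid`.
#' @export
simulate_bathymetry <- function(cfg) {
  ext_km <- cfg$basin_km["max"] + 60
  dlat <- ext_km / 111.2
  dlon <- ext_km / (111.2 * cos(deg2rad(cfg$colony["lat"])))
  lat <- seq(cfg$colony["lat"] - dlat, cfg$colony["lat"] + dlat,
             by = cfg$grid_res_deg)
  lon <- seq(cfg$colony["lon"] - dlon, cfg$colony["lon"] + dlon,
             by = cfg$grid_res_deg)
  g <- expand.grid(lon = lon, lat = lat)
  d <- haversine_km(cfg$colony["lat"], cfg$colony["lon"], g$lat, g$lon)
  ramp <- pmin(pmax((d - cfg$shelf_break_km) / cfg$slope_width_km, 0), 1)
  depth <- cfg$shelf_depth_m + ramp * (cfg$basin_depth_m - cfg$shelf_depth_m)
  structure(list(lon = lon, lat = lat,
                 depth = matrix(depth, length(lon), length(lat))),
            class = "bathy_grid")
}

# Behavior segments for the at-destination phase of one trip, as a
# data.frame(behavior, dur_s). Basin trips get more bouts plus resting
# periods so the stay spans the night; shelf stays are shorter.
dest_schedule <- function(habitat) {
  segs <- list()
  if (habitat == "basin") {
    n_bouts <- sample(8:12, 1)
    n_rest <- sample(1:2, 1)
    rest_at <- sample(seq_len(n_bouts), n_rest)
  } else {
    n_bouts <- sample(3:6, 1)
    rest_at <- if (stats::runif(1) < 0.5) sample(seq_len(n_bouts), 1) else integer()
  }
  for (b in seq_len(n_bouts)) {
    segs[[length(segs) + 1]] <- c("forage", stats::runif(1, 600, 1800))
    if (b %in% rest_at) {
      segs[[length(segs) + 1]] <- c("rest", stats::runif(1, 1800, 3600))
    }
    if (b < n_bouts) {
      segs[[length(segs) + 1]] <- c("relocate", stats::runif(1, 120, 600))
    }
  }
  data.frame(behavior = vapply(segs, `[`, character(1), 1),
             dur_s = as.numeric(vapply(segs, `[`, character(1), 2)))
}

#' Simulate GPS tracks and immersion records with truth labels
#'
#' Each bird makes one or more trips from the colony. A trip is an
#' outbound commuting flight along a fixed bearing, a sequence of
#' foraging bouts (alternating 5-30 s wet / 10-120 s dry immersion),
#' resting bouts (continuous wet, 30-60 min) and short relocation
#' flights around the destination, and a return flight. Basin trips
#' depart in the local evening and stay out overnight; shelf trips are
#' daytime. Movement is simulated in an azimuthal-equidistant plane
#' around the colony and inverse-projected.
#'
#' @param cfg a [sim_config()].
#' @return list with `tracks` (GPS fixes), `immersion` (wet/dry
#'   records) and `truth` (list of `trips`, `segments`, `birds`
#'   data.frames labelling every generated record).
#' @export
simulate_tracks <- function(cfg) {
  set.seed(cfg$seed)
  deploy0 <- as.POSIXct(paste0(cfg$year, "-07-05 00:00:00"), tz = "UTC")
  v_ms <- cfg$flight_speed_kmh / 3.6

  all_fixes <- list(); all_imm <- list()
  truth_trips <- list(); truth_segs <- list()

  for (i in seq_len(cfg$n_birds)) {
    bird <- sprintf("B%03d", i)
    n_trips <- cfg$trips_per_bird["min"] + stats::rpois(1, cfg$trips_per_bird["lambda"])
    cur_t <- deploy0 + stats::runif(1, 0, 6 * 3600)
    segs <- list()  # x0,y0,x1,y1,t0,t1,behavior,trip
    add_seg <- function(x0, y0, x1, y1, t0, dur, behavior, trip) {
      segs[[length(segs) + 1]] <<- data.frame(
        x0 = x0, y0 = y0, x1 = x1, y1 = y1,
        t0 = as.numeric(t0), t1 = as.numeric(t0) + dur,
        behavior = behavior, trip = trip)
      as.numeric(t0) + dur
    }

    for (j in seq_len(n_trips)) {
      habitat <- if (stats::runif(1) < cfg$p_basin) "basin" else "shelf"
      par <- if (habitat == "basin") cfg$basin_km else cfg$shelf_km
      D <- rtruncnorm1(1, par["mean"], par["sd"], par["min"], par["max"])
      beta <- stats::runif(1, 0, 360)
      start_hour <- if (habitat == "basin") stats::runif(1, 16, 18) else stats::runif(1, 7, 11)
      t_start <- next_local_hour(cur_t + 3600, start_hour)
      # at-colony segment up to departure
      end <- add_seg(0, 0, 0, 0, cur_t, as.numeric(t_start) - as.numeric(cur_t),
                     "colony", NA)
      P <- c(D * sin(deg2rad(beta)), D * cos(deg2rad(beta)))
      transit_s <- D * 1000 / v_ms
      end <- add_seg(0, 0, P[1], P[2], end, transit_s, "flight", j)
      cur_xy <- P
      sched <- dest_schedule(habitat)
      for (k in seq_len(nrow(sched))) {
        beh <- sched$behavior[k]; dur <- sched$dur_s[k]
        if (beh == "relocate") {
          ang <- stats::runif(1, 0, 2 * pi); r <- sqrt(stats::runif(1)) * 6
          target <- P + r * c(cos(ang), sin(ang))
          dur <- max(60, sqrt(sum((target - cur_xy)^2)) * 1000 / v_ms)
          end <- add_seg(cur_xy[1], cur_xy[2], target[1], target[2], end, dur,
                         "flight", j)
          cur_xy <- target
        } else {
          drift <- cur_xy + stats::rnorm(2, 0, 0.15)
          end <- add_seg(cur_xy[1], cur_xy[2], drift[1], drift[2], end, dur,
                         beh, j)
          cur_xy <- drift
        }
      }
      Dback <- sqrt(sum(cur_xy^2))
      end <- add_seg(cur_xy[1], cur_xy[2], 0, 0, end, Dback * 1000 / v_ms,
                     "flight", j)
      cur_t <- as.POSIXct(end, origin = "1970-01-01", tz = "UTC")
      truth_trips[[length(truth_trips) + 1]] <- data.frame(
        bird_id = bird, trip_id = j,
        start = as.POSIXct(as.numeric(t_start), origin = "1970-01-01", tz = "UTC"),
        end = cur_t, habitat = habitat, distance_km = D, bearing = beta,
        dest_x = P[1], dest_y = P[2])
    }
    # trailing hour at the colony so the last trip is bracketed
    add_seg(0, 0, 0, 0, cur_t, 3600, "colony", NA)
    seg <- do.call(rbind, segs)

    # GPS fixes on the bird's full timeline
    ft <- seq(seg$t0[1], seg$t1[nrow(seg)], by = cfg$gps_interval_s)
    idx <- findInterval(ft, seg$t0)
    frac <- (ft - seg$t0[idx]) / pmax(seg$t1[idx] - seg$t0[idx], 1e-9)
    fx <- seg$x0[idx] + frac * (seg$x1[idx] - seg$x0[idx])
    fy <- seg$y0[idx] + frac * (seg$y1[idx] - seg$y0[idx])

    # recording gaps: drop fixes inside a window on an outbound transit
    for (j in seq_len(max(seg$trip, na.rm = TRUE))) {
      if (stats::runif(1) < cfg$gap_p) {
        out_seg <- seg[!is.na(seg$trip) & seg$trip == j & seg$behavior == "flight", ][1, ]
        span <- out_seg$t1 - out_seg$t0
        if (span > cfg$gap_min * 60 + 600) {
          g0 <- out_seg$t0 + stats::runif(1, 300, span - cfg$gap_min * 60 - 300)
          drop <- ft > g0 & ft < g0 + cfg$gap_min * 60
          ft <- ft[!drop]; fx <- fx[!drop]; fy <- fy[!drop]
        }
      }
    }
    ll <- aeqd_unproject(cbind(fx, fy), cfg$colony)
    all_fixes[[i]] <- data.frame(
      bird_id = bird,
      t = as.POSIXct(round(ft), origin = "1970-01-01", tz = "UTC"),
      lat = ll$lat, lon = ll$lon)

    # immersion samples during trips (colony periods excluded: birds dry
    # ashore and never analyzed there)
    on_trip <- seg[seg$behavior != "colony", , drop = FALSE]
    imm <- vector("list", nrow(on_trip))
    for (k in seq_len(nrow(on_trip))) {
      st <- ceiling(on_trip$t0[k]); en <- floor(on_trip$t1[k])
      if (en <= st) next
      tt <- seq(st, en, by = cfg$immersion_interval_s)
      beh <- on_trip$behavior[k]
      if (beh == "flight") {
        state <- rep("dry", length(tt))
      } else if (beh == "rest") {
        state <- rep("wet", length(tt))
      } else {
        dur_total <- en - st
        n_cyc <- ceiling(dur_total / 15) + 2
        wet_d <- stats::runif(n_cyc, 5, 30)
        dry_d <- stats::runif(n_cyc, 10, 120)
        bounds <- cumsum(as.vector(rbind(wet_d, dry_d)))
        pos <- findInterval(tt - st, c(0, bounds))
        state <- ifelse(pos %% 2 == 1, "wet", "dry")
      }
      imm[[k]] <- data.frame(t = tt, state = state)
    }
    imm <- do.call(rbind, imm[!vapply(imm, is.null, logical(1))])
    all_imm[[i]] <- data.frame(
      bird_id = bird,
      t = as.POSIXct(imm$t, origin = "1970-01-01", tz = "UTC"),
      state = imm$state,
      sample_interval_s = cfg$immersion_interval_s)
    truth_segs[[i]] <- data.frame(
      bird_id = bird,
      start = as.POSIXct(seg$t0, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(seg$t1, origin = "1970-01-01", tz = "UTC"),
      behavior = seg$behavior, trip_id = seg$trip)
  }

  tracks <- do.call(rbind, all_fixes)
  immersion <- do.call(rbind, all_imm)
  trips <- do.call(rbind, truth_trips)
  dest_ll <- aeqd_unproject(cbind(trips$dest_x, trips$dest_y), cfg$colony)
  trips$dest_lat <- dest_ll$lat; trips$dest_lon <- dest_ll$lon
  birds <- do.call(rbind, lapply(split(trips, trips$bird_id), function(d) {
    data.frame(bird_id = d$bird_id[1], n_trips = nrow(d),
               basin_fraction = mean(d$habitat == "basin"))
  }))
  rownames(birds) <- NULL
  list(tracks = tracks, immersion = immersion,
       truth = list(trips = trips, segments = do.call(rbind, truth_segs),
                    birds = birds))
}

default_eddies <- function(cfg) {
  place <- function(bearing, dist) {
    p <- destination_point(cfg$colony["lat"], cfg$colony["lon"], bearing, dist)
    c(p$lat, p$lon)
  }
  e1 <- place(225, 230); e2 <- place(260, 170); e3 <- place(300, 150)
  data.frame(eddy_id = c("A1", "A2", "C1"),
             center_lat = c(e1[1], e2[1], e3[1]),
             center_lon = c(e1[2], e2[2], e3[2]),
             radius_km = c(50, 60, 45),
             polarity = c("anticyclonic", "anticyclonic", "cyclonic"),
             amplitude_cm = c(21, 17, 9.7),
             lifetime_weeks = c(20L, 20L, 18L))
}

#' Simulate weekly SSHA snapshots with planted Gaussian eddies
#'
#' Each eddy contributes an isotropic Gaussian bump in sea-surface
#' height anomaly, positive for anticyclones and negative for cyclones,
#' with e-folding scale equal to its radius, so the anomaly at the
#' center equals plus/minus the planted amplitude. Centers drift 3 km
#' west per week. The weekly eddy-trajectory table is returned
#' alongside the grid.
#'
#' @param cfg a [sim_config()].
#' @return list with `ssha` (an `ssha_grid`) and `eddies` (trajectory
#'   table, one row per eddy per week).
#' @export
simulate_ssha <- function(cfg) {
  set.seed(cfg$seed + 1L)
  base <- if (is.null(cfg$eddies)) default_eddies(cfg) else cfg$eddies
  ext_km <- cfg$basin_km["max"] + 60
  dlat <- ext_km / 111.2
  dlon <- ext_km / (111.2 * cos(deg2rad(cfg$colony["lat"])))
  lat <- seq(cfg$colony["lat"] - dlat, cfg$colony["lat"] + dlat,
             by = cfg$grid_res_deg)
  lon <- seq(cfg$colony["lon"] - dlon, cfg$colony["lon"] + dlon,
             by = cfg$grid_res_deg)
  weeks <- cfg$week0 + 7 * (seq_len(cfg$n_weeks) - 1)
  g <- expand.grid(lon = lon, lat = lat)
  eta <- array(0, c(length(lon), length(lat), length(weeks)))
  rows <- list()
  # pairwise overlap check: warn when planted bumps materially interact
  if (nrow(base) > 1) {
    for (a in seq_len(nrow(base) - 1)) for (b in (a + 1):nrow(base)) {
      dab <- haversine_km(base$center_lat[a], base$center_lon[a],
                          base$center_lat[b], base$center_lon[b])
      if (dab < base$radius_km[a] + base$radius_km[b]) {
        warning(sprintf("planted eddies %s and %s overlap (%.0f km apart)",
                        base$eddy_id[a], base$eddy_id[b], dab))
      }
    }
  }
  for (k in seq_along(weeks)) {
    drift_km <- 3 * (k - 1)
    for (e in seq_len(nrow(base))) {
      c_ll <- destination_point(base$center_lat[e], base$center_lon[e],
                                270, drift_km)
      d <- haversine_km(c_ll$lat, c_ll$lon, g$lat, g$lon)
      sgn <- if (base$polarity[e] == "anticyclonic") 1 else -1
      eta[, , k] <- eta[, , k] +
        matrix(sgn * base$amplitude_cm[e] * exp(-d^2 / (2 * base$radius_km[e]^2)),
               length(lon), length(lat))
      rows[[length(rows) + 1]] <- data.frame(
        eddy_id = base$eddy_id[e], week = weeks[k],
        center_lat = c_ll$lat, center_lon = c_ll$lon,
        radius_km = base$radius_km[e], polarity = base$polarity[e],
        amplitude_cm = base$amplitude_cm[e],
        lifetime_weeks = base$lifetime_weeks[e])
    }
  }
  list(ssha = structure(list(time = weeks, lon = lon, lat = lat, eta = eta),
                        class = "ssha_grid"),
       eddies = do.call(rbind, rows))
}

#' Simulate diet samples linked to tracked birds' habitats
#'
#' One sample per tracked bird; prey categories are drawn independently
#' with the presence probabilities configured for the habitat of the
#' bird's furthest trip (shelf prey for shelf birds, myctophids/squid
#' for basin birds). A sample with no prey is flagged empty.
#'
#' @param cfg a [sim_config()].
#' @param truth truth list from [simulate_tracks()].
#' @return diet-sample data.frame (see [read_diet_samples()]).
#' @export
simulate_diets <- function(cfg, truth) {
  set.seed(cfg$seed + 2L)
  trips <- truth$trips
  out <- lapply(split(trips, trips$bird_id), function(d) {
    hab <- d$habitat[which.max(d$distance_km)]
    pr <- cfg$diet_probs[[hab]]
    present <- names(pr)[stats::runif(length(pr)) < pr]
    data.frame(sample_id = paste0("S-", d$bird_id[1]),
               colony = cfg$colony_name, year = cfg$year,
               prey = paste(present, collapse = ";"),
               true_habitat = hab)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  res <- data.frame(sample_id = df$sample_id, colony = df$colony,
                    year = df$year)
  res$prey_present <- strsplit(df$prey, ";", fixed = TRUE)
  res$prey_present <- lapply(res$prey_present, function(p) p[nzchar(p)])
  res$empty <- lengths(res$prey_present) == 0
  res$true_habitat <- df$true_habitat
  res
}

#' Simulate productivity plots
#'
#' Nests per plot are uniform over the configured range; fledging nests
#' are binomial with the configured success probability.
#'
#' @param cfg a [sim_config()].
#' @export
simulate_productivity <- function(cfg) {
  set.seed(cfg$seed + 3L)
  p <- cfg$productivity
  chicks <- sample(p$nests_range[1]:p$nests_range[2], p$n_plots, replace = TRUE)
  data.frame(plot_id = sprintf("P%02d", seq_len(p$n_plots)),
             colony = cfg$colony_name, year = cfg$year,
             nests_with_chicks = chicks,
             nests_with_fledglings = stats::rbinom(p$n_plots, chicks, p$success))
}

#' Simulate baseline corticosterone samples
#'
#' Log10 concentrations are normal with the configured mean and SD
#' (i.e. concentrations are log-normal on the ng/mL scale).
#'
#' @param cfg a [sim_config()].
#' @export
simulate_cort <- function(cfg) {
  set.seed(cfg$seed + 4L)
  lg <- stats::rnorm(cfg$cort$n, cfg$cort$mean_log10, cfg$cort$sd_log10)
  data.frame(bird_id = sprintf("B%03d", seq_len(cfg$cort$n)),
             colony = cfg$colony_name, year = cfg$year,
             cort_ng_ml = 10^lg)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator under the configured seed and writes the
#' data_io CSV formats plus truth tables to `dir`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of written file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- simulate_tracks(cfg)
  ss <- simulate_ssha(cfg)
  diets <- simulate_diets(cfg, tr$truth)
  plots <- simulate_productivity(cfg)
  cort <- simulate_cort(cfg)
  bathy <- simulate_bathymetry(cfg)
  f <- function(x) file.path(dir, x)
  write_tracks(tr$tracks, f("tracks.csv"))
  write_immersion(tr$immersion, f("immersion.csv"))
  write_bathymetry(bathy, f("bathymetry.csv"))
  write_ssha(ss$ssha, f("ssha.csv"))
  write_eddy_table(ss$eddies, f("eddies.csv"))
  write_diet_samples(diets, f("diets.csv"))
  write_csv_base(plots, f("plots.csv"))
  cw <- cort; cw$cort_ng_ml <- sprintf("%.6f", cw$cort_ng_ml)
  write_csv_base(cw, f("cort.csv"))
  tt <- tr$truth$trips
  tt$start <- format_utc(tt$start); tt$end <- format_utc(tt$end)
  write_csv_base(tt, f("truth_trips.csv"))
  ts <- tr$truth$segments
  ts$start <- format_utc(ts$start); ts$end <- format_utc(ts$end)
  write_csv_base(ts, f("truth_segments.csv"))
  write_csv_base(tr$truth$birds, f("truth_birds.csv"))
  invisible(list(dir = dir,
                 files = list.files(dir, full.names = TRUE)))
}
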