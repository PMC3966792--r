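# Independent brute-force oracles used across tests. Each is written as a
# direct transcription of the rule, kept free of the vectorized package code
# paths it checks.

# foraging/resting/not_wet by explicit per-window lookup of neighbours
oracle_classify <- function(wf, threshold = 0.9) {
  n <- length(wf)
  out <- character(n)
  for (i in seq_len(n)) {
    high <- wf[i] >= threshold
    adj <- (i > 1 && wf[i - 1] >= threshold) || (i < n && wf[i + 1] >= threshold)
    out[i] <- if (high && adj) "resting" else if (wf[i] > 0) "foraging" else "not_wet"
  }
  out
}

# wet fraction by raw recount over immersion samples in [t-before, t+after]
oracle_wet_fraction <- function(imm, t, before_s = 480, after_s = 120) {
  sel <- as.numeric(imm$t) >= as.numeric(t) - before_s &
    as.numeric(imm$t) <= as.numeric(t) + after_s
  if (!any(sel)) return(NA_real_)
  mean(imm$state[sel] == "wet")
}

# solar elevation via the Michalsky (1988) almanac algorithm -- an
# independent derivation from the NOAA route used by the package
oracle_solar_elevation <- function(t, lat, lon) {
  n <- as.numeric(t) / 86400 + 2440587.5 - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * pi / 180) + 0.020 * sin(2 * g * pi / 180)
  eps <- 23.439 - 0.0000004 * n
  ra <- atan2(cos(eps * pi / 180) * sin(lam * pi / 180), cos(lam * pi / 180)) * 180 / pi
  dec <- asin(sin(eps * pi / 180) * sin(lam * pi / 180))
  hour_ut <- (as.numeric(t) %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * (n - hour_ut / 24) + 1.00273790935 * hour_ut) %% 24
  lmst <- (gmst * 15 + lon) %% 360
  ha <- ((lmst - ra + 540) %% 360) - 180
  el <- asin(sin(dec) * sin(lat * pi / 180) +
               cos(dec) * cos(lat * pi / 180) * cos(ha * pi / 180))
  el * 180 / pi
}

# signed distance/category per (location, week, eddy) by full enumeration
oracle_match <- function(loc, eddies, near_km = 20, outer_km = 200,
                         max_offset_days = 7) {
  best <- NULL
  for (w in unique(eddies$week)) {
    off <- abs(as.numeric(as.Date(loc$t)) - as.numeric(as.Date(w)))
    if (is.null(best) || off < best$off) best <- list(week = w, off = off)
  }
  if (best$off > max_offset_days) return(NULL)
  ew <- eddies[eddies$week == best$week, ]
  sd_km <- sapply(seq_len(nrow(ew)), function(j)
    eddyforage::haversine_km(loc$lat, loc$lon, ew$center_lat[j], ew$center_lon[j]) -
      ew$radius_km[j])
  j <- which.min(abs(sd_km))
  cat_ <- if (sd_km[j] < 0) "inside" else if (sd_km[j] < near_km) "near"
    else if (sd_km[j] <= outer_km) "outside" else NA_character_
  list(eddy_id = ew$eddy_id[j], signed = sd_km[j], category = cat_)
}
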