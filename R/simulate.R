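# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a well-separated child seed from a scenario seed, kept below 2^31.
derive_seed <- function(seed, k) (seed * 1103515245 + 12345 * k) %% 2147483647

#' The study's home aviary and release-site geometry
#'
#' The home aviary sits on the Tuscan coast (43.6571 N, 10.3041 E, 1.8 km
#' east of the Tyrrhenian Sea); the three release sites are reconstructed
#' from their published bearing/distance to home: site 1 at 241 deg / 59.9 km
#' to home, site 2 at 309 deg / 50.5 km, site 3 at 270 deg / 61.0 km (so the
#' sites lie 61, 129 and 90 deg from home, 50-61 km inland).
#'
#' @return A tibble with columns `site`, `release_lat`, `release_lon`,
#'   `home_lat`, `home_lon`, `bearing_to_home`, `distance_km`.
#' @export
arnino_sites <- function() {
  home_lat <- 43.65714
  home_lon <- 10.30408
  bearing_to_home <- c(241, 309, 270)
  distance_km <- c(59.9, 50.5, 61.0)
  rel <- destination_point(home_lat, home_lon, wrap360(bearing_to_home - 180),
                           distance_km)
  tibble::tibble(
    site = 1:3,
    release_lat = rel$lat, release_lon = rel$lon,
    home_lat = home_lat, home_lon = home_lon,
    bearing_to_home = bearing_to_home, distance_km = distance_km
  )
}

#' Simulate a coastal sea-breeze meteorology series
#'
#' One-minute records reproducing the statistical structure of a
#' Mediterranean sea-breeze system: wind from inland (von Mises around
#' `offshore_dir`, default 150 deg) outside the onshore window, and from the
#' sea (around `onshore_dir`, default 270 deg) between `onshore_from` and
#' `onshore_to` local hours (default 12:00-20:00); temperature and relative
#' humidity as anti-phased diel sinusoids inside 12-25 C and 60-85 %.
#'
#' @param days Number of simulated days (>= 1).
#' @param seed Integer seed; identical seeds give identical series.
#' @param start Local date-time of the first record.
#' @param offshore_dir,onshore_dir Mean wind directions, degrees
#'   (coming-from).
#' @param onshore_from,onshore_to Onshore window, local hours.
#' @param kappa_dir Von Mises concentration of wind-direction noise.
#' @param ws_mean_ms Mean wind speed, m/s (afternoons run ~50 % brisker).
#' @return A tibble: `time`, `temp_c`, `rh_pct`, `ws_ms`, `wd_deg`,
#'   `rain_mm`.
#' @export
gen_sea_breeze_met <- function(days = 7, seed = 1,
                               start = as.POSIXct("2018-05-15 00:00:00", tz = "UTC"),
                               offshore_dir = 150, onshore_dir = 270,
                               onshore_from = 12, onshore_to = 20,
                               kappa_dir = 8, ws_mean_ms = 2.2) {
  if (days < 1) abort("`days` must be >= 1")
  if (onshore_to <= onshore_from) abort("invalid onshore window")
  with_seed(seed, {
    n <- days * 1440L
    time <- start + (seq_len(n) - 1L) * 60
    h <- (as.numeric(time - start) / 3600) %% 24
    onshore <- h >= onshore_from & h < onshore_to
    mu <- ifelse(onshore, onshore_dir, offshore_dir)
    wd <- wrap360(mu + rvonmises_deg(n, 0, kappa_dir))
    ws <- rlnorm(n, meanlog = log(ws_mean_ms) + ifelse(onshore, 0.4, 0), sdlog = 0.3)
    temp <- 18.5 + 6.5 * cos(2 * pi * (h - 15) / 24) + rnorm(n, 0, 0.4)
    rh <- 72.5 - 12.5 * cos(2 * pi * (h - 15) / 24) + rnorm(n, 0, 1.5)
    tibble::tibble(
      time = time,
      temp_c = pmin(pmax(temp, 12), 25),
      rh_pct = pmin(pmax(rh, 60), 85),
      ws_ms = ws,
      wd_deg = wd,
      rain_mm = 0
    )
  })
}

#' Default direction-dependent VOC source table
#'
#' Sources emulating the study region: marine DMS advected from the west,
#' monoterpenes from the vegetated inland with nocturnal accumulation,
#' daytime isoprene from the north-east, and anthropogenic xylenes from the
#' south-east.
#'
#' @return A tibble: `species`, `baseline` (ppbv), `gain` (ppbv),
#'   `source_dir` (deg), `kappa`, `diel`
#'   (`"flat"`, `"daytime"`, `"nocturnal"`), `noise_sdlog`.
#' @export
default_voc_sources <- function() {
  tibble::tibble(
    species = c("DMS m/z 63", "isoprene m/z 69", "monoterpenes m/z 81",
                "xylenes m/z 107"),
    baseline = c(0.02, 0.10, 0.20, 0.05),
    gain = c(0.20, 0.60, 1.40, 0.25),
    source_dir = c(270, 60, 120, 135),
    kappa = c(2, 1.5, 1.5, 2),
    diel = c("flat", "daytime", "nocturnal", "flat"),
    noise_sdlog = c(0.4, 0.4, 0.4, 0.4)
  )
}

diel_emission_factor <- function(diel, hour) {
  switch(diel,
    flat = rep(1, length(hour)),
    daytime = pmax(0, sin(pi * (hour - 6) / 12)),
    nocturnal = ifelse(hour < 6 | hour >= 21, 1.5, 0.3),
    abort(sprintf("unknown diel pattern '%s'", diel))
  )
}

#' Simulate VOC mixing-ratio series from meteorology
#'
#' Each species' mixing ratio is baseline + directional source gain (a von
#' Mises kernel on the wind direction, peaked at the species' source sector)
#' times a diel emission factor, plus multiplicative lognormal measurement
#' noise. Generated series inherit the meteorology's timestamps.
#'
#' @param met Meteorology series (see [gen_sea_breeze_met()]).
#' @param sources Source table (see [default_voc_sources()]).
#' @param seed Integer seed.
#' @return A tibble: `species`, `time`, `vmr` (ppbv).
#' @export
gen_voc_series <- function(met, sources = default_voc_sources(), seed = 1) {
  stopifnot(all(c("time", "wd_deg") %in% names(met)))
  required <- c("species", "baseline", "gain", "source_dir", "kappa", "diel",
                "noise_sdlog")
  if (!all(required %in% names(sources))) {
    abort("`sources` lacks required columns")
  }
  h <- as.numeric(format(met$time, "%H", tz = "UTC")) +
    as.numeric(format(met$time, "%M", tz = "UTC")) / 60
  with_seed(seed, {
    purrr::pmap_dfr(sources, function(species, baseline, gain, source_dir,
                                      kappa, diel, noise_sdlog) {
      kern <- exp(kappa * (cos(deg2rad(met$wd_deg - source_dir)) - 1))
      signal <- baseline + gain * kern * diel_emission_factor(diel, h)
      tibble::tibble(
        species = species,
        time = met$time,
        vmr = signal * rlnorm(nrow(met), -noise_sdlog^2 / 2, noise_sdlog)
      )
    })
  })
}

#' Simulate one homeward-biased pigeon flight
#'
#' Correlated random walk at one fix per `step_s` seconds: headings are von
#' Mises draws (concentration `kappa`) around a mean direction that blends
#' the instantaneous home azimuth with due west (270 deg) at weight
#' `westward_weight` -- the mechanism by which a weak DMS signal at the
#' release site pulls a bird's initial orientation west. Speeds are
#' lognormal around `speed_median_kmh`. The walk stops on home arrival
#' (within `home_radius_km`) or after `max_duration_min` minutes.
#'
#' @param release_lat,release_lon,home_lat,home_lon Coordinates, degrees.
#' @param westward_weight Blend weight in `[0, 1]`: 0 = pure homing,
#'   1 = pure westward flight.
#' @param kappa Heading concentration (default 2). `Inf` gives noiseless
#'   headings.
#' @param speed_median_kmh,speed_sdlog Lognormal flight-speed parameters
#'   (median 60 km/h).
#' @param step_s Fix interval, seconds (default 10, the logger rate).
#' @param max_duration_min Maximum simulated flight, minutes.
#' @param home_radius_km Arrival radius, km.
#' @param bird_id Track label.
#' @param release_time POSIXct of the first fix.
#' @param seed Integer seed (`NULL`: use the current RNG stream).
#' @return A fix tibble: `bird_id`, `time`, `lat`, `lon`, `speed_kmh`.
#' @export
gen_track <- function(release_lat, release_lon, home_lat, home_lon,
                      westward_weight = 0, kappa = 2,
                      speed_median_kmh = 60, speed_sdlog = 0.25,
                      step_s = 10, max_duration_min = 90, home_radius_km = 0.5,
                      bird_id = "bird1",
                      release_time = as.POSIXct("2016-07-15 09:00:00", tz = "UTC"),
                      seed = NULL) {
  if (westward_weight < 0 || westward_weight > 1) {
    abort("`westward_weight` must be in [0, 1]")
  }
  with_seed(seed, {
    n_max <- ceiling(max_duration_min * 60 / step_s)
    noise <- if (is.infinite(kappa)) rep(0, n_max) else {
      deg2rad(wrap180(rvonmises_deg(n_max, 0, kappa)))
    }
    speeds <- rlnorm(n_max, log(speed_median_kmh), speed_sdlog)
    lat <- numeric(n_max + 1L); lon <- numeric(n_max + 1L)
    lat[1] <- release_lat; lon[1] <- release_lon
    phi <- deg2rad(release_lat); lam <- deg2rad(release_lon)
    phiH <- deg2rad(home_lat); lamH <- deg2rad(home_lon)
    west <- deg2rad(270)
    w <- westward_weight
    arr_rad <- home_radius_km / EARTH_RADIUS_KM
    k <- 0L
    for (i in seq_len(n_max)) {
      dlam <- lamH - lam
      hb <- atan2(sin(dlam) * cos(phiH),
                  cos(phi) * sin(phiH) - sin(phi) * cos(phiH) * cos(dlam))
      mu <- atan2(w * sin(west) + (1 - w) * sin(hb),
                  w * cos(west) + (1 - w) * cos(hb))
      hd <- mu + noise[i]
      delta <- speeds[i] * step_s / 3600 / EARTH_RADIUS_KM
      phi2 <- asin(sin(phi) * cos(delta) + cos(phi) * sin(delta) * cos(hd))
      lam2 <- lam + atan2(sin(hd) * sin(delta) * cos(phi),
                          cos(delta) - sin(phi) * sin(phi2))
      phi <- phi2; lam <- lam2
      k <- i
      lat[i + 1L] <- rad2deg(phi); lon[i + 1L] <- rad2deg(lam)
      # great-circle distance to home via haversine, radians
      a <- sin((phiH - phi) / 2)^2 + cos(phi) * cos(phiH) * sin((lamH - lam) / 2)^2
      if (2 * asin(sqrt(a)) <= arr_rad) break
    }
    idx <- seq_len(k + 1L)
    tibble::new_tibble(list(
      bird_id = rep(bird_id, k + 1L),
      time = release_time + (idx - 1L) * step_s,
      lat = lat[idx],
      lon = wrap180(lon[idx]),
      speed_kmh = c(speeds[seq_len(k)], 0)
    ), nrow = k + 1L)
  })
}

#' Simulate a 24 h backward air-mass trajectory
#'
#' Hourly back-trajectory from a release site at the birds' flying altitude
#' (150 m): each hour steps upwind towards the prevailing source direction
#' with von Mises jitter, altitude wobbles around 150 m and the mixing-layer
#' depth follows a diel cycle (shallow at night). With a half-plane coastal
#' mask the sea/land residence of the result is analytically checkable.
#'
#' @param site_lat,site_lon Release-site coordinates.
#' @param start_time POSIXct release time (trajectory runs 24 h backward).
#' @param prevailing_dir Direction the air comes from, compass degrees.
#' @param speed_ms Mean transport speed, m/s (default 8, a typical
#'   synoptic flow at 150 m).
#' @param kappa_dir Jitter concentration of the hourly upwind bearing.
#' @param altitude_m Mean transport altitude (default 150 m).
#' @param traj_id Integer trajectory id.
#' @param seed Integer seed (`NULL`: current stream).
#' @return A trajectory tibble in the [read_hysplit()] layout (25 hourly
#'   points, offsets 0 .. -24).
#' @export
gen_trajectory <- function(site_lat, site_lon, start_time, prevailing_dir,
                           speed_ms = 8, kappa_dir = 20, altitude_m = 150,
                           traj_id = 1L, seed = NULL) {
  with_seed(seed, {
    n <- 24L
    bear <- rvonmises_deg(n, prevailing_dir, kappa_dir)
    step_km <- speed_ms * 3.6 * stats::rlnorm(n, -0.02, 0.2)
    lat <- numeric(n + 1L); lon <- numeric(n + 1L)
    lat[1] <- site_lat; lon[1] <- site_lon
    phi <- deg2rad(site_lat); lam <- deg2rad(site_lon)
    for (i in seq_len(n)) {
      hd <- deg2rad(bear[i])
      delta <- step_km[i] / EARTH_RADIUS_KM
      phi2 <- asin(sin(phi) * cos(delta) + cos(phi) * sin(delta) * cos(hd))
      lam <- lam + atan2(sin(hd) * sin(delta) * cos(phi),
                         cos(delta) - sin(phi) * sin(phi2))
      phi <- phi2
      lat[i + 1L] <- rad2deg(phi); lon[i + 1L] <- wrap180(rad2deg(lam))
    }
    offs <- 0:(-n)
    hour_local <- (as.numeric(format(start_time, "%H", tz = "UTC")) + offs) %% 24
    day <- hour_local >= 8 & hour_local < 20
    mixdepth <- ifelse(day, 800, 300) * rlnorm(n + 1L, 0, 0.1)
    tibble::new_tibble(list(
      traj_id = rep(as.integer(traj_id), n + 1L),
      direction = rep("backward", n + 1L),
      start_time = rep(start_time, n + 1L),
      hour_offset = offs,
      lat = lat,
      lon = lon,
      height_m = pmax(altitude_m + rnorm(n + 1L, 0, 15), 0),
      mixdepth_m = pmax(mixdepth, 50)
    ), nrow = n + 1L)
  })
}

#' Simulate a 16 x 6 wind profile
#'
#' Draws `n` wind records with von Mises directions around `dominant_dir`
#' and speeds from a categorical mix over the 6 speed classes, then bins
#' them with [build_wind_profile()].
#'
#' @param dominant_dir Dominant coming-from direction, compass degrees.
#' @param concentration Von Mises concentration of directions.
#' @param speed_mix Probabilities over the 6 speed classes (normalised
#'   internally).
#' @param n Number of simulated records.
#' @param seed Integer seed.
#' @inheritParams build_wind_profile
#' @return An `olf_wind_profile` tibble.
#' @export
gen_wind_profile <- function(dominant_dir = 270, concentration = 2,
                             speed_mix = c(1, 2, 3, 2, 1, 1), n = 2000,
                             seed = 1, speed_edges = c(0, 1, 2, 4, 6, 8, Inf),
                             s_values = "ordinal") {
  with_seed(seed, {
    speed_mix <- speed_mix / sum(speed_mix)
    wd <- rvonmises_deg(n, dominant_dir, concentration)
    cls <- sample.int(6, n, replace = TRUE, prob = speed_mix)
    lo <- speed_edges[cls]
    hi <- ifelse(is.finite(speed_edges[cls + 1]), speed_edges[cls + 1],
                 speed_edges[cls] + 2)
    ws <- runif(n, lo, hi)
    build_wind_profile(tibble::tibble(wd_deg = wd, ws_ms = ws),
                       speed_edges = speed_edges, s_values = s_values)
  })
}

#' Simulate a release cohort with air-mass-coupled westward bias
#'
#' Generates `n_birds` released from the three study sites. Each bird gets a
#' backward air-mass trajectory drawn from the regional ensemble (prevailing
#' direction uniform, origin at the release-region centroid: at synoptic
#' transport speeds a 24 h trajectory spans hundreds of km, so the air-mass
#' history is common to sites lying within 60 km of each other, and the
#' covariate is by construction independent of which site a bird flies
#' from). Its sea/land boundary-layer residence against the half-plane
#' coastal mask yields the bird's sea:land ratio. The bird's westward blend
#' weight is `bias_coef * (1 - sea_fraction)`, clamped to `[0, 1]`: air that
#' spent little time over sea carries little DMS, and such birds are pulled
#' west, as the olfactory-map reasoning predicts. `bias_coef = 0` gives a
#' null cohort of pure homers whose orientation is exchangeable with respect
#' to the covariate.
#'
#' @param n_birds Cohort size (default 100).
#' @param seed Integer scenario seed; all child streams derive from it.
#' @param bias_coef Coupling strength between (1 - sea fraction) and the
#'   westward weight (default 1).
#' @param sites Release-site table (default [arnino_sites()]).
#' @param coast_lon Half-plane coastline longitude (default 10.282, the sea
#'   1.8 km west of the aviary).
#' @param traj_speed_ms Air-mass transport speed, m/s (default 8).
#' @param max_duration_min Simulated flight duration per bird, minutes. The
#'   default 15 covers the 10 km initial-orientation window at typical
#'   flight speed.
#' @inheritParams gen_track
#' @return A list with tibbles `tracks`, `sites` (per bird), `residence`
#'   (per bird, keyed by `bird_id`) and `truth` (the constructed
#'   `sea_fraction` and `westward_weight` per bird).
#' @export
simulate_cohort <- function(n_birds = 100, seed = 1, bias_coef = 1,
                            sites = arnino_sites(), coast_lon = 10.282,
                            traj_speed_ms = 8, max_duration_min = 15,
                            kappa = 2, speed_median_kmh = 60, step_s = 10) {
  mask <- halfplane_mask(coast_lon)
  release_time <- as.POSIXct("2016-07-15 09:00:00", tz = "UTC")
  ids <- sprintf("bird%03d", seq_len(n_birds))
  site_rows <- (seq_len(n_birds) - 1L) %% nrow(sites) + 1L
  origin_lat <- mean(sites$release_lat)
  origin_lon <- mean(sites$release_lon)
  prevailing <- with_seed(derive_seed(seed, 1L), runif(n_birds, 0, 360))
  traj_all <- purrr::map_dfr(seq_len(n_birds), function(i) {
    gen_trajectory(origin_lat, origin_lon, release_time,
                   prevailing_dir = prevailing[i], speed_ms = traj_speed_ms,
                   traj_id = i, seed = derive_seed(seed, 2L * i))
  })
  res <- classify_trajectories(traj_all, mask)
  res <- res[match(seq_len(n_birds), res$traj_id), ]
  bl <- res$hours_sea_bl + res$hours_land_bl
  sea_frac <- ifelse(bl > 0, res$hours_sea_bl / bl, 0.5)
  w <- pmin(1, pmax(0, bias_coef * (1 - sea_frac)))
  tracks <- purrr::map_dfr(seq_len(n_birds), function(i) {
    st <- sites[site_rows[i], ]
    gen_track(st$release_lat, st$release_lon, st$home_lat, st$home_lon,
              westward_weight = w[i], kappa = kappa,
              speed_median_kmh = speed_median_kmh, step_s = step_s,
              max_duration_min = max_duration_min,
              bird_id = ids[i], release_time = release_time,
              seed = derive_seed(seed, 2L * i + 1L))
  })
  list(
    tracks = tracks,
    sites = tibble::tibble(
      bird_id = ids, site = sites$site[site_rows],
      release_lat = sites$release_lat[site_rows],
      release_lon = sites$release_lon[site_rows],
      home_lat = sites$home_lat[site_rows],
      home_lon = sites$home_lon[site_rows],
      release_time = release_time
    ),
    residence = dplyr::bind_cols(tibble::tibble(bird_id = ids),
                                 dplyr::select(res, -"traj_id")),
    truth = tibble::tibble(bird_id = ids, sea_fraction = sea_frac,
                           westward_weight = w)
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Chains cohort simulation, per-bird homing indices, trajectory residence
#' classification and the orientation association: the end-to-end re-creation
#' of the deviation-from-west vs sea:land-ratio analysis on synthetic birds.
#'
#' @inheritParams simulate_cohort
#' @param index_col,covariate_col Columns passed to
#'   [orientation_association()].
#' @return A list: `cohort` (the simulated inputs), `indices` (per-bird
#'   tibble), `association` (an `olf_assoc`) and `config` (the scenario
#'   parameters used).
#' @export
run_pipeline <- function(n_birds = 100, seed = 1, bias_coef = 1,
                         index_col = "dev_west_abs",
                         covariate_col = "ratio_sea_land", ...) {
  cohort <- simulate_cohort(n_birds = n_birds, seed = seed,
                            bias_coef = bias_coef, ...)
  indices <- compute_indices(cohort$tracks, cohort$sites)
  assoc <- orientation_association(indices, cohort$residence,
                                   index_col = index_col,
                                   covariate_col = covariate_col)
  list(
    cohort = cohort,
    indices = indices,
    association = assoc,
    config = list(n_birds = n_birds, seed = seed, bias_coef = bias_coef,
                  index_col = index_col, covariate_col = covariate_col)
  )
}
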