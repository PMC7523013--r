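#' Per-step summary of GPS tracks
#'
#' Breaks each bird's fix sequence into consecutive steps: heading, length,
#' duration and speed per fix pair. When the logger did not report a speed,
#' the step speed is length/duration. Zero-length steps (duplicate positions,
#' e.g. a bird at rest) are kept but carry an `NA` heading and are excluded
#' from heading statistics downstream.
#'
#' @param tracks A data frame with columns `bird_id`, `time` (POSIXct),
#'   `lat`, `lon` and optionally `speed_kmh` (logger-reported).
#' @return A tibble, one row per step, with columns `bird_id`, `t0`, `t1`,
#'   `lat0`, `lon0`, `lat1`, `lon1`, `heading_deg`, `length_km`,
#'   `duration_s`, `speed_kmh`.
#' @export
#' @examples
#' trk <- tibble::tibble(
#'   bird_id = "b1",
#'   time = as.POSIXct("2016-07-15 09:00", tz = "UTC") + c(0, 360),
#'   lat = c(43.0, 43.009), lon = 10.3
#' )
#' track_steps(trk)
track_steps <- function(tracks) {
  stopifnot(all(c("bird_id", "time", "lat", "lon") %in% names(tracks)))
  has_speed <- "speed_kmh" %in% names(tracks) && !anyNA(tracks$speed_kmh)
  df <- dplyr::arrange(tracks, .data$bird_id, .data$time)
  n <- nrow(df)
  same <- df$bird_id[-n] == df$bird_id[-1]
  counts <- table(df$bird_id)
  if (any(counts < 2L)) {
    abort(sprintf("track '%s' needs at least 2 fixes",
                  names(counts)[which(counts < 2L)[1]]))
  }
  i0 <- which(same); i1 <- i0 + 1L
  dur <- as.numeric(df$time[i1]) - as.numeric(df$time[i0])
  if (any(dur <= 0)) {
    abort(sprintf("track '%s' has non-increasing timestamps",
                  df$bird_id[i0[which(dur <= 0)[1]]]))
  }
  len <- haversine_km(df$lat[i0], df$lon[i0], df$lat[i1], df$lon[i1])
  tibble::tibble(
    bird_id = df$bird_id[i0],
    t0 = df$time[i0], t1 = df$time[i1],
    lat0 = df$lat[i0], lon0 = df$lon[i0],
    lat1 = df$lat[i1], lon1 = df$lon[i1],
    heading_deg = initial_bearing(df$lat[i0], df$lon[i0], df$lat[i1], df$lon[i1]),
    length_km = len, duration_s = dur,
    speed_kmh = if (has_speed) df$speed_kmh[i0] else len / dur * 3600
  )
}

#' Initial orientation mean vector of one track
#'
#' Circular mean of step headings over the initial part of the flight: all
#' steps whose start fix lies within `radius_km` (great circle) of the
#' release site. Birds whose mean vector length r falls below 0.1 did not
#' orient consistently and are excluded from association analyses.
#'
#' @param steps Step table for a single bird (see [track_steps()]).
#' @param release_lat,release_lon Release-site coordinates.
#' @param radius_km Radius of the initial track portion, km (default 10).
#' @return A list as returned by [circular_mean()].
#' @export
initial_orientation <- function(steps, release_lat, release_lon, radius_km = 10) {
  d <- haversine_km(steps$lat0, steps$lon0, release_lat, release_lon)
  h <- steps$heading_deg[d <= radius_km & !is.na(steps$heading_deg)]
  if (length(h) == 0L) abort("no steps start within `radius_km` of the release site")
  circular_mean(h)
}

# Index of the truncation fix for the HEI window: the fix where cumulative
# active-flight time (steps faster than the threshold) reaches the window, or
# the first fix within home_radius_km of home, whichever comes first. Falls
# back to the last recorded fix for birds lost early.
hei_truncation_index <- function(steps, home_lat, home_lon,
                                 active_minutes = 50, speed_threshold_kmh = 10,
                                 home_radius_km = 0.5) {
  n <- nrow(steps)
  dist_home <- haversine_km(steps$lat1, steps$lon1, home_lat, home_lon)
  active <- steps$speed_kmh > speed_threshold_kmh
  cum_active <- cumsum(ifelse(active, steps$duration_s, 0))
  k_time <- which(cum_active >= active_minutes * 60)[1]
  k_home <- which(dist_home <= home_radius_km)[1]
  min(k_time, k_home, n, na.rm = TRUE)
}

#' Homing Efficiency Index (HEI)
#'
#' HEI = (a/l) * (b - c)/b, where a is the beeline from the release site to
#' the last considered fix, l the path length to that fix, b the beeline from
#' release site to home and c the beeline from the last considered fix to
#' home. The track is truncated at the fix corresponding to `active_minutes`
#' of active flight (steps with speed above `speed_threshold_kmh`), or
#' earlier if the bird reaches home (within `home_radius_km`). All steps up
#' to the truncation fix contribute to l; only the active ones advance the
#' clock. HEI is 1 for a straight flight home and negative for a bird ending
#' farther from home than the release site.
#'
#' @inheritParams initial_orientation
#' @param home_lat,home_lon Home (aviary) coordinates.
#' @param active_minutes Active-flight window, minutes (default 50).
#' @param speed_threshold_kmh Active-flight speed threshold, km/h (default 10).
#' @param home_radius_km Radius defining home arrival, km (default 0.5).
#' @return A list with `hei`, the components `a_km`, `l_km`, `b_km`, `c_km`,
#'   and `trunc_index` (step index of the truncation fix).
#' @export
homing_efficiency_index <- function(steps, release_lat, release_lon,
                                    home_lat, home_lon,
                                    active_minutes = 50, speed_threshold_kmh = 10,
                                    home_radius_km = 0.5) {
  b <- haversine_km(release_lat, release_lon, home_lat, home_lon)
  if (b <= 0) abort("release site and home coincide: b = 0")
  k <- hei_truncation_index(steps, home_lat, home_lon,
                            active_minutes, speed_threshold_kmh, home_radius_km)
  l <- sum(steps$length_km[seq_len(k)])
  if (l <= 0) abort("zero track length up to the truncation fix")
  a <- haversine_km(release_lat, release_lon, steps$lat1[k], steps$lon1[k])
  cc <- haversine_km(steps$lat1[k], steps$lon1[k], home_lat, home_lon)
  list(hei = (a / l) * (b - cc) / b, a_km = a, l_km = l, b_km = b, c_km = cc,
       trunc_index = k)
}

#' Mean Aggregate Azimuth Penalty (MAAP)
#'
#' The flight is downsampled to regular intervals (one hour by default): at
#' each interval boundary the fix nearest in time (within `tol_min`) is
#' taken. For each consecutive pair of sampled fixes the required azimuth A
#' (bearing from the fix to home) is compared with the observed azimuth (the
#' displacement bearing to the next sampled fix); MAAP is the mean absolute
#' difference, in degrees in `[0, 180]`. Boundaries with no fix nearby
#' (signal loss) are skipped rather than penalised.
#'
#' @param fixes A single bird's fixes: data frame with `time`, `lat`, `lon`.
#' @inheritParams homing_efficiency_index
#' @param interval_h Sampling interval in hours (default 1).
#' @param tol_min Half-width of the matching window around each boundary,
#'   minutes (default 5).
#' @return MAAP in degrees.
#' @export
mean_aggregate_azimuth_penalty <- function(fixes, home_lat, home_lon,
                                           interval_h = 1, tol_min = 5) {
  t0 <- fixes$time[1]
  span_s <- as.numeric(difftime(fixes$time[nrow(fixes)], t0, units = "secs"))
  bounds <- seq(0, span_s, by = interval_h * 3600)
  rel <- as.numeric(difftime(fixes$time, t0, units = "secs"))
  idx <- vapply(bounds, function(b) {
    j <- which.min(abs(rel - b))
    if (abs(rel[j] - b) <= tol_min * 60) j else NA_integer_
  }, integer(1))
  idx <- idx[!is.na(idx)]
  idx <- idx[!duplicated(idx)]
  if (length(idx) < 2L) abort("fewer than 2 sampled fixes: track too short for MAAP")
  i0 <- idx[-length(idx)]; i1 <- idx[-1]
  A <- initial_bearing(fixes$lat[i0], fixes$lon[i0], home_lat, home_lon)
  obs <- initial_bearing(fixes$lat[i0], fixes$lon[i0], fixes$lat[i1], fixes$lon[i1])
  keep <- !is.na(A) & !is.na(obs)
  if (!any(keep)) abort("no valid azimuth pairs for MAAP")
  mean(angular_difference(A[keep], obs[keep], signed = FALSE))
}

#' Per-bird homing indices
#'
#' Computes, for every bird in `tracks`, the full set of homing indices:
#' initial mean vector (direction and r), the consistency flag (r >= 0.1),
#' deviation from west (signed in `(-180, 180]` and absolute), HEI, MAAP and
#' the endpoint distance (home to last recorded fix). Birds whose track is
#' too short for an index carry `NA` there rather than failing the batch.
#'
#' @param tracks Fix table for one or more birds (see [track_steps()]).
#' @param sites A data frame keyed by `bird_id` with columns `release_lat`,
#'   `release_lon`, `home_lat`, `home_lon`.
#' @param radius_km Initial-orientation radius, km (default 10).
#' @inheritParams homing_efficiency_index
#' @param maap_interval_h,maap_tol_min MAAP downsampling interval (h) and
#'   matching tolerance (min).
#' @return A tibble with one row per bird: `bird_id`, `n_fixes`, `mean_dir`,
#'   `r`, `consistent`, `dev_west`, `dev_west_abs`, `hei`, `maap`,
#'   `endpoint_km`, `track_length_km`.
#' @export
compute_indices <- function(tracks, sites, radius_km = 10,
                            active_minutes = 50, speed_threshold_kmh = 10,
                            home_radius_km = 0.5,
                            maap_interval_h = 1, maap_tol_min = 5) {
  stopifnot(all(c("bird_id", "release_lat", "release_lon", "home_lat", "home_lon") %in% names(sites)))
  steps_all <- track_steps(tracks)
  fixes_by <- split(tracks[c("time", "lat", "lon")], tracks$bird_id)
  steps_by <- split(steps_all, steps_all$bird_id)
  purrr::map_dfr(unique(tracks$bird_id), function(id) {
    fixes <- fixes_by[[id]]
    fixes <- fixes[order(fixes$time), ]
    steps <- steps_by[[id]]
    site <- sites[match(id, sites$bird_id), ]
    if (is.na(site$release_lat[1])) abort(sprintf("no site row for bird '%s'", id))
    mv <- tryCatch(
      initial_orientation(steps, site$release_lat, site$release_lon, radius_km),
      error = function(e) list(direction = NA_real_, r = NA_real_, n = 0L)
    )
    hei <- tryCatch(
      homing_efficiency_index(steps, site$release_lat, site$release_lon,
                              site$home_lat, site$home_lon,
                              active_minutes, speed_threshold_kmh, home_radius_km)$hei,
      error = function(e) NA_real_
    )
    span_h <- as.numeric(difftime(fixes$time[nrow(fixes)], fixes$time[1],
                                  units = "hours"))
    maap <- if (span_h < maap_interval_h) NA_real_ else tryCatch(
      mean_aggregate_azimuth_penalty(fixes, site$home_lat, site$home_lon,
                                     maap_interval_h, maap_tol_min),
      error = function(e) NA_real_
    )
    last <- fixes[nrow(fixes), ]
    tibble::tibble(
      bird_id = id,
      n_fixes = nrow(fixes),
      mean_dir = mv$direction,
      r = mv$r,
      consistent = !is.na(mv$r) & mv$r >= 0.1,
      dev_west = angular_difference(mv$direction, 270, signed = TRUE),
      dev_west_abs = angular_difference(mv$direction, 270, signed = FALSE),
      hei = hei,
      maap = maap,
      endpoint_km = haversine_km(site$home_lat, site$home_lon, last$lat, last$lon),
      track_length_km = sum(steps$length_km)
    )
  })
}
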