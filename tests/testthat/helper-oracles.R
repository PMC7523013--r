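# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances via the spherical law of cosines,
# ranks by counting, grouped means by explicit loops.

# Great-circle distance via the spherical law of cosines (km).
slc_distance_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  cosc <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R * acos(pmin(pmax(cosc, -1), 1))
}

# Average ranks by counting smaller and equal elements.
counting_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Spearman rho as Pearson correlation of counting ranks, from the
# textbook covariance formula.
oracle_spearman <- function(x, y) {
  rx <- counting_ranks(x); ry <- counting_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Circular mean by explicit resultant-vector arithmetic.
oracle_circular_mean <- function(deg, w = rep(1, length(deg))) {
  th <- deg * pi / 180
  S <- sum(w * sin(th)); C <- sum(w * cos(th))
  r <- sqrt(S^2 + C^2) / sum(w)
  dir <- (atan2(S, C) * 180 / pi) %% 360
  list(direction = dir, r = r)
}

# A straight great-circle track of hourly fixes from release towards home.
straight_track <- function(release_lat, release_lon, home_lat, home_lon,
                           n_fix, step_km, step_s = 3600, bird_id = "s1",
                           t0 = as.POSIXct("2016-07-15 09:00:00", tz = "UTC")) {
  lat <- numeric(n_fix); lon <- numeric(n_fix)
  lat[1] <- release_lat; lon[1] <- release_lon
  for (i in seq_len(n_fix - 1)) {
    b <- initial_bearing(lat[i], lon[i], home_lat, home_lon)
    p <- destination_point(lat[i], lon[i], b, step_km)
    lat[i + 1] <- p$lat; lon[i + 1] <- p$lon
  }
  tibble::tibble(bird_id = bird_id, time = t0 + (seq_len(n_fix) - 1) * step_s,
                 lat = lat, lon = lon)
}

arnino_home <- c(lat = 43.65714, lon = 10.30408)

# A hand-built backward trajectory table: positions and boundary-layer
# status fully controlled by the caller.
manual_trajectory <- function(lons, lats = 43.5, height = 150, mixdepth = 800,
                              traj_id = 1L) {
  n <- length(lons)
  tibble::tibble(
    traj_id = traj_id,
    direction = "backward",
    start_time = as.POSIXct("2016-07-15 09:00:00", tz = "UTC"),
    hour_offset = 0:(-(n - 1)),
    lat = rep_len(lats, n),
    lon = lons,
    height_m = rep_len(height, n),
    mixdepth_m = rep_len(mixdepth, n)
  )
}
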