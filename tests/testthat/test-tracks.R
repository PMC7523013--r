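t0 <- as.POSIXct("2016-07-15 09:00:00", tz = "UTC")
home <- arnino_home

test_that("track steps report heading, length, duration and derived speed", {
  p <- destination_point(43.0, 10.3, 90, 1)
  trk <- tibble::tibble(bird_id = "b1", time = t0 + c(0, 360),
                        lat = c(43.0, p$lat), lon = c(10.3, p$lon))
  st <- track_steps(trk)
  expect_equal(nrow(st), 1L)
  expect_equal(st$length_km, 1, tolerance = 1e-9)
  expect_equal(st$duration_s, 360)
  expect_equal(st$speed_kmh, 10, tolerance = 1e-9)
  expect_equal(st$heading_deg, 90, tolerance = 1e-6)

  # a duplicate fix yields a zero-length step with undefined heading
  trk2 <- tibble::tibble(bird_id = "b1", time = t0 + c(0, 10, 20),
                         lat = c(43, 43, 43.01), lon = 10.3)
  st2 <- track_steps(trk2)
  expect_equal(st2$length_km[1], 0)
  expect_true(is.na(st2$heading_deg[1]))
  expect_false(is.na(st2$heading_deg[2]))

  expect_error(track_steps(tibble::tibble(bird_id = "b", time = t0,
                                          lat = 1, lon = 1)), "at least 2")
  expect_error(
    track_steps(tibble::tibble(bird_id = "b", time = t0 + c(0, 0),
                               lat = c(1, 2), lon = 1)),
    "non-increasing"
  )
})

test_that("step lengths re-sum to brute-force pairwise haversine totals", {
  set.seed(21)
  trk <- gen_track(43.9, 11.0, home["lat"], home["lon"], kappa = 2,
                   max_duration_min = 10, seed = 77)
  st <- track_steps(trk)
  brute <- sum(slc_distance_km(trk$lat[-nrow(trk)], trk$lon[-nrow(trk)],
                               trk$lat[-1], trk$lon[-1]))
  expect_equal(sum(st$length_km), brute, tolerance = 1e-6)
})

test_that("initial orientation recovers construction and applies the r < 0.1 rule", {
  east <- straight_track(43.5, 10.0, 43.5, 11.5, n_fix = 30, step_km = 0.5)
  st <- track_steps(east)
  mv <- initial_orientation(st, 43.5, 10.0)
  expect_equal(mv$direction, 90, tolerance = 0.5)
  expect_equal(mv$r, 1, tolerance = 1e-6)

  # alternating out-and-back headings cancel: r = 0, bird inconsistent
  lat <- 43.5 + c(0, 0.001, 0, 0.001, 0, 0.001, 0)
  zig <- tibble::tibble(bird_id = "z", time = t0 + seq(0, by = 10, length.out = 7),
                        lat = lat, lon = 10.0)
  mvz <- initial_orientation(track_steps(zig), 43.5, 10.0)
  expect_lt(mvz$r, 0.1)
  expect_true(is.na(mvz$direction))

  # von Mises headings around 270: parameter recovery within 10 degrees
  trk <- gen_track(43.66, 10.95, home["lat"], home["lon"], westward_weight = 1,
                   kappa = 2, max_duration_min = 12, seed = 303)
  mvw <- initial_orientation(track_steps(trk), 43.66, 10.95)
  expect_lt(angular_difference(mvw$direction, 270, signed = FALSE), 10)

  # enlarging the radius to cover everything equals the all-step circular mean
  stw <- track_steps(trk)
  all_steps <- circular_mean(stw$heading_deg[!is.na(stw$heading_deg)])
  wide <- initial_orientation(stw, 43.66, 10.95, radius_km = 1e6)
  expect_equal(wide$direction, all_steps$direction)
  expect_equal(wide$r, all_steps$r)

  expect_error(initial_orientation(stw, 0, 0, radius_km = 10), "no steps")
})

test_that("HEI reproduces its closed forms", {
  # straight flight release -> home: a = l = b, c = 0, HEI = 1
  rel <- destination_point(home["lat"], home["lon"], 61, 59.9)
  n <- 61
  # 1 km steps every 30 s (~120 km/h): home is reached well inside the
  # 50 min active-flight window, so the truncation fix is the home fix
  trk <- straight_track(rel$lat, rel$lon, home["lat"], home["lon"],
                        n_fix = n, step_km = 59.9 / (n - 1), step_s = 30)
  trk$lat[n] <- home[["lat"]]; trk$lon[n] <- home[["lon"]]
  h <- homing_efficiency_index(track_steps(trk), rel$lat, rel$lon,
                               home["lat"], home["lon"], home_radius_km = 0)
  expect_equal(h$hei, 1, tolerance = 1e-6)
  expect_equal(h$c_km, 0, tolerance = 1e-6)

  # b = 60 km, straight 30 km directly away from home: HEI = -0.5
  rel2 <- destination_point(home["lat"], home["lon"], 90, 60)
  away_bearing <- initial_bearing(rel2$lat, rel2$lon, home["lat"], home["lon"]) + 180
  far <- destination_point(rel2$lat, rel2$lon, away_bearing, 30)
  n2 <- 31
  trk2 <- straight_track(rel2$lat, rel2$lon, far$lat, far$lon,
                         n_fix = n2, step_km = 30 / (n2 - 1), step_s = 60)
  h2 <- homing_efficiency_index(track_steps(trk2), rel2$lat, rel2$lon,
                                home["lat"], home["lon"])
  expect_equal(h2$b_km, 60, tolerance = 1e-6)
  expect_equal(h2$hei, -0.5, tolerance = 1e-3)
})

test_that("HEI components match brute-force recomputation on tortuous tracks", {
  for (seed in c(5, 6)) {
    trk <- gen_track(43.9, 11.0, home["lat"], home["lon"], westward_weight = 0.4,
                     kappa = 1.5, max_duration_min = 70, seed = seed)
    st <- track_steps(trk)
    h <- homing_efficiency_index(st, 43.9, 11.0, home["lat"], home["lon"])
    # oracle: walk fixes accumulating active time (speed > 10 km/h)
    lens <- slc_distance_km(trk$lat[-nrow(trk)], trk$lon[-nrow(trk)],
                            trk$lat[-1], trk$lon[-1])
    spd <- trk$speed_kmh[-nrow(trk)]
    dur <- as.numeric(diff(trk$time))
    cum_active <- cumsum(ifelse(spd > 10, dur, 0))
    dist_home <- slc_distance_km(trk$lat[-1], trk$lon[-1],
                                 home[["lat"]], home[["lon"]])
    k <- min(c(which(cum_active >= 50 * 60), which(dist_home <= 0.5),
               length(lens)))
    expect_equal(h$trunc_index, k)
    expect_equal(h$l_km, sum(lens[1:k]), tolerance = 1e-6)
    expect_equal(h$a_km, slc_distance_km(43.9, 11.0, trk$lat[k + 1], trk$lon[k + 1]),
                 tolerance = 1e-6)
    expect_equal(h$c_km, dist_home[k], tolerance = 1e-6)
    b <- slc_distance_km(43.9, 11.0, home[["lat"]], home[["lon"]])
    expect_equal(h$hei, (h$a_km / h$l_km) * (b - h$c_km) / b, tolerance = 1e-9)
    expect_lte(h$hei, 1)
  }
})

test_that("MAAP is 0 on a great-circle home flight and 90 at constant offset", {
  rel <- destination_point(home["lat"], home["lon"], 61, 59.9)
  trk <- straight_track(rel$lat, rel$lon, home["lat"], home["lon"],
                        n_fix = 6, step_km = 9, step_s = 3600)
  m0 <- mean_aggregate_azimuth_penalty(trk, home["lat"], home["lon"])
  expect_lt(m0, 1)

  # constant 90-degree offset spiral: every hourly displacement is
  # perpendicular to the home azimuth
  lat <- numeric(6); lon <- numeric(6)
  lat[1] <- rel$lat; lon[1] <- rel$lon
  for (i in 1:5) {
    A <- initial_bearing(lat[i], lon[i], home["lat"], home["lon"])
    p <- destination_point(lat[i], lon[i], wrap360(A + 90), 8)
    lat[i + 1] <- p$lat; lon[i + 1] <- p$lon
  }
  spiral <- tibble::tibble(bird_id = "sp", time = t0 + 0:5 * 3600,
                           lat = lat, lon = lon)
  m90 <- mean_aggregate_azimuth_penalty(spiral, home["lat"], home["lon"])
  expect_equal(m90, 90, tolerance = 0.1)

  expect_error(
    mean_aggregate_azimuth_penalty(spiral[1:2, ][-2, ], home["lat"], home["lon"]),
    "fewer than 2"
  )
})

test_that("MAAP matches an hourly-downsampling oracle and is time-shift invariant", {
  trk <- gen_track(43.9, 11.0, home["lat"], home["lon"], westward_weight = 0.3,
                   kappa = 2, max_duration_min = 200, home_radius_km = 0,
                   seed = 99)
  m <- mean_aggregate_azimuth_penalty(trk, home["lat"], home["lon"])
  # oracle: exact hourly fixes exist (10 s cadence), so sample directly
  rel_s <- as.numeric(trk$time - trk$time[1])
  idx <- match(seq(0, max(rel_s), by = 3600), rel_s)
  idx <- idx[!is.na(idx)]
  i0 <- idx[-length(idx)]; i1 <- idx[-1]
  A <- initial_bearing(trk$lat[i0], trk$lon[i0], home[["lat"]], home[["lon"]])
  obs <- initial_bearing(trk$lat[i0], trk$lon[i0], trk$lat[i1], trk$lon[i1])
  expect_equal(m, mean(abs(wrap180(A - obs))), tolerance = 1e-9)
  expect_true(m >= 0 && m <= 180)

  shifted <- dplyr::mutate(trk, time = time + 7 * 24 * 3600)
  expect_equal(mean_aggregate_azimuth_penalty(shifted, home["lat"], home["lon"]), m)
})

test_that("batch indices carry correct flags and propagate per-bird failures as NA", {
  co <- simulate_cohort(n_birds = 10, seed = 33, bias_coef = 1)
  idx <- compute_indices(co$tracks, co$sites)
  expect_equal(nrow(idx), 10L)
  expect_setequal(idx$bird_id, unique(co$tracks$bird_id))
  expect_true(all(idx$consistent == (idx$r >= 0.1)))
  expect_true(all(is.na(idx$maap)))  # 15 min tracks are too short for MAAP
  expect_true(all(abs(idx$dev_west) == idx$dev_west_abs, na.rm = TRUE))
  expect_true(all(idx$dev_west_abs >= 0 & idx$dev_west_abs <= 180, na.rm = TRUE))
  # straight westward flier: dev_west = 0
  trk <- gen_track(43.66, 10.95, 43.66, 10.0, westward_weight = 0, kappa = Inf,
                   max_duration_min = 10, bird_id = "w1", seed = 1)
  sites <- tibble::tibble(bird_id = "w1", release_lat = 43.66, release_lon = 10.95,
                          home_lat = 43.66, home_lon = 10.0)
  iw <- compute_indices(trk, sites)
  expect_equal(iw$dev_west, 0, tolerance = 0.5)
  expect_gt(iw$hei, 0)  # straight path: positive approach to home
})
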