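test_that("generators are pure functions of their seed", {
  m1 <- gen_sea_breeze_met(days = 1, seed = 9)
  m2 <- gen_sea_breeze_met(days = 1, seed = 9)
  expect_identical(m1, m2)
  expect_false(identical(m1$wd_deg, gen_sea_breeze_met(days = 1, seed = 10)$wd_deg))

  t1 <- gen_track(43.9, 11.0, 43.66, 10.3, seed = 4, max_duration_min = 5)
  t2 <- gen_track(43.9, 11.0, 43.66, 10.3, seed = 4, max_duration_min = 5)
  expect_identical(t1, t2)

  tr1 <- gen_trajectory(43.9, 10.9, m1$time[1], 270, seed = 3)
  tr2 <- gen_trajectory(43.9, 10.9, m1$time[1], 270, seed = 3)
  expect_identical(tr1, tr2)

  wp1 <- gen_wind_profile(seed = 2)
  expect_identical(wp1, gen_wind_profile(seed = 2))

  co1 <- simulate_cohort(n_birds = 5, seed = 12)
  co2 <- simulate_cohort(n_birds = 5, seed = 12)
  expect_identical(co1, co2)
})

test_that("sea-breeze meteorology reproduces the diel wind reversal and ranges", {
  met <- gen_sea_breeze_met(days = 4, seed = 21)
  h <- (as.numeric(met$time - met$time[1]) / 3600) %% 24
  onshore <- circular_mean(met$wd_deg[h >= 13 & h < 19])
  expect_lt(angular_difference(onshore$direction, 270, signed = FALSE), 5)
  offshore <- circular_mean(met$wd_deg[h < 11])
  expect_lt(angular_difference(offshore$direction, 150, signed = FALSE), 5)
  expect_true(all(met$temp_c >= 12 & met$temp_c <= 25))
  expect_true(all(met$rh_pct >= 60 & met$rh_pct <= 85))
  expect_true(all(met$ws_ms >= 0))
  expect_error(gen_sea_breeze_met(days = 0), ">= 1")
  expect_error(gen_sea_breeze_met(onshore_from = 20, onshore_to = 12), "window")
})

test_that("generated VOC series carry their constructed source geography", {
  met <- gen_sea_breeze_met(days = 6, seed = 22)
  voc <- gen_voc_series(met, seed = 23)

  # DMS: the westerly marine source puts the polar-map maximum in the
  # westerly half-disc
  dms <- dplyr::filter(voc, species == "DMS m/z 63")
  grid <- polar_bin(dms[c("time", "vmr")], met, min_count = 10)
  top <- grid[which.max(grid$mean_vmr), ]
  expect_true(top$wd_mid > 180 & top$wd_mid < 360)

  # monoterpenes: nocturnal accumulation beats daytime levels
  mt <- dplyr::filter(voc, species == "monoterpenes m/z 81")
  dc <- diel_cycle(mt[c("time", "vmr")])
  night <- mean(dc$mean[dc$hour %in% c(0:5, 22, 23)])
  day <- mean(dc$mean[dc$hour %in% 9:18])
  expect_gt(night, day)

  # a single sharply-westerly noise-free source is (numerically) zero
  # whenever the wind comes from inland
  src <- tibble::tibble(species = "tracer", baseline = 0, gain = 1,
                        source_dir = 270, kappa = 200, diel = "flat",
                        noise_sdlog = 1e-12)
  tr <- gen_voc_series(met, src, seed = 1)
  offshore <- angular_difference(met$wd_deg, 150, signed = FALSE) < 30
  expect_lt(max(tr$vmr[offshore]), 1e-30)
  expect_gt(max(tr$vmr[!offshore]), 0.5)

  expect_error(gen_voc_series(met, dplyr::select(src, -kappa)), "columns")
})

test_that("track generator limits reproduce straight homing and pure west flight", {
  s <- arnino_sites()[1, ]
  # 90 km/h cruise reaches the 59.9 km distant home inside the 50 min
  # active-flight window, so the HEI window runs to arrival
  straight <- gen_track(s$release_lat, s$release_lon, s$home_lat, s$home_lon,
                        westward_weight = 0, kappa = Inf, speed_sdlog = 0,
                        speed_median_kmh = 90, max_duration_min = 90, seed = 1)
  st <- track_steps(straight)
  h <- homing_efficiency_index(st, s$release_lat, s$release_lon,
                               s$home_lat, s$home_lon)
  expect_gt(h$hei, 0.98)
  end <- straight[nrow(straight), ]
  expect_lt(haversine_km(end$lat, end$lon, s$home_lat, s$home_lon), 0.51)

  west <- gen_track(s$release_lat, s$release_lon, s$home_lat, s$home_lon,
                    westward_weight = 1, kappa = 2, max_duration_min = 12,
                    seed = 2)
  mv <- initial_orientation(track_steps(west), s$release_lat, s$release_lon)
  expect_lt(angular_difference(mv$direction, 270, signed = FALSE), 10)
})

test_that("synthetic trajectories respect the coastline limits and round-trip", {
  t0 <- as.POSIXct("2016-07-15 09:00:00", tz = "UTC")
  mask <- halfplane_mask(10.282)
  s <- arnino_sites()[3, ]  # due east of home, well inland

  # air from due west at synoptic speed: over sea within the first hours
  from_west <- gen_trajectory(s$release_lat, s$release_lon, t0, 270,
                              kappa_dir = 1e4, seed = 11)
  res_w <- classify_trajectories(from_west, mask)
  expect_gt(res_w$hours_sea_bl + res_w$hours_above_bl, 20)

  # air from due east never reaches the sea
  from_east <- gen_trajectory(s$release_lat, s$release_lon, t0, 90,
                              kappa_dir = 1e4, seed = 12)
  res_e <- classify_trajectories(from_east, mask)
  expect_equal(res_e$hours_sea_bl, 0)
  expect_identical(res_e$ratio_land_sea, Inf)

  f <- withr::local_tempfile(fileext = ".tdump")
  write_hysplit(from_west, f)
  rt <- read_hysplit(f)
  expect_equal(classify_trajectories(rt, mask)$hours_sea_bl, res_w$hours_sea_bl)
})

test_that("wind-profile generator limits give the expected WWC", {
  # all mass from due west: WWC equals the S-weighted speed mix
  wp <- gen_wind_profile(dominant_dir = 270, concentration = 1e5,
                         speed_mix = c(0, 0, 1, 0, 0, 0), n = 500, seed = 5)
  expect_equal(west_wind_component(wp), 3, tolerance = 1e-9)

  mix <- c(0.2, 0.3, 0.1, 0.2, 0.1, 0.1)
  wp2 <- gen_wind_profile(dominant_dir = 270, concentration = 1e5,
                          speed_mix = mix, n = 20000, seed = 6)
  expect_equal(west_wind_component(wp2), sum(1:6 * mix), tolerance = 0.05)

  unif <- gen_wind_profile(concentration = 0, n = 40000, seed = 7)
  expect_lt(abs(west_wind_component(unif)), 0.1)
})

test_that("cohort truth couples the westward weight to the constructed sea fraction", {
  co <- simulate_cohort(n_birds = 30, seed = 77, bias_coef = 1)
  expect_equal(co$truth$westward_weight, 1 - co$truth$sea_fraction,
               tolerance = 1e-12)
  expect_equal(nrow(co$residence), 30L)
  expect_true(all(co$residence$hours_sea_bl + co$residence$hours_land_bl +
                  co$residence$hours_above_bl == 24))
  # the full pipeline recovers the constructed positive association
  pl <- run_pipeline(n_birds = 60, seed = 78, bias_coef = 1)
  expect_gt(pl$association$rho, 0)
  expect_lt(pl$association$p_value, 0.05)
})
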