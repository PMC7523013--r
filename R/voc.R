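#' Subtract instrument background from a VOC series
#'
#' PTR-MS background runs (synthetic-air measurements) are reduced to their
#' run midpoints; the background level at every ambient timestamp is linearly
#' interpolated between midpoints and held constant before the first and
#' after the last run. The interpolated background is subtracted and negative
#' results are clipped to zero; the number of clipped records is attached as
#' the `n_clipped` attribute so data loss stays visible.
#'
#' @param series Data frame with columns `time` (POSIXct) and `vmr`
#'   (mixing ratio, ppbv).
#' @param backgrounds Data frame of background runs: either columns `start`,
#'   `end`, `value` or pre-computed midpoints `time`, `value`.
#' @return A tibble like `series` with `vmr` background-corrected, plus a
#'   `background` column; attribute `n_clipped` counts records clipped at 0.
#' @export
subtract_background <- function(series, backgrounds) {
  stopifnot(all(c("time", "vmr") %in% names(series)))
  if (nrow(backgrounds) == 0L) abort("at least one background run is required")
  if (all(c("start", "end") %in% names(backgrounds))) {
    if (any(backgrounds$end <= backgrounds$start)) {
      abort("background runs must have positive duration")
    }
    mid <- backgrounds$start + (backgrounds$end - backgrounds$start) / 2
  } else {
    stopifnot("time" %in% names(backgrounds))
    mid <- backgrounds$time
  }
  bg <- if (length(mid) == 1L) {
    rep(backgrounds$value, nrow(series))
  } else {
    approx(as.numeric(mid), backgrounds$value, xout = as.numeric(series$time),
           rule = 2)$y
  }
  corrected <- series$vmr - bg
  n_clipped <- sum(corrected < 0)
  out <- dplyr::mutate(tibble::as_tibble(series),
                       background = bg, vmr = pmax(corrected, 0))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Diel cycle of a VOC or meteorological series
#'
#' Summarises a time series by local hour of day the way campaign diel plots
#' are drawn: records are first averaged within each day and hour (so days
#' with denser sampling do not dominate), then statistics are taken across
#' days per hour: mean, sd, median, interquartile range and the 10th/90th
#' percentiles. The campaign-wide maximum hourly mean and the sd of the
#' daily means at that hour (the "maximum hourly average +/- 1 sigma") are
#' attached as attributes.
#'
#' @param series Data frame with columns `time` (POSIXct) and `vmr`.
#' @param tz_offset_h Hours added to `time` to obtain local time (default 0:
#'   timestamps already local).
#' @return A 24-row tibble of class `olf_diel` with columns `hour`, `n_days`,
#'   `mean`, `sd`, `median`, `q25`, `q75`, `p10`, `p90`; attributes
#'   `max_hourly_mean`, `sd_at_max`, `peak_hour`.
#' @export
diel_cycle <- function(series, tz_offset_h = 0) {
  stopifnot(all(c("time", "vmr") %in% names(series)))
  if (nrow(series) == 0L) abort("empty series")
  lt <- series$time + tz_offset_h * 3600
  hr <- as.integer(format(lt, "%H", tz = "UTC"))
  day <- format(lt, "%Y-%m-%d", tz = "UTC")
  daily <- tibble::tibble(day = day, hour = hr, vmr = series$vmr) |>
    dplyr::group_by(.data$day, .data$hour) |>
    dplyr::summarise(vmr = mean(.data$vmr), .groups = "drop")
  out <- daily |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean = mean(.data$vmr),
      sd = sd(.data$vmr),
      median = median(.data$vmr),
      q25 = quantile(.data$vmr, 0.25, names = FALSE),
      q75 = quantile(.data$vmr, 0.75, names = FALSE),
      p10 = quantile(.data$vmr, 0.10, names = FALSE),
      p90 = quantile(.data$vmr, 0.90, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(hour = 0:23), by = "hour") |>
    dplyr::arrange(.data$hour)
  peak <- which.max(out$mean)
  class(out) <- c("olf_diel", class(out))
  attr(out, "max_hourly_mean") <- out$mean[peak]
  attr(out, "sd_at_max") <- out$sd[peak]
  attr(out, "peak_hour") <- out$hour[peak]
  out
}

#' Bivariate polar map of a VOC series
#'
#' Pairs each mixing-ratio record with the meteorological record nearest in
#' time (within `match_tol_s`), then bins the pairs jointly by wind direction
#' (sector width `wd_bin` degrees) and wind speed (`ws_bin` m/s) and reports
#' the arithmetic mean mixing ratio per cell, as in source-apportionment
#' polar plots. Cells with fewer than `min_count` pairs are masked (`NA`
#' mean) but keep their count. No smoothing is applied, so every cell value
#' is an exact group mean.
#'
#' @param series Data frame with `time`, `vmr`.
#' @param met Data frame with `time`, `wd_deg`, `ws_ms`.
#' @param wd_bin Wind-direction bin width, degrees (default 10).
#' @param ws_bin Wind-speed bin width, m/s (default 1).
#' @param min_count Minimum pairs per cell before masking (default 3).
#' @param match_tol_s Maximum timestamp mismatch when pairing, seconds
#'   (default 60).
#' @return A tibble of class `olf_polar`: `wd_mid`, `ws_mid`, `mean_vmr`
#'   (`NA` when masked), `n`. Attribute `n_matched` gives the total number
#'   of paired records.
#' @export
polar_bin <- function(series, met, wd_bin = 10, ws_bin = 1, min_count = 3,
                      match_tol_s = 60) {
  stopifnot(all(c("time", "vmr") %in% names(series)),
            all(c("time", "wd_deg", "ws_ms") %in% names(met)))
  mt <- as.numeric(met$time)
  st <- as.numeric(series$time)
  ord <- order(mt)
  mt <- mt[ord]
  j <- findInterval(st, mt, all.inside = FALSE)
  j_lo <- pmax(j, 1L); j_hi <- pmin(j + 1L, length(mt))
  nearest <- ifelse(abs(st - mt[j_lo]) <= abs(st - mt[j_hi]), j_lo, j_hi)
  ok <- abs(st - mt[nearest]) <= match_tol_s
  if (!any(ok)) abort("no timestamp overlap between series and meteorology")
  midx <- ord[nearest[ok]]
  wd <- wrap360(met$wd_deg[midx])
  ws <- met$ws_ms[midx]
  out <- tibble::tibble(
    wd_mid = (floor(wd / wd_bin) + 0.5) * wd_bin,
    ws_mid = (floor(ws / ws_bin) + 0.5) * ws_bin,
    vmr = series$vmr[ok]
  ) |>
    dplyr::group_by(.data$wd_mid, .data$ws_mid) |>
    dplyr::summarise(mean_vmr = mean(.data$vmr), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(mean_vmr = ifelse(.data$n < min_count, NA_real_, .data$mean_vmr))
  class(out) <- c("olf_polar", class(out))
  attr(out, "n_matched") <- sum(ok)
  out
}

#' OH-reactivity atmospheric lifetime
#'
#' The lifetime of a VOC against oxidation by the OH radical,
#' tau = 1 / (k_OH * \[OH\]), in seconds. The default OH concentration of
#' 2e6 molecules cm^-3 is a typical daytime boundary-layer value.
#'
#' @param k_oh OH rate constant, cm^3 molecule^-1 s^-1 (positive).
#' @param oh_conc OH radical concentration, molecules cm^-3 (default `2e6`).
#' @return Lifetime in seconds (vectorised over `k_oh`).
#' @export
#' @examples
#' oh_lifetime(1.0e-10) / 3600          # isoprene: ~1.4 h
#' oh_lifetime(1.7e-10) / 60            # limonene: ~49 min
oh_lifetime <- function(k_oh, oh_conc = 2e6) {
  if (any(k_oh <= 0) || any(oh_conc <= 0)) abort("`k_oh` and `oh_conc` must be positive")
  1 / (k_oh * oh_conc)
}

#' Horizontal e-folding transport distance
#'
#' Distance over which a reactive gas advected at `wind_speed_ms` decays to
#' 1/e of its initial concentration: u * tau, reported in km. With the
#' default 2.2 m/s typical wind speed, isoprene's OH-only lifetime of 5000 s
#' gives 11 km.
#'
#' @param tau_s Atmospheric lifetime, seconds (positive).
#' @param wind_speed_ms Wind speed, m/s (non-negative, default 2.2).
#' @return Distance in km.
#' @export
#' @examples
#' efolding_distance(oh_lifetime(1.0e-10))  # 11 km
efolding_distance <- function(tau_s, wind_speed_ms = 2.2) {
  if (any(tau_s <= 0)) abort("`tau_s` must be positive")
  if (any(wind_speed_ms < 0)) abort("`wind_speed_ms` must be non-negative")
  wind_speed_ms * tau_s / 1000
}

#' Packaged OH rate-constant table
#'
#' Literature-recommended OH rate constants for the study's focal VOCs,
#' shipped as a plain CSV in `inst/extdata/koh_rates.csv`.
#'
#' @return A tibble with columns `species`, `k_oh` (cm^3 molecule^-1 s^-1)
#'   and `note`.
#' @export
koh_rates <- function() {
  path <- system.file("extdata", "koh_rates.csv", package = "olfnav",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
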