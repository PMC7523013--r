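#' Land/sea masks
#'
#' A mask answers one question: is a point over sea or over land?
#' `halfplane_mask()` builds the idealised coastline used by the synthetic
#' study system: everything west of `coast_lon` is sea. `read_mask_geojson()`
#' reads a GeoJSON FeatureCollection of polygons whose `surface` property is
#' `"sea"` or `"land"`; points falling in no polygon are outside mask
#' coverage and raise an error at classification time.
#'
#' @param coast_lon Longitude of the straight north-south coastline, degrees.
#' @return An object of class `olf_mask`.
#' @export
#' @examples
#' m <- halfplane_mask(10.282)
#' is_sea(m, lon = c(10.1, 10.5), lat = c(43.6, 43.6))  # TRUE FALSE
halfplane_mask <- function(coast_lon) {
  structure(list(type = "halfplane", coast_lon = coast_lon), class = "olf_mask")
}

#' @rdname halfplane_mask
#' @param path Path to a GeoJSON file of sea/land polygons.
#' @export
read_mask_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) abort("mask GeoJSON must be a FeatureCollection")
  polys <- lapply(gj$features, function(f) {
    surface <- f$properties$surface %||% "land"
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    list(surface = surface, lon = xy[, 1], lat = xy[, 2])
  })
  structure(list(type = "polygons", polygons = polys), class = "olf_mask")
}

#' Classify points of a mask as sea or land
#'
#' @param mask An `olf_mask`.
#' @param lon,lat Point coordinates, degrees.
#' @return Logical vector: `TRUE` over sea, `FALSE` over land, `NA` outside
#'   mask coverage (polygon masks only).
#' @export
is_sea <- function(mask, lon, lat) {
  stopifnot(inherits(mask, "olf_mask"))
  if (mask$type == "halfplane") return(lon < mask$coast_lon)
  out <- rep(NA, length(lon))
  pts <- cbind(lon, lat)
  for (pg in mask$polygons) {
    bnd <- list(x = pg$lon, y = pg$lat)
    inside <- mgcv::in.out(cbind(bnd$x, bnd$y), pts)
    out[inside & is.na(out)] <- identical(pg$surface, "sea")
  }
  out
}

#' Sea / land / above-boundary-layer residence of air-mass trajectories
#'
#' Each hourly trajectory point inside the analysis window contributes one
#' hour to exactly one class: above the boundary layer if its transport
#' altitude exceeds the local mixing-layer depth (this test takes
#' precedence), otherwise marine boundary layer if the point is over sea,
#' otherwise land. For backward trajectories the window is the `window_h`
#' hours prior to release (offsets -window_h .. -1); for forward ones,
#' offsets 1 .. window_h. The origin point (offset 0) never counts. The
#' sea:land and land:sea residence ratios are formed with x/0 = +Inf (and
#' 0/0 = NaN), so rank statistics downstream can use them unmodified.
#'
#' @param traj Trajectory tibble (see [read_hysplit()] / [gen_trajectory()]).
#' @param mask An `olf_mask` covering all trajectory points.
#' @param window_h Analysis window in hours (default 24).
#' @return A tibble, one row per `traj_id`: `hours_sea_bl`, `hours_land_bl`,
#'   `hours_above_bl`, `ratio_sea_land`, `ratio_land_sea`.
#' @export
classify_trajectories <- function(traj, mask, window_h = 24) {
  backward <- tolower(traj$direction) == "backward"
  inwin <- ifelse(backward,
                  traj$hour_offset >= -window_h & traj$hour_offset <= -1,
                  traj$hour_offset >= 1 & traj$hour_offset <= window_h)
  w <- traj[inwin, ]
  above <- w$height_m > w$mixdepth_m
  sea <- is_sea(mask, w$lon, w$lat)
  if (anyNA(sea[!above])) {
    bad <- w$traj_id[!above & is.na(sea)][1]
    abort(sprintf("trajectory %s has points outside mask coverage", bad))
  }
  ids <- unique(traj$traj_id)
  grp <- split(seq_len(nrow(w)), factor(w$traj_id, levels = ids))
  count <- function(flag) vapply(grp, function(i) sum(flag[i], na.rm = TRUE), numeric(1))
  n_above <- count(above)
  n_sea <- count(sea & !above)
  n_land <- count(!sea & !above)
  tibble::new_tibble(list(
    traj_id = ids,
    hours_sea_bl = unname(n_sea),
    hours_land_bl = unname(n_land),
    hours_above_bl = unname(n_above),
    ratio_sea_land = unname(n_sea / n_land),
    ratio_land_sea = unname(n_land / n_sea)
  ), nrow = length(ids))
}

# Map a meteorological "coming-from" compass direction (deg) onto the wind
# profile angle theta, where theta = 0 is west, pi east, measured so that
# compass 270 -> 0. Returns radians in [0, 2*pi).
compass_to_theta <- function(wd_deg) deg2rad(wrap360(270 - wd_deg))

#' Build a 16-direction by 6-speed-class wind profile
#'
#' Bins a wind record series into the 16 x 6 occupancy matrix P used by the
#' west wind component: 16 equi-distant direction sectors (theta = 0 aligned
#' with west, pi with east, sectors centred on multiples of 22.5 degrees)
#' and 6 ordinal speed classes. Entries are fractions of records and sum
#' to 1.
#'
#' @param met Data frame with columns `wd_deg` (meteorological coming-from
#'   direction, degrees) and `ws_ms` (wind speed, m/s).
#' @param speed_edges Seven increasing bin edges defining the 6 speed
#'   classes, m/s; default `c(0, 1, 2, 4, 6, 8, Inf)`.
#' @param s_values `"ordinal"` (classes weighted 1..6, the default) or
#'   `"midpoint"` (class midpoints in m/s; the open top class uses its lower
#'   edge + 1).
#' @return A tibble of class `olf_wind_profile` with 96 rows: `sector`
#'   (0..15), `theta_rad`, `compass_deg` (sector centre as a compass
#'   direction), `speed_class` (1..6), `s` (class weight) and `fraction`.
#' @export
build_wind_profile <- function(met, speed_edges = c(0, 1, 2, 4, 6, 8, Inf),
                               s_values = c("ordinal", "midpoint")) {
  s_values <- match.arg(s_values)
  stopifnot(all(c("wd_deg", "ws_ms") %in% names(met)))
  if (nrow(met) == 0L) abort("empty meteorology series")
  if (length(speed_edges) != 7L || is.unsorted(speed_edges, strictly = TRUE)) {
    abort("`speed_edges` must be 7 strictly increasing values")
  }
  if (any(met$ws_ms < 0)) abort("wind speeds must be non-negative")
  theta_deg <- wrap360(270 - met$wd_deg)
  sector <- floor(((theta_deg + 11.25) %% 360) / 22.5)
  cls <- cut(met$ws_ms, breaks = speed_edges, labels = FALSE,
             include.lowest = TRUE, right = FALSE)
  if (anyNA(cls)) abort("wind speeds outside `speed_edges` range")
  tab <- table(factor(sector, levels = 0:15), factor(cls, levels = 1:6))
  P <- as.numeric(tab) / nrow(met)
  s <- switch(s_values,
    ordinal = 1:6,
    midpoint = {
      lo <- speed_edges[1:6]; hi <- speed_edges[2:7]
      ifelse(is.finite(hi), (lo + hi) / 2, lo + 1)
    }
  )
  grid <- expand.grid(sector = 0:15, speed_class = 1:6)
  out <- tibble::tibble(
    sector = grid$sector,
    theta_rad = grid$sector * pi / 8,
    compass_deg = wrap360(270 - grid$sector * 22.5),
    speed_class = grid$speed_class,
    s = s[grid$speed_class],
    fraction = P
  )
  class(out) <- c("olf_wind_profile", class(out))
  attr(out, "speed_edges") <- speed_edges
  out
}

#' West Wind Component of a wind profile
#'
#' WWC = sum over the 16 x 6 profile of cos(theta) * S * P: winds from due
#' west (theta = 0) are weighted +1, from due east -1, so westerly-dominated
#' profiles give positive values. WWC is linear in P and bounded by
#' +/- max(S).
#'
#' @param profile A wind profile from [build_wind_profile()] or
#'   [gen_wind_profile()].
#' @return The WWC, a dimensionless scalar.
#' @export
west_wind_component <- function(profile) {
  stopifnot(all(c("theta_rad", "s", "fraction") %in% names(profile)))
  sum(cos(profile$theta_rad) * profile$s * profile$fraction)
}
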