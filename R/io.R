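parse_time <- function(x) {
  t <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"
  ))
  if (anyNA(t)) abort("unparseable ISO-8601 timestamps in input")
  t
}

read_csv_file <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("input file '%s' does not exist", path))
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("'%s' lacks required columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  df
}

#' Read and write the package's tabular interchange files
#'
#' All tabular interchange is CSV with ISO-8601 UTC timestamps. Tracks:
#' `bird_id`, `time`, `lat`, `lon`, optional `speed_kmh`. Sites: `bird_id`,
#' `release_lat`, `release_lon`, `home_lat`, `home_lon`, optional
#' `release_time`. Meteorology: `time`, `temp_c`, `rh_pct`, `ws_ms`,
#' `wd_deg`, `rain_mm`. VOC: `species`, `time`, `vmr`.
#'
#' @param path File path.
#' @return A tibble with parsed timestamp columns.
#' @export
read_tracks_csv <- function(path) {
  df <- read_csv_file(path, c("bird_id", "time", "lat", "lon"))
  dplyr::mutate(df, time = parse_time(.data$time))
}

#' @rdname read_tracks_csv
#' @export
read_sites_csv <- function(path) {
  df <- read_csv_file(path, c("bird_id", "release_lat", "release_lon",
                              "home_lat", "home_lon"))
  if ("release_time" %in% names(df)) {
    df <- dplyr::mutate(df, release_time = parse_time(.data$release_time))
  }
  df
}

#' @rdname read_tracks_csv
#' @export
read_met_csv <- function(path) {
  df <- read_csv_file(path, c("time", "ws_ms", "wd_deg"))
  dplyr::mutate(df, time = parse_time(.data$time))
}

#' @rdname read_tracks_csv
#' @export
read_voc_csv <- function(path) {
  df <- read_csv_file(path, c("species", "time", "vmr"))
  dplyr::mutate(df, time = parse_time(.data$time))
}

format_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' @rdname read_tracks_csv
#' @param x Tibble to write.
#' @export
write_table_csv <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(function(c) inherits(c, "POSIXct")),
                                      format_time))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a land/sea mask as GeoJSON polygons
#'
#' A half-plane mask is rendered as two rectangles (sea west of the
#' coastline, land east of it) over the given bounding box, so the same file
#' round-trips through [read_mask_geojson()].
#'
#' @param mask An `olf_mask`.
#' @param path Output path.
#' @param bbox Bounding box `c(lon_min, lat_min, lon_max, lat_max)` used for
#'   half-plane masks; the default spans well beyond a 24 h synoptic
#'   trajectory from the study region.
#' @return `path`, invisibly.
#' @export
write_mask_geojson <- function(mask, path, bbox = c(-15, 25, 35, 65)) {
  stopifnot(inherits(mask, "olf_mask"))
  rect <- function(lon0, lon1, lat0, lat1) {
    list(list(
      list(lon0, lat0), list(lon1, lat0), list(lon1, lat1),
      list(lon0, lat1), list(lon0, lat0)
    ))
  }
  features <- if (mask$type == "halfplane") {
    list(
      list(type = "Feature", properties = list(surface = "sea"),
           geometry = list(type = "Polygon",
                           coordinates = rect(bbox[1], mask$coast_lon, bbox[2], bbox[4]))),
      list(type = "Feature", properties = list(surface = "land"),
           geometry = list(type = "Polygon",
                           coordinates = rect(mask$coast_lon, bbox[3], bbox[2], bbox[4])))
    )
  } else {
    lapply(mask$polygons, function(pg) {
      coords <- lapply(seq_along(pg$lon), function(i) list(pg$lon[i], pg$lat[i]))
      list(type = "Feature", properties = list(surface = pg$surface),
           geometry = list(type = "Polygon", coordinates = list(coords)))
    })
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Emit a complete synthetic scenario as files
#'
#' Writes the full interchange file set for one seeded scenario: per-bird
#' tracks and sites, sea-breeze meteorology, VOC series, one tdump
#' back-trajectory file, the land/sea mask GeoJSON, the wind-profile
#' occupancy table and a machine-readable JSON manifest. Re-running with the
#' same seed reproduces every file byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param seed Scenario seed.
#' @param n_birds Cohort size.
#' @param days Days of meteorology.
#' @param ... Passed to [simulate_cohort()].
#' @return Named character vector of the files written, invisibly.
#' @export
write_scenario <- function(dir, seed = 1, n_birds = 6, days = 2, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(n_birds = n_birds, seed = seed, ...)
  met <- gen_sea_breeze_met(days = days, seed = derive_seed(seed, 101L))
  voc <- gen_voc_series(met, seed = derive_seed(seed, 102L))
  profile <- gen_wind_profile(seed = derive_seed(seed, 103L))
  traj <- purrr::map_dfr(seq_len(min(n_birds, 3L)), function(i) {
    sites <- arnino_sites()
    s <- sites[(i - 1L) %% nrow(sites) + 1L, ]
    gen_trajectory(s$release_lat, s$release_lon,
                   as.POSIXct("2016-07-15 09:00:00", tz = "UTC"),
                   prevailing_dir = 270, traj_id = i,
                   seed = derive_seed(seed, 200L + i))
  })
  paths <- c(
    tracks = file.path(dir, "tracks.csv"),
    sites = file.path(dir, "sites.csv"),
    residence = file.path(dir, "residence.csv"),
    met = file.path(dir, "met.csv"),
    voc = file.path(dir, "voc.csv"),
    tdump = file.path(dir, "trajectories.tdump"),
    mask = file.path(dir, "mask.geojson"),
    profile = file.path(dir, "wind_profile.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_table_csv(cohort$tracks, paths[["tracks"]])
  write_table_csv(cohort$sites, paths[["sites"]])
  write_table_csv(cohort$residence, paths[["residence"]])
  write_table_csv(met, paths[["met"]])
  write_table_csv(voc, paths[["voc"]])
  write_hysplit(traj, paths[["tdump"]])
  write_mask_geojson(halfplane_mask(10.282), paths[["mask"]])
  write_table_csv(tibble::as_tibble(profile), paths[["profile"]])
  manifest <- list(
    package = "olfnav",
    version = as.character(utils::packageVersion("olfnav")),
    seed = seed, n_birds = n_birds, days = days,
    files = as.list(setNames(basename(paths[names(paths) != "manifest"]),
                             names(paths)[names(paths) != "manifest"]))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
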