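#' Read a HYSPLIT trajectory endpoint ("tdump") file
#'
#' Parses the standard endpoint dialect: a met-grid header block, a line
#' giving the number of trajectories and the run direction, one start line
#' per trajectory, a diagnostic-variable header, then one row per trajectory
#' hour (trajectory number, grid, date/time, forecast hour, age, latitude,
#' longitude, height and the diagnostic columns). The MIXDEPTH diagnostic is
#' required: residence classification needs the mixing-layer depth at every
#' hour.
#'
#' @param path Path to a tdump endpoint file.
#' @return A tibble with one row per trajectory hour: `traj_id`,
#'   `direction` (`"backward"` or `"forward"`), `start_time` (UTC),
#'   `hour_offset` (signed age in hours, negative backward), `lat`, `lon`,
#'   `height_m` (above ground) and `mixdepth_m`.
#' @export
read_hysplit <- function(path) {
  lines <- readLines(path)
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  num <- function(x, i) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) abort(sprintf("malformed tdump row at line %d of '%s'", i, path))
    v
  }
  ngrids <- num(toks(1)[1], 1)[1]
  i <- 2 + ngrids
  hd <- toks(i)
  ntraj <- num(hd[1], i)[1]
  direction <- tolower(hd[2])
  if (!direction %in% c("backward", "forward")) {
    abort(sprintf("unrecognised run direction '%s' at line %d", hd[2], i))
  }
  starts <- lapply(seq_len(ntraj), function(k) num(toks(i + k), i + k))
  i <- i + ntraj + 1
  diag_hd <- toks(i)
  diag_names <- toupper(diag_hd[-1])
  if (!"MIXDEPTH" %in% diag_names) {
    abort("tdump file lacks the MIXDEPTH diagnostic column required for boundary-layer classification")
  }
  mix_col <- 12L + which(diag_names == "MIXDEPTH")
  rows <- (i + 1):length(lines)
  rows <- rows[nzchar(trimws(lines[rows]))]
  mat <- t(vapply(rows, function(j) {
    v <- num(toks(j), j)
    if (length(v) < mix_col) abort(sprintf("malformed tdump row at line %d of '%s'", j, path))
    v[c(1, 3:8, 9, 10, 11, 12, mix_col)]
  }, numeric(12)))
  yr <- mat[, 2]
  yr <- ifelse(yr < 100, ifelse(yr > 50, 1900 + yr, 2000 + yr), yr)
  start_time <- as.POSIXct(
    sprintf("%04d-%02d-%02d %02d:%02d:00", yr, mat[, 3], mat[, 4], mat[, 5], mat[, 6]),
    tz = "UTC"
  ) - mat[, 8] * 3600
  tibble::tibble(
    traj_id = as.integer(mat[, 1]),
    direction = direction,
    start_time = start_time,
    hour_offset = mat[, 8],
    lat = mat[, 9],
    lon = mat[, 10],
    height_m = mat[, 11],
    mixdepth_m = mat[, 12]
  ) |>
    dplyr::arrange(.data$traj_id, .data$hour_offset)
}

#' Write trajectories to a HYSPLIT-style endpoint file
#'
#' Emits the same tdump endpoint dialect that [read_hysplit()] consumes
#' (PRESSURE and MIXDEPTH diagnostics; pressure is filled with a nominal
#' value). Round-tripping a trajectory table through write and read
#' reproduces positions, offsets, heights and mixing depths.
#'
#' @param traj Trajectory tibble as returned by [read_hysplit()] or
#'   [gen_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hysplit <- function(traj, path) {
  stopifnot(all(c("traj_id", "direction", "start_time", "hour_offset",
                  "lat", "lon", "height_m", "mixdepth_m") %in% names(traj)))
  direction <- toupper(unique(traj$direction))
  if (length(direction) != 1L) abort("all trajectories in one file must share a direction")
  ids <- unique(traj$traj_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("     1     1",
               "    GDAS     1     1     1     0     0"), con)
  writeLines(sprintf("%6d %s OMEGA", length(ids), direction), con)
  for (id in ids) {
    g <- traj[traj$traj_id == id, ]
    st <- as.POSIXlt(g$start_time[1], tz = "UTC")
    o <- g[which.min(abs(g$hour_offset)), ]
    writeLines(sprintf("%6d %5d %5d %5d %8.3f %9.3f %8.1f",
                       st$year %% 100, st$mon + 1, st$mday, st$hour,
                       o$lat, o$lon, o$height_m), con)
  }
  writeLines("     2 PRESSURE MIXDEPTH", con)
  for (id in ids) {
    g <- traj[traj$traj_id == id, ]
    g <- g[order(if (tolower(direction) == "backward") -g$hour_offset else g$hour_offset), ]
    pt_time <- as.POSIXlt(g$start_time + g$hour_offset * 3600, tz = "UTC")
    writeLines(sprintf(
      "%6d %5d %5d %5d %5d %5d %5d %5d %8.1f %8.3f %9.3f %8.1f %8.1f %8.1f",
      id, 1L, pt_time$year %% 100, pt_time$mon + 1, pt_time$mday,
      pt_time$hour, pt_time$min, 0L, g$hour_offset, g$lat, g$lon,
      g$height_m, 990.0, g$mixdepth_m), con)
  }
  invisible(path)
}
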