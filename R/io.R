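# Plain-text I/O: long-format CSV for gridded fields (lat, lon, month,
# value) with the variable name and units carried in comment headers, and
# YAML for world configurations. Round-trips are lossless including the
# validity mask (invalid cells are written as NA).

#' Write / read a monthly climatology as CSV
#'
#' The dialect is a long table `lat, lon, month, value` preceded by
#' `# variable:` and `# units:` comment lines; invalid cells are written
#' with `NA` in all 12 months so the mask survives a round-trip.
#'
#' @param grid A [climatology_grid()].
#' @param path File path.
#' @return `write_climatology_csv()` returns `path` invisibly;
#'   `read_climatology_csv()` returns a `climatology_grid`.
#' @export
write_climatology_csv <- function(grid, path) {
  stopifnot(inherits(grid, "climatology_grid"))
  header <- c(paste0("# variable: ", grid$variable),
              paste0("# units: ", grid$units))
  writeLines(header, path)
  readr::write_csv(as_tibble(grid), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_climatology_csv
#' @export
read_climatology_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "nichescape_io_error")
  }
  meta <- readLines(path, n = 10)
  meta <- meta[startsWith(meta, "#")]
  pick <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0) return("")
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("lat", "lon", "month", "value") %in% names(tab))) {
    abort("climatology CSV needs columns lat, lon, month, value",
          class = "nichescape_format_error")
  }
  months <- sort(unique(tab$month))
  if (!identical(as.integer(months), 1:12)) {
    abort(sprintf("expected 12 monthly layers, found %d", length(months)),
          class = "nichescape_format_error")
  }
  lat <- sort(unique(tab$lat))
  lon <- sort(unique(tab$lon))
  if (nrow(tab) != length(lat) * length(lon) * 12) {
    abort("climatology CSV is not a complete lat x lon x month grid",
          class = "nichescape_format_error")
  }
  arr <- array(NA_real_, c(length(lat), length(lon), 12))
  arr[cbind(match(tab$lat, lat), match(tab$lon, lon), tab$month)] <- tab$value
  climatology_grid(arr, lat, lon, variable = pick("variable"),
                   units = pick("units"))
}

#' Write / read a bathymetry grid as CSV
#'
#' Long table `lat, lon, depth` with `NA` depth on land.
#'
#' @param bathy A [bathymetry_grid()].
#' @param path File path.
#' @export
write_bathymetry_csv <- function(bathy, path) {
  stopifnot(inherits(bathy, "bathymetry_grid"))
  tab <- tidyr::expand_grid(lon = bathy$lon, lat = bathy$lat) |>
    dplyr::mutate(depth = as.vector(bathy$depth)) |>
    dplyr::select("lat", "lon", "depth")
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_bathymetry_csv
#' @export
read_bathymetry_csv <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  lat <- sort(unique(tab$lat))
  lon <- sort(unique(tab$lon))
  depth <- matrix(NA_real_, length(lat), length(lon))
  depth[cbind(match(tab$lat, lat), match(tab$lon, lon))] <- tab$depth
  bathymetry_grid(depth, lat, lon)
}

#' Write / read a world configuration as YAML
#'
#' @param config A [world_config()].
#' @param path File path.
#' @export
write_world_config <- function(config, path) {
  stopifnot(inherits(config, "world_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_world_config
#' @export
read_world_config <- function(path) {
  do.call(world_config, yaml::read_yaml(path))
}

#' Write / read a full synthetic world as a directory of text files
#'
#' One CSV per climatology, a bathymetry CSV, and the generating
#' configuration as YAML.
#'
#' @param world A [generate_world()] result.
#' @param dir Directory (created if missing).
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in c("sst", "land_temp", "precip", "seabed_temp", "seabed_light")) {
    write_climatology_csv(world[[v]], file.path(dir, paste0(v, ".csv")))
  }
  write_bathymetry_csv(world$bathymetry, file.path(dir, "bathymetry.csv"))
  write_world_config(world$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  config <- read_world_config(file.path(dir, "config.yaml"))
  grids <- lapply(c(sst = "sst", land_temp = "land_temp", precip = "precip",
                    seabed_temp = "seabed_temp", seabed_light = "seabed_light"),
                  function(v) read_climatology_csv(file.path(dir, paste0(v, ".csv"))))
  bathy <- read_bathymetry_csv(file.path(dir, "bathymetry.csv"))
  structure(c(grids,
              list(bathymetry = bathy, land_mask = bathy$land_mask,
                   lat = bathy$lat, lon = bathy$lon, config = config)),
            class = "synthetic_world")
}

#' Export a materialized niche pool as CSV
#'
#' One row per niche and axis: `niche_id, axis, x, y, alpha`.
#'
#' @param pool A materialized [niche_pool].
#' @param path File path.
#' @export
write_pool_csv <- function(pool, path) {
  readr::write_csv(tidy(pool), path)
  invisible(path)
}
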