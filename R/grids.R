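# Gridded monthly climatologies and bathymetry. Fields are stored as
# plain matrices/arrays indexed [lat, lon(, month)] with ascending
# latitude centres and longitudes in [-180, 180); every grid carries a
# validity mask, and a cell invalid in any month is invalid in all of
# them (no imputation anywhere in the pipeline).

#' Monthly climatology on a regular latitude-longitude grid
#'
#' @param values Numeric array `n_lat x n_lon x 12` of monthly fields.
#'   `NA` cells are treated as invalid.
#' @param lat,lon Cell-centre coordinates (degrees); `lat` ascending,
#'   `lon` in `[-180, 180)`. Both must be regularly spaced.
#' @param variable,units Variable name and units, recorded verbatim.
#' @param mask Optional logical `n_lat x n_lon` validity mask; defaults to
#'   cells that are non-`NA` in every month. Cells masked out are set `NA`
#'   in all 12 months so partial months cannot occur.
#' @return A `climatology_grid` object.
#' @export
climatology_grid <- function(values, lat, lon, variable = "variable",
                             units = "", mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3 || dim(values)[3] != 12) {
    abort("a climatology needs exactly 12 monthly layers",
          class = "nichescape_format_error")
  }
  if (dim(values)[1] != length(lat) || dim(values)[2] != length(lon)) {
    abort("field dimensions do not match lat/lon centres",
          class = "nichescape_dimension_error")
  }
  check_regular_axis(lat, "lat")
  check_regular_axis(lon, "lon")
  complete <- apply(!is.na(values), c(1, 2), all)
  if (is.null(mask)) mask <- complete else mask <- mask & complete
  values[array(rep(!mask, 12), dim(values))] <- NA_real_
  structure(
    list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
         variable = variable, units = units, mask = mask),
    class = "climatology_grid"
  )
}

check_regular_axis <- function(x, what) {
  if (length(x) > 1) {
    d <- diff(x)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
      abort(paste0("irregular ", what, " axis is not supported"),
            class = "nichescape_unsupported_grid_error")
    }
  }
  invisible(x)
}

grid_resolution <- function(grid) {
  c(lat = diff(grid$lat[1:2]), lon = diff(grid$lon[1:2]))
}

#' @export
print.climatology_grid <- function(x, ...) {
  res <- grid_resolution(x)
  cat(sprintf("<climatology_grid> %s [%s]\n", x$variable, x$units))
  cat(sprintf("  %d x %d cells (%.3g deg lat x %.3g deg lon), 12 months\n",
              length(x$lat), length(x$lon), res["lat"], res["lon"]))
  cat(sprintf("  %d valid cells (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
as_tibble.climatology_grid <- function(x, ...) {
  tidyr::expand_grid(month = 1:12, lon = x$lon, lat = x$lat) |>
    dplyr::mutate(value = as.vector(x$values)) |>
    dplyr::select("lat", "lon", "month", "value")
}

#' @rdname climatology_grid
#' @param x A `climatology_grid`.
#' @param ... Unused.
#' @export
tidy.climatology_grid <- function(x, ...) {
  dplyr::filter(as_tibble(x), !is.na(.data$value))
}

#' Bathymetry on a regular latitude-longitude grid
#'
#' @param depth Numeric `n_lat x n_lon` matrix of water depth, metres,
#'   positive downward; `NA` over land.
#' @param lat,lon As in [climatology_grid()].
#' @param land_mask Logical matrix flagging land cells; defaults to
#'   `is.na(depth)`.
#' @return A `bathymetry_grid` object.
#' @export
bathymetry_grid <- function(depth, lat, lon, land_mask = NULL) {
  depth <- as.matrix(depth)
  if (nrow(depth) != length(lat) || ncol(depth) != length(lon)) {
    abort("depth dimensions do not match lat/lon centres",
          class = "nichescape_dimension_error")
  }
  check_regular_axis(lat, "lat")
  check_regular_axis(lon, "lon")
  if (is.null(land_mask)) land_mask <- is.na(depth)
  if (any(depth[!land_mask & !is.na(depth)] < 0)) {
    abort("ocean depth must be >= 0 (positive downward)",
          class = "nichescape_format_error")
  }
  structure(list(depth = depth, lat = as.numeric(lat), lon = as.numeric(lon),
                 land_mask = land_mask),
            class = "bathymetry_grid")
}

#' @export
print.bathymetry_grid <- function(x, ...) {
  cat(sprintf("<bathymetry_grid> %d x %d cells, %.0f%% land\n",
              length(x$lat), length(x$lon), 100 * mean(x$land_mask)))
  invisible(x)
}

#' Bilinear regridding of a monthly climatology
#'
#' Interpolates each monthly layer bilinearly at the cell centres of a new
#' regular grid at `target_resolution`. Any target cell whose four-point
#' interpolation stencil touches an invalid source cell (or falls outside
#' the span of source centres) becomes invalid: no information is invented
#' near coasts or domain edges.
#'
#' @param grid A [climatology_grid()].
#' @param target_resolution Target cell size in degrees.
#' @return A `climatology_grid` on the target grid.
#' @export
regrid_linear <- function(grid, target_resolution) {
  stopifnot(inherits(grid, "climatology_grid"))
  if (!any(grid$mask)) {
    abort("cannot regrid a grid with an empty valid region",
          class = "nichescape_degenerate_input_error")
  }
  res <- grid_resolution(grid)
  new_axis <- function(centers, res_old, res_new) {
    lo <- min(centers) - res_old / 2
    hi <- max(centers) + res_old / 2
    n <- round((hi - lo) / res_new)
    if (n < 1) abort("target resolution is coarser than the domain",
                     class = "nichescape_config_error")
    seq(lo + res_new / 2, by = res_new, length.out = n)
  }
  lat2 <- new_axis(grid$lat, res["lat"], target_resolution)
  lon2 <- new_axis(grid$lon, res["lon"], target_resolution)

  locate <- function(p, centers) {
    i <- findInterval(p, centers)
    ok <- p >= centers[1] & p <= centers[length(centers)]
    i <- pmin(pmax(i, 1L), length(centers) - 1L)
    w <- (p - centers[i]) / (centers[i + 1] - centers[i])
    list(i = i, w = w, ok = ok)
  }
  la <- locate(lat2, grid$lat)
  lo <- locate(lon2, grid$lon)

  n2a <- length(lat2)
  n2o <- length(lon2)
  ii <- rep(la$i, times = n2o)
  jj <- rep(lo$i, each = n2a)
  wy <- rep(la$w, times = n2o)
  wx <- rep(lo$w, each = n2a)
  inside <- rep(la$ok, times = n2o) & rep(lo$ok, each = n2a)

  out <- array(NA_real_, c(n2a, n2o, 12))
  for (m in 1:12) {
    v <- grid$values[, , m]
    v00 <- v[cbind(ii, jj)]
    v10 <- v[cbind(ii + 1L, jj)]
    v01 <- v[cbind(ii, jj + 1L)]
    v11 <- v[cbind(ii + 1L, jj + 1L)]
    val <- (1 - wy) * (1 - wx) * v00 + wy * (1 - wx) * v10 +
      (1 - wy) * wx * v01 + wy * wx * v11
    val[!inside] <- NA_real_
    out[, , m] <- val
  }
  climatology_grid(out, lat2, lon2, variable = grid$variable,
                   units = grid$units)
}

#' Realm and depth-zone membership masks
#'
#' Splits the grid into the land realm, the pelagic (sea-surface) zones and
#' the benthic (seabed) depth bands used throughout the simulations:
#' neritic (0-200 m), shelf-edge (200-2,000 m) and deep (>2,000 m). A cell
#' whose depth equals a band boundary belongs to the shallower band
#' ("0-200 m" is read as an inclusive upper bound). Zone areas are the sum
#' of member [cell_area()]s.
#'
#' @param bathy A [bathymetry_grid()].
#' @param land_mask Optional logical land mask overriding the one in
#'   `bathy`.
#' @return A named list of `zone_mask` objects (`land`, `surface_all`,
#'   `surface_neritic`, `surface_oceanic`, `benthic_all`,
#'   `benthic_neritic`, `benthic_shelf_edge`, `benthic_deep`), each with
#'   fields `zone_id`, `member` (logical matrix) and `area_km2`.
#' @export
make_zone_masks <- function(bathy, land_mask = NULL) {
  stopifnot(inherits(bathy, "bathymetry_grid"))
  land <- land_mask %||% bathy$land_mask
  ocean <- !land & !is.na(bathy$depth)
  if (!any(ocean)) warn("grid is all land: marine zone masks are empty")
  d <- bathy$depth
  res <- c(if (length(bathy$lat) > 1) diff(bathy$lat[1:2]) else 1,
           if (length(bathy$lon) > 1) diff(bathy$lon[1:2]) else 1)
  areas <- matrix(cell_area(bathy$lat, res), nrow = length(bathy$lat),
                  ncol = length(bathy$lon))
  zone <- function(id, member) {
    structure(list(zone_id = id, member = member,
                   area_km2 = sum(areas[member])),
              class = "zone_mask")
  }
  list(
    land              = zone("land", land),
    surface_all       = zone("surface_all", ocean),
    surface_neritic   = zone("surface_neritic", ocean & d <= 200),
    surface_oceanic   = zone("surface_oceanic", ocean & d > 200),
    benthic_all       = zone("benthic_all", ocean),
    benthic_neritic   = zone("benthic_neritic", ocean & d <= 200),
    benthic_shelf_edge = zone("benthic_shelf_edge", ocean & d > 200 & d <= 2000),
    benthic_deep      = zone("benthic_deep", ocean & d > 2000)
  )
}

#' @export
print.zone_mask <- function(x, ...) {
  cat(sprintf("<zone_mask> %s: %d cells, %.4g million km2\n",
              x$zone_id, sum(x$member), x$area_km2 / 1e6))
  invisible(x)
}
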