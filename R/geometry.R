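# Spherical geometry on the simulation grid. All distances use the same
# Earth radius as the area calculations downstream so that species-range
# areas and zone areas are mutually consistent.

#' Earth radius used throughout the package (km)
#'
#' A single radius constant is used for every great-circle distance and
#' cell-area computation so that species-range areas and zone areas are
#' directly comparable.
#'
#' @format A length-one numeric, kilometres.
#' @export
earth_radius_km <- 6377.221

#' Great-circle distance between points on the globe
#'
#' Distance along the sphere of radius [earth_radius_km] between two sets
#' of coordinates, via the spherical law of cosines. Inputs are recycled
#' to a common length, so the function works both for point pairs and for
#' whole vectors of coordinates.
#'
#' @param lat1,lon1 Latitude/longitude of the first point(s), decimal degrees.
#' @param lat2,lon2 Latitude/longitude of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_distance(0, 0, 90, 0)  # a quarter meridian
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  g1 <- lat1 * pi / 180
  g2 <- lat2 * pi / 180
  g <- (lon2 - lon1) * pi / 180
  h <- acos(pmin(1, pmax(-1, sin(g1) * sin(g2) + cos(g1) * cos(g2) * cos(g))))
  earth_radius_km * h
}

#' Area of a regular latitude-longitude grid cell
#'
#' The cell is treated as the quadrilateral bounded by its edges; its area
#' is the product of the great-circle spans between the midpoints of the
#' opposite edges (zonal span at the cell's central latitude, meridional
#' span along its central meridian). Accurate to well under a percent at
#' the resolutions used here (<= 2 degrees).
#'
#' @param lat_center Latitude(s) of cell centres, decimal degrees.
#' @param resolution Cell size in degrees (one number, or `c(dlat, dlon)`).
#' @return Cell area(s) in km^2, strictly decreasing with `abs(lat_center)`.
#' @examples
#' cell_area(0, 1)
#' cell_area(c(0, 30, 60), 2)
#' @export
cell_area <- function(lat_center, resolution) {
  if (length(resolution) == 1) resolution <- c(resolution, resolution)
  dlat <- resolution[1]
  dlon <- resolution[2]
  stopifnot(all(abs(lat_center) + dlat / 2 <= 90 + 1e-9))
  zonal <- great_circle_distance(lat_center, -dlon / 2, lat_center, dlon / 2)
  merid <- great_circle_distance(lat_center - dlat / 2, 0, lat_center + dlat / 2, 0)
  zonal * merid
}

#' Light-limitation weight for seabed richness
#'
#' A beta-type unimodal response of benthic richness to annual light at the
#' seabed: zero at both ends of the tolerated range and exactly `v` at the
#' optimum. Used to down-weight richness of the light-requiring neritic
#' benthos (corals, seagrasses, mangroves) where little light reaches the
#' bottom.
#'
#' @param e Irradiance at the seabed, E m^-2 yr^-1. Values outside
#'   `[e_min, e_max]` are clipped to the range.
#' @param params A [light_weight_params()] object.
#' @return Weights in `[0, v]` (default `[0, 1]`), same shape as `e`.
#' @examples
#' light_weight(20)      # at the optimum: 1
#' light_weight(33.43)   # upper end of observed seabed light
#' @export
light_weight <- function(e, params = light_weight_params()) {
  stopifnot(inherits(params, "light_weight_params"))
  e <- pmin(params$e_max, pmax(params$e_min, e))
  expo <- (params$e_opt - params$e_min) / (params$e_max - params$e_opt)
  base <- (e - params$e_min) / (params$e_opt - params$e_min)
  params$v * ((params$e_max - e) / (params$e_max - params$e_opt)) * base^expo
}

#' Parameters of the seabed light weighting
#'
#' @param v Weight at the optimum (default 1).
#' @param e_max,e_opt,e_min Maximum, optimal and minimum irradiance
#'   (E m^-2 yr^-1); defaults 70, 20 and 0.
#' @return An object of class `light_weight_params`.
#' @export
light_weight_params <- function(v = 1, e_max = 70, e_opt = 20, e_min = 0) {
  if (!(e_min < e_opt && e_opt < e_max)) {
    abort("light weighting requires e_min < e_opt < e_max",
          class = "nichescape_config_error")
  }
  if (v <= 0) {
    abort("light weighting requires v > 0", class = "nichescape_config_error")
  }
  structure(list(v = v, e_max = e_max, e_opt = e_opt, e_min = e_min),
            class = "light_weight_params")
}
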