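# Seeded synthetic world: smooth zonal climatologies with the features
# the analysis assumes (hemispherically antiphased seasonal cycles, an
# equatorial rain belt flanked by subtropical dry belts, a meridional
# supercontinent, shelf/slope/abyss bathymetry, cold stable seabed, light
# decaying with depth). It is first-class, tested code: every downstream
# stage of the pipeline can run on it without any external data.

#' Configuration of the synthetic world
#'
#' Defaults are chosen so that the canonical contrasts of the simulation
#' emerge at 2 degree resolution: a terrestrial richness peak at the
#' equator driven jointly by temperature and precipitation, and a marine
#' surface richness peak in the 20-40 degree bands with a local equatorial
#' dip driven by temperature alone.
#'
#' @param n_lat,n_lon Grid size; `resolution * n_lat` must span
#'   `lat_range` exactly and longitudes always span 360 degrees.
#' @param lat_range Latitude span, degrees (default -90..90).
#' @param resolution Degrees per latitude cell.
#' @param seed Master RNG seed; per-variable noise seeds derive from it.
#' @param sst_eq,sst_pole Annual-mean sea-surface temperature at the
#'   equator and the poles (degC).
#' @param seasonal_amp_pole Seasonal half-amplitude of SST at the poles
#'   (degC); zero at the equator, growing linearly with `abs(lat)`.
#' @param land_temp_eq,land_temp_pole,land_seasonal_amp_pole Same three
#'   controls for air temperature over land.
#' @param precip_eq Peak monthly precipitation of the equatorial rain belt
#'   (mm).
#' @param precip_subtrop Background monthly precipitation at the
#'   subtropical dry-belt minimum (mm); must be `< precip_eq`.
#' @param dry_belt_lat Latitude (degrees) near which the zonal-mean
#'   precipitation has its subtropical local minima.
#' @param midlat_wet Amplitude (mm) of the secondary midlatitude storm
#'   track wet band.
#' @param precip_seasonal_frac Relative seasonal modulation of land
#'   precipitation (0 disables it).
#' @param land_fraction Fraction of longitude columns covered by the
#'   meridional supercontinent (so land spans all latitudes).
#' @param shelf_width_cells Width of the continental shelf, cells.
#' @param max_depth Abyssal depth, metres.
#' @param photic_cutoff_m Depth below which seabed light is exactly zero.
#' @param light_atten_per_m Exponential decay rate of light with depth.
#' @param light_surface_max Surface irradiance at the equator
#'   (E m^-2 yr^-1); seabed light is clipped to `[0, light_surface_max]`.
#' @param noise_sd Standard deviation of the seeded spatial noise added to
#'   each variable. The noise field is drawn once per variable and added
#'   to all 12 monthly layers, so switching seasonality off leaves the
#'   twelve layers bit-identical.
#' @return A `world_config` object.
#' @export
world_config <- function(n_lat = 90, n_lon = 180, lat_range = c(-90, 90),
                         resolution = 2, seed = 1,
                         sst_eq = 29, sst_pole = -1.8, seasonal_amp_pole = 8,
                         land_temp_eq = 30, land_temp_pole = -25,
                         land_seasonal_amp_pole = 18,
                         precip_eq = 250, precip_subtrop = 25,
                         dry_belt_lat = 25, midlat_wet = 80,
                         precip_seasonal_frac = 0.25,
                         land_fraction = 0.3, shelf_width_cells = 3,
                         max_depth = 4500,
                         photic_cutoff_m = 200, light_atten_per_m = 0.04,
                         light_surface_max = 33.43,
                         noise_sd = 0.5) {
  cfg <- as.list(environment())
  if (n_lat < 1 || n_lon < 1) {
    abort("grid sizes must be positive", class = "nichescape_config_error")
  }
  if (abs(resolution * n_lat - diff(lat_range)) > 1e-9) {
    abort("resolution * n_lat must span lat_range exactly",
          class = "nichescape_config_error")
  }
  if (precip_eq <= precip_subtrop) {
    abort("precip_eq must exceed precip_subtrop",
          class = "nichescape_config_error")
  }
  if (land_fraction < 0 || land_fraction > 1) {
    abort("land_fraction must be in [0, 1]",
          class = "nichescape_config_error")
  }
  structure(cfg, class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf("<world_config> %d x %d cells at %g deg, seed %d\n",
              x$n_lat, x$n_lon, x$resolution, x$seed))
  invisible(x)
}

#' Generate the synthetic world
#'
#' Deterministic for a fixed configuration (the master seed drives one
#' spatial noise field per variable). Monthly SST and land temperature are
#' a zonal annual-mean profile plus a seasonal term whose sign flips
#' between hemispheres (northern maximum in July, southern in January) and
#' whose amplitude grows from zero at the equator to its polar value.
#' Monthly precipitation combines an equatorial rain belt, subtropical dry
#' belts near `dry_belt_lat` and a midlatitude wet band. Bathymetry is
#' monotone from the coast (0 m) across the shelf (<200 m) and shelf edge
#' (200-2,000 m) to the abyss; the seabed is cold and nearly aseasonal at
#' depth, and seabed light decays exponentially with depth, clipped to
#' `[0, light_surface_max]` and exactly zero below the photic cutoff.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world`: climatology grids `sst`, `land_temp`,
#'   `precip` (land only), `seabed_temp`, `seabed_light` (ocean only), a
#'   [bathymetry_grid()] and the logical `land_mask`, all sharing one
#'   geometry.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  res <- cfg$resolution
  lat <- seq(cfg$lat_range[1] + res / 2, by = res, length.out = cfg$n_lat)
  res_lon <- 360 / cfg$n_lon
  lon <- seq(-180 + res_lon / 2, by = res_lon, length.out = cfg$n_lon)
  nla <- cfg$n_lat
  nlo <- cfg$n_lon

  # meridional supercontinent centred on lon 0 so land exists at all lats
  n_land_cols <- round(cfg$land_fraction * nlo)
  land_cols <- if (n_land_cols > 0) {
    order(abs(lon))[seq_len(n_land_cols)]
  } else integer(0)
  land <- matrix(FALSE, nla, nlo)
  land[, land_cols] <- TRUE

  latm <- matrix(lat, nla, nlo)
  frac <- abs(latm) / 90
  noise <- function(offset) {
    withr_seed(cfg$seed + offset,
               matrix(rnorm(nla * nlo, sd = cfg$noise_sd), nla, nlo))
  }
  seasonal <- function(amp, month) {
    sign <- ifelse(latm >= 0, 1, -1)
    amp * sign * cos(2 * pi * (month - 7) / 12)
  }
  monthly <- function(base, amp, noise_field, mask) {
    arr <- array(NA_real_, c(nla, nlo, 12))
    for (m in 1:12) {
      layer <- base + seasonal(amp, m) + noise_field
      layer[!mask] <- NA_real_
      arr[, , m] <- layer
    }
    arr
  }

  ocean <- !land
  sst_base <- cfg$sst_pole + (cfg$sst_eq - cfg$sst_pole) * (1 - frac)
  sst <- climatology_grid(
    monthly(sst_base, cfg$seasonal_amp_pole * frac, noise(1), ocean),
    lat, lon, variable = "sst", units = "degC")

  lt_base <- cfg$land_temp_pole + (cfg$land_temp_eq - cfg$land_temp_pole) * (1 - frac)
  land_temp <- climatology_grid(
    monthly(lt_base, cfg$land_seasonal_amp_pole * frac, noise(2), land),
    lat, lon, variable = "land_temp", units = "degC")

  # zonal precipitation: equatorial peak, dry belts near dry_belt_lat,
  # midlatitude wet band; widths scale with the dry-belt latitude
  w_eq <- cfg$dry_belt_lat * 0.48
  mid_ctr <- cfg$dry_belt_lat + 20
  p_base <- cfg$precip_subtrop +
    cfg$precip_eq * exp(-(latm / w_eq)^2) +
    cfg$midlat_wet * exp(-((abs(latm) - mid_ctr) / 12)^2)
  p_noise <- noise(3) * 4  # mm-scale noise
  p_arr <- array(NA_real_, c(nla, nlo, 12))
  samp <- cfg$precip_seasonal_frac * pmin(abs(latm) / 30, 1)
  for (m in 1:12) {
    sgn <- ifelse(latm >= 0, 1, -1)
    layer <- p_base * (1 + samp * sgn * cos(2 * pi * (m - 7) / 12)) + p_noise
    layer <- pmax(layer, 0)
    layer[!land] <- NA_real_
    p_arr[, , m] <- layer
  }
  precip <- climatology_grid(p_arr, lat, lon, variable = "precip",
                             units = "mm/month")

  # bathymetry: zonal distance (in cells, cyclic) to the continent
  depth <- matrix(0, nla, nlo)
  if (length(land_cols) > 0 && length(land_cols) < nlo) {
    dist_cells <- vapply(seq_len(nlo), function(j) {
      dd <- abs(j - land_cols)
      min(pmin(dd, nlo - dd))
    }, numeric(1))
    slope_cells <- 3
    prof <- vapply(dist_cells, function(d) {
      if (d == 0) return(NA_real_)
      if (d <= cfg$shelf_width_cells) return(200 * d / cfg$shelf_width_cells)
      extra <- min((d - cfg$shelf_width_cells) / slope_cells, 1)
      200 + (cfg$max_depth - 200) * extra
    }, numeric(1))
    depth <- matrix(prof, nla, nlo, byrow = TRUE)
  } else if (length(land_cols) == 0) {
    depth <- matrix(cfg$max_depth, nla, nlo)
  } else {
    depth <- matrix(NA_real_, nla, nlo)
  }
  depth[land] <- NA_real_
  bathy <- bathymetry_grid(depth, lat, lon, land_mask = land)

  # seabed: cold, nearly aseasonal at depth
  deep_temp <- 2
  atten <- exp(-ifelse(is.na(depth), 0, depth) / 500)
  sb_base <- deep_temp + (sst_base - deep_temp) * atten
  sb_amp <- cfg$seasonal_amp_pole * frac * exp(-ifelse(is.na(depth), 0, depth) / 150)
  sb_arr <- array(NA_real_, c(nla, nlo, 12))
  sb_noise <- noise(4) * 0.2
  for (m in 1:12) {
    layer <- sb_base + seasonal(1, m) * sb_amp + sb_noise
    layer[!ocean] <- NA_real_
    sb_arr[, , m] <- layer
  }
  seabed_temp <- climatology_grid(sb_arr, lat, lon,
                                  variable = "seabed_temp", units = "degC")

  e0 <- cfg$light_surface_max * cos(latm * pi / 180)
  light <- e0 * exp(-cfg$light_atten_per_m * ifelse(is.na(depth), 0, depth))
  light <- pmin(pmax(light, 0), cfg$light_surface_max)
  light[!is.na(depth) & depth > cfg$photic_cutoff_m] <- 0
  l_arr <- array(NA_real_, c(nla, nlo, 12))
  for (m in 1:12) {
    layer <- light
    layer[!ocean] <- NA_real_
    l_arr[, , m] <- layer
  }
  seabed_light <- climatology_grid(l_arr, lat, lon,
                                   variable = "seabed_light",
                                   units = "E m-2 yr-1")

  structure(
    list(sst = sst, land_temp = land_temp, precip = precip,
         seabed_temp = seabed_temp, seabed_light = seabed_light,
         bathymetry = bathy, land_mask = land, lat = lat, lon = lon,
         config = cfg),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells at %g deg, %.0f%% land, seed %d\n",
              length(x$lat), length(x$lon), x$config$resolution,
              100 * mean(x$land_mask), x$config$seed))
  invisible(x)
}

#' Pseudo-observed richness grid for validation exercises
#'
#' Adds seeded Gaussian noise to a modeled richness map (truncated at
#' zero), standing in for an independent observational richness layer so
#' the correlation machinery can be exercised against known ground truth.
#'
#' @param world A [generate_world()] result (defines the geometry).
#' @param model_richness A [richness_field] or a richness matrix on the
#'   world geometry.
#' @param noise_sd Noise standard deviation, richness units.
#' @param seed Integer seed.
#' @return Matrix of noisy richness, `NA` where the model is undefined.
#' @export
generate_observed_richness <- function(world, model_richness, noise_sd, seed) {
  mat <- if (inherits(model_richness, "richness_field")) {
    model_richness$annual
  } else {
    as.matrix(model_richness)
  }
  if (nrow(mat) != length(world$lat) || ncol(mat) != length(world$lon)) {
    abort("model richness is not on the world geometry",
          class = "nichescape_dimension_error")
  }
  out <- withr_seed(seed, mat + rnorm(length(mat), sd = noise_sd))
  out <- pmax(out, 0)
  out[is.na(mat)] <- NA_real_
  out
}
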