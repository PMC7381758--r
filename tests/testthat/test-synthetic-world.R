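test_that("worlds are bit-identical for a fixed seed and differ otherwise", {
  w1 <- small_world(seed = 7)
  w2 <- small_world(seed = 7)
  expect_identical(w1$sst$values, w2$sst$values)
  expect_identical(w1$precip$values, w2$precip$values)
  expect_identical(w1$bathymetry$depth, w2$bathymetry$depth)
  w3 <- small_world(seed = 8)
  expect_false(identical(w1$sst$values, w3$sst$values))
})

test_that("switching seasonality off freezes the monthly cycle", {
  w <- small_world(seasonal_amp_pole = 0, land_seasonal_amp_pole = 0,
                   precip_seasonal_frac = 0)
  for (g in list(w$sst, w$land_temp, w$precip)) {
    for (m in 2:12) expect_identical(g$values[, , m], g$values[, , 1])
  }
})

test_that("seasonal cycles are hemispherically antiphased and vanish at the equator", {
  w <- generate_world(world_config(n_lat = 45, n_lon = 90, resolution = 4,
                                   noise_sd = 0))
  sstm <- w$sst$values
  nh <- which.max(w$lat)   # northernmost row
  sh <- which.min(w$lat)
  july_nh <- mean(sstm[nh, , 7], na.rm = TRUE) - mean(sstm[nh, , 1], na.rm = TRUE)
  july_sh <- mean(sstm[sh, , 7], na.rm = TRUE) - mean(sstm[sh, , 1], na.rm = TRUE)
  expect_gt(july_nh, 0)
  expect_lt(july_sh, 0)
  eq <- which.min(abs(w$lat))
  ocean_col <- which(!w$land_mask[eq, ])[1]
  expect_lt(diff(range(sstm[eq, ocean_col, ])), 1e-9)
})

test_that("zonal precipitation has an equatorial peak and subtropical dry belts", {
  w <- generate_world()
  zonal <- function(m) {
    vapply(seq_along(w$lat),
           function(i) mean(w$precip$values[i, , m], na.rm = TRUE),
           numeric(1))
  }
  july <- zonal(7)
  at <- function(prof, l) prof[which.min(abs(w$lat - l))]
  expect_gt(at(july, 0), at(july, 25))
  annual <- rowMeans(vapply(1:12, zonal, numeric(length(w$lat))))
  expect_lte(abs(w$lat[which.max(annual)]), 10)
  dry <- w$config$dry_belt_lat
  for (sgn in c(-1, 1)) {
    expect_lt(at(annual, sgn * dry), at(annual, 0))
    expect_lt(at(annual, sgn * dry), at(annual, sgn * (dry + 20)))
  }
})

test_that("bathymetry deepens monotonically away from the coast and fills all bands", {
  w <- generate_world()
  z <- make_zone_masks(w$bathymetry)
  expect_gt(sum(z$benthic_neritic$member), 0)
  expect_gt(sum(z$benthic_shelf_edge$member), 0)
  expect_gt(sum(z$benthic_deep$member), 0)
  # walking east from the continent's east coast, depth never decreases
  row <- which.min(abs(w$lat))
  land_cols <- which(w$land_mask[row, ])
  east <- max(land_cols)
  run <- w$bathymetry$depth[row, (east + 1):min(east + 8, length(w$lon))]
  expect_true(all(diff(run) >= 0))
})

test_that("seabed light decays with depth, is clipped, and is dark below the photic cutoff", {
  w <- generate_world()
  light <- w$seabed_light$values[, , 1]
  depth <- w$bathymetry$depth
  ok <- !is.na(light)
  expect_true(all(light[ok] >= 0))
  expect_true(all(light[ok] <= w$config$light_surface_max + 1e-12))
  expect_true(all(light[ok & depth > w$config$photic_cutoff_m] == 0))
  # shallower cells receive at least as much light along a latitude row
  row <- which.min(abs(w$lat))
  shallow <- which(!is.na(depth[row, ]) & depth[row, ] <= 200)
  deep <- which(!is.na(depth[row, ]) & depth[row, ] > 2000)
  expect_gt(min(light[row, shallow]), max(light[row, deep]))
})

test_that("fields share one geometry and respect the land/ocean masks", {
  w <- small_world()
  for (g in list(w$sst, w$land_temp, w$precip, w$seabed_temp,
                 w$seabed_light)) {
    expect_identical(g$lat, w$lat)
    expect_identical(g$lon, w$lon)
  }
  expect_true(all(is.na(w$land_temp$values[, , 1][!w$land_mask])))
  expect_true(all(!is.na(w$precip$values[, , 1][w$land_mask])))
  expect_true(all(is.na(w$sst$values[, , 1][w$land_mask])))
  expect_true(all(!is.na(w$sst$values[, , 1][!w$land_mask])))
})

test_that("pseudo-observed richness is model + truncated seeded noise", {
  w <- small_world()
  z <- make_zone_masks(w$bathymetry)
  pool <- sample_pool(build_axis_niches(thermal_axis_spec()), 0.02, seed = 2)
  f <- richness_field(pool, w$sst, zone = z$surface_all,
                      compute_union = FALSE)
  obs0 <- generate_observed_richness(w, f, noise_sd = 0, seed = 1)
  expect_equal(obs0, f$annual)
  expect_equal(correlate_maps(f, obs0)$r, 1)
  obs1 <- generate_observed_richness(w, f, noise_sd = 1, seed = 1)
  obs1b <- generate_observed_richness(w, f, noise_sd = 1, seed = 1)
  expect_identical(obs1, obs1b)
  # noise far above the signal range attenuates the correlation
  big <- 20 * stats::sd(f$annual, na.rm = TRUE)
  obs2 <- generate_observed_richness(w, f, noise_sd = big, seed = 3)
  expect_lt(correlate_maps(f, obs2)$r, 0.5)
  expect_error(generate_observed_richness(w, matrix(0, 2, 2), 1, 1),
               class = "nichescape_dimension_error")
})

test_that("invalid world configurations are rejected", {
  expect_error(world_config(n_lat = 0), class = "nichescape_config_error")
  expect_error(world_config(n_lat = 10, resolution = 1),
               class = "nichescape_config_error")
  expect_error(world_config(precip_eq = 10, precip_subtrop = 20),
               class = "nichescape_config_error")
})
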