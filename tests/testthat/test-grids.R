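test_that("climatology grids enforce 12 complete monthly layers", {
  expect_error(climatology_grid(array(0, c(2, 2, 11)), 1:2, 1:2),
               class = "nichescape_format_error")
  arr <- array(1, c(2, 2, 12))
  arr[1, 1, 3] <- NA  # partial month: whole cell becomes invalid
  g <- climatology_grid(arr, c(0, 2), c(0, 2))
  expect_false(g$mask[1, 1])
  expect_true(all(is.na(g$values[1, 1, ])))
  expect_error(climatology_grid(array(0, c(3, 2, 12)), c(0, 1, 3), c(0, 2)),
               class = "nichescape_unsupported_grid_error")
})

test_that("climatology CSV round-trips are lossless including the mask", {
  w <- small_world()
  path <- withr::local_tempfile(fileext = ".csv")
  write_climatology_csv(w$sst, path)
  back <- read_climatology_csv(path)
  expect_equal(back$values, w$sst$values)
  expect_identical(back$mask, w$sst$mask)
  expect_equal(back$lat, w$sst$lat)
  expect_equal(back$variable, "sst")
  expect_equal(back$units, "degC")
})

test_that("a hand-written 3x3 CSV fixture loads with its values", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- tidyr::expand_grid(lat = c(-10, 0, 10), lon = c(0, 10, 20),
                            month = 1:12) |>
    dplyr::mutate(value = lat + lon / 100 + month / 1000)
  writeLines(c("# variable: toy", "# units: degC"), path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  g <- read_climatology_csv(path)
  expect_equal(dim(g$values), c(3, 3, 12))
  expect_equal(g$values[2, 3, 5], 0 + 20 / 100 + 5 / 1000)
  # a truncated file with 11 months is a format error
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::filter(tab, month < 12), path2)
  expect_error(read_climatology_csv(path2),
               class = "nichescape_format_error")
})

test_that("bilinear regridding preserves constants and linear fields", {
  arr <- array(3.5, c(10, 10, 12))
  g <- climatology_grid(arr, seq(-45, 45, by = 10), seq(-45, 45, by = 10))
  fine <- regrid_linear(g, 5)
  expect_true(all(abs(fine$values[fine$mask] - 3.5) < 1e-12))
  lin <- array(rep(seq(-45, 45, by = 10) * 2, 10 * 12), c(10, 10, 12))
  gl <- climatology_grid(lin, seq(-45, 45, by = 10), seq(-45, 45, by = 10))
  fl <- regrid_linear(gl, 5)
  expect_equal(fl$values[cbind(5, 3, 1)], fl$lat[5] * 2)
  # a stencil touching an invalid source cell goes invalid
  arr2 <- arr
  arr2[5, 5, ] <- NA
  g2 <- climatology_grid(arr2, seq(-45, 45, by = 10), seq(-45, 45, by = 10))
  f2 <- regrid_linear(g2, 5)
  touched <- f2$lat > g2$lat[4] & f2$lat < g2$lat[6]
  expect_true(any(!f2$mask[touched, ]))
  empty <- climatology_grid(array(NA_real_, c(3, 3, 12)), 1:3, 1:3)
  expect_error(regrid_linear(empty, 0.5),
               class = "nichescape_degenerate_input_error")
})

test_that("depth-band zone masks follow the shallower-band tie rule and partition", {
  depth <- matrix(c(150, 200, 2000, 2500, NA, 0), 2, 3)
  bathy <- bathymetry_grid(depth, c(0, 2), c(0, 2, 4))
  z <- make_zone_masks(bathy)
  expect_true(z$benthic_neritic$member[1, 1])   # 150 m
  expect_true(z$surface_neritic$member[1, 1])
  expect_true(z$benthic_neritic$member[2, 1])   # exactly 200 m
  expect_false(z$benthic_shelf_edge$member[2, 1])
  expect_true(z$benthic_shelf_edge$member[1, 2]) # exactly 2000 m
  expect_true(z$benthic_deep$member[2, 2])      # 2500 m
  expect_true(z$surface_oceanic$member[2, 2])
  expect_true(z$land$member[1, 3])
  # partition invariants
  expect_identical(z$surface_neritic$member | z$surface_oceanic$member,
                   z$surface_all$member)
  benthic_sum <- z$benthic_neritic$member + z$benthic_shelf_edge$member +
    z$benthic_deep$member
  expect_true(all(benthic_sum[z$benthic_all$member] == 1))
  expect_true(all(benthic_sum[!z$benthic_all$member] == 0))
  all_land <- bathymetry_grid(matrix(NA_real_, 2, 2), c(0, 2), c(0, 2),
                              land_mask = matrix(TRUE, 2, 2))
  expect_warning(make_zone_masks(all_land), "all land")
})

test_that("the light weighting is the printed beta response", {
  expect_equal(light_weight(20), 1)
  expect_equal(light_weight(0), 0)
  expect_equal(light_weight(70), 0)
  expect_equal(light_weight(33.43), 0.898, tolerance = 1e-3)
  # unimodal with its maximum at e_opt
  e <- seq(0, 70, length.out = 701)
  w <- light_weight(e)
  expect_equal(e[which.max(w)], 20)
  expect_true(all(diff(w[e <= 20]) >= 0))
  expect_true(all(diff(w[e >= 20]) <= 0))
  # out-of-range irradiance is clipped, not extrapolated
  expect_equal(light_weight(-5), 0)
  expect_equal(light_weight(100), 0)
  expect_error(light_weight_params(e_opt = 80),
               class = "nichescape_config_error")
  expect_error(light_weight_params(v = 0),
               class = "nichescape_config_error")
})

test_that("great-circle distances use the fixed Earth radius", {
  expect_equal(great_circle_distance(10, 20, 10, 20), 0, tolerance = 1e-3)
  expect_equal(great_circle_distance(0, 0, 90, 0),
               earth_radius_km * pi / 2, tolerance = 1e-10)
  expect_equal(great_circle_distance(0, 10, 0, 20),
               great_circle_distance(0, 50, 0, 60))
  expect_equal(great_circle_distance(12, 34, -45, 101),
               great_circle_distance(-45, 101, 12, 34))
})

test_that("cell areas shrink with latitude and tile the sphere", {
  expect_lt(cell_area(60, 1), cell_area(0, 1))
  expect_equal(cell_area(0, 1), (earth_radius_km * pi / 180)^2,
               tolerance = 1e-4)
  lats <- seq(-85, 85, by = 10)
  total <- sum(cell_area(lats, 10)) * 36
  expect_equal(total, 4 * pi * earth_radius_km^2, tolerance = 0.02)
  expect_true(all(diff(cell_area(seq(0, 80, 10), 2)) < 0))
})
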