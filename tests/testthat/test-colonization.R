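test_that("single-cell colonization matches hand enumeration of the toy pool", {
  toy <- toy_pool()
  f6 <- richness_field(toy, constant_cell_grid(rep(6, 12)))
  expect_equal(f6$monthly[1, 1, ], rep(5, 12))
  expect_equal(f6$annual[1, 1], 5)
  expect_equal(f6$union[1, 1], 5)
  # months alternating between 1 (3 niches) and 6 (5 niches)
  falt <- richness_field(toy, constant_cell_grid(rep(c(1, 6), 6)))
  expect_equal(falt$annual[1, 1], (6 * 3 + 6 * 5) / 12)
  expect_equal(falt$union[1, 1], 6)
  # strict residency keeps only niches covering both values
  fall <- richness_field(toy, constant_cell_grid(rep(c(1, 6), 6)),
                         policy = "all_months")
  expect_equal(fall$annual[1, 1], 2)
})

test_that("an empty pool yields an all-zero field", {
  toy <- toy_pool()
  toy$niches <- toy$niches[0, ]
  f <- richness_field(toy, constant_cell_grid(rep(6, 12)))
  expect_equal(f$annual[1, 1], 0)
  expect_equal(f$union[1, 1], 0)
})

test_that("richness fields agree with the naive triple-loop oracle", {
  set.seed(99)
  for (k in 1:30) {
    spec <- random_small_spec()
    pool <- build_axis_niches(spec)
    if (nrow(pool$niches) > 60) {
      pool <- sample_pool(pool, 60 / nrow(pool$niches), seed = k)
    }
    nr <- sample(2:6, 1)
    nc <- sample(2:6, 1)
    V <- matrix(runif(nr * nc * 12, spec$rho_min - 2, spec$rho_max + 2),
                nr * nc, 12)
    f <- richness_field(pool, grid_from_values(V, nr, nc))
    oracle <- naive_richness(pool$niches, V)
    for (m in 1:12) {
      expect_equal(as.vector(f$monthly[, , m]), oracle$monthly[, m])
    }
    expect_equal(as.vector(f$union), oracle$union)
  }
})

test_that("the separable product fast path equals direct evaluation", {
  spec_p <- niche_axis_spec("precipitation", 0, 300, 100, 100, 150)
  prod <- build_product_pool(toy_spec(), spec_p)
  mat <- sample_pool(prod, 1)  # materialized: generic chunked path
  nr <- 4; nc <- 5
  Vt <- matrix(runif(nr * nc * 12, -2, 12), nr * nc, 12)
  Vp <- matrix(runif(nr * nc * 12, 0, 350), nr * nc, 12)
  climate <- list(temperature = grid_from_values(Vt, nr, nc),
                  precipitation = grid_from_values(Vp, nr, nc))
  f_lazy <- richness_field(prod, climate)
  f_mat <- richness_field(mat, climate)
  expect_equal(f_lazy$monthly, f_mat$monthly)
  expect_equal(f_lazy$annual, f_mat$annual)
  expect_null(f_lazy$union)          # union is not separable
  expect_false(is.null(f_mat$union))
})

test_that("adding niches never decreases richness anywhere", {
  set.seed(17)
  spec <- niche_axis_spec("temperature", 0, 20, 2, 2, 2)
  pool <- build_axis_niches(spec)
  small <- pool; small$niches <- pool$niches[1:20, ]
  V <- matrix(runif(25 * 12, -1, 22), 25, 12)
  g <- grid_from_values(V, 5, 5)
  f_small <- richness_field(small, g)
  f_big <- richness_field(pool, g)
  expect_true(all(f_big$monthly >= f_small$monthly))
  expect_true(all(f_big$annual >= f_small$annual))
  expect_true(all(f_big$union >= f_small$union))
})

test_that("strict residency is a subset of per-month presence", {
  set.seed(31)
  spec <- niche_axis_spec("temperature", 0, 20, 2, 2, 2)
  pool <- build_axis_niches(spec)
  V <- matrix(runif(16 * 12, -1, 22), 16, 12)
  g <- grid_from_values(V, 4, 4)
  f_any <- richness_field(pool, g)
  f_all <- richness_field(pool, g, policy = "all_months")
  expect_true(all(f_all$union <= f_any$union))
  expect_true(all(f_all$monthly <= f_any$monthly))
})

test_that("richness peaks where the climate crosses the niche-domain midpoint", {
  # aseasonal SST rising linearly with latitude through the pool midpoint
  spec <- niche_axis_spec("temperature", 0, 20, 2, 2, 2)
  pool <- build_axis_niches(spec)
  nlat <- 41
  lat <- seq(-40, 40, length.out = nlat)
  sst <- seq(0, 20, length.out = nlat)
  V <- matrix(rep(sst, 3 * 12), nlat * 3, 12)
  g <- grid_from_values(V, nlat, 3, lat = lat,
                        lon = c(-10, 0, 10))
  f <- richness_field(pool, g, compute_union = FALSE)
  peak_lat <- lat[which.max(f$annual[, 1])]
  expect_equal(sst[which(lat == peak_lat)], 10)
})

test_that("light weighting scales annual richness through the beta response", {
  toy <- toy_pool()
  f <- richness_field(toy, constant_cell_grid(rep(6, 12)))
  mk_light <- function(e) climatology_grid(array(e, c(1, 1, 12)), 0, 0,
                                           variable = "seabed_light")
  expect_equal(weighted_richness(f, mk_light(20))[1, 1], f$annual[1, 1])
  expect_equal(weighted_richness(f, mk_light(0))[1, 1], 0)
  f10 <- f; f10$annual[1, 1] <- 10
  expect_equal(weighted_richness(f10, mk_light(33.43))[1, 1], 8.98,
               tolerance = 1e-3)
})

test_that("mismatched climate inputs are configuration errors", {
  toy <- toy_pool()
  prod <- build_product_pool(toy_spec(),
                             niche_axis_spec("precipitation", 0, 300, 100, 100, 150))
  g <- constant_cell_grid(rep(6, 12))
  expect_error(richness_field(prod, g), class = "nichescape_config_error")
  expect_error(richness_field(toy, list(a = g, b = g)),
               class = "nichescape_config_error")
  g2 <- climatology_grid(array(6, c(2, 1, 12)), c(0, 2), 0)
  expect_error(richness_field(prod, list(temperature = g,
                                         precipitation = g2)),
               class = "nichescape_config_error")
})
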