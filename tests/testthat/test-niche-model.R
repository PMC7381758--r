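test_that("amplitude sequences follow the exact integer construction", {
  expect_equal(max(build_amplitudes(thermal_axis_spec())), 45.8)
  expect_equal(build_amplitudes(precipitation_axis_spec()),
               seq(100, 3000, by = 100))
  expect_equal(build_amplitudes(toy_spec()), c(2, 6, 10))
})

test_that("axis enumeration reproduces the published pool counts", {
  expect_equal(nrow(build_axis_niches(precipitation_axis_spec())$niches), 930)
  expect_equal(
    nrow(build_axis_niches(precipitation_axis_spec(mu = 400, s = 200))$niches),
    72)
  toy <- toy_pool()
  expect_equal(nrow(toy$niches), 7)
  expect_equal(toy$niches$x, c(0, 5, 10, 0, 5, 0, 5))
  expect_equal(toy$niches$y, c(2, 7, 12, 6, 11, 10, 15))
})

test_that("enumerated counts equal the closed form for random specs", {
  set.seed(41)
  for (k in 1:25) {
    spec <- random_small_spec()
    tab <- build_axis_niches(spec)$niches
    it <- spec$int
    amax <- it$rho_max - it$rho_min
    a <- seq(it$alpha_1, amax, by = it$mu)
    expect_equal(nrow(tab), sum((amax + it$s - a) %/% it$s + 1))
    # Gause uniqueness: no two niches share an interval
    expect_false(any(duplicated(tab[, c("x", "alpha")])))
    # ends may overshoot rho_max but never by more than s
    expect_true(all(tab$y <= spec$rho_max + spec$s))
  }
})

test_that("product pools multiply axis counts and stay lazy", {
  prod <- build_product_pool(thermal_axis_spec(), precipitation_axis_spec())
  expect_equal(prod$R_full, 101474 * 930)
  expect_null(prod$niches)
  toy2 <- build_product_pool(toy_spec(),
                             niche_axis_spec("precipitation", 0, 300, 100, 100, 150))
  expect_equal(toy2$R_full, 7 * nrow(build_axis_niches(
    niche_axis_spec("precipitation", 0, 300, 100, 100, 150))$niches))
  one <- build_axis_niches(toy_spec())
  expect_equal(one$R_full, nrow(one$niches))
})

test_that("pool sampling is seeded, size-exact and records phi", {
  pool <- build_axis_niches(precipitation_axis_spec())
  full <- sample_pool(pool, 1)
  expect_equal(nrow(full$niches), 930)
  expect_equal(full$phi, 1)
  s1 <- sample_pool(pool, 0.25, seed = 11)
  s2 <- sample_pool(pool, 0.25, seed = 11)
  expect_identical(s1$niches, s2$niches)
  expect_equal(nrow(s1$niches), round(930 * 0.25))
  expect_equal(s1$phi, 4)
  s3 <- sample_pool(pool, 0.25, seed = 12)
  expect_false(identical(s1$niches, s3$niches))
  # product pools materialize by global index
  prod <- build_product_pool(toy_spec(),
                             niche_axis_spec("precipitation", 0, 300, 100, 100, 150))
  sp <- sample_pool(prod, 0.5, seed = 3)
  expect_equal(nrow(sp$niches), round(prod$R_full * 0.5))
  expect_true(all(c("x_temperature", "x_precipitation") %in% names(sp$niches)))
  expect_error(sample_pool(pool, 0), class = "nichescape_config_error")
  expect_error(sample_pool(pool, 1.2), class = "nichescape_config_error")
})

test_that("niche membership uses closed intervals on every axis", {
  toy <- toy_pool()
  expect_equal(sum(niche_contains(toy, 6)), 5)
  expect_equal(sum(niche_contains(toy, -3)), 0)
  expect_true(niche_contains(toy, 2)[1])   # value exactly at an end
  expect_equal(count_containing(toy, c(1, 6)), c(3L, 5L))
  prod <- sample_pool(build_product_pool(toy_spec(),
    niche_axis_spec("precipitation", 0, 300, 100, 100, 150)), 1)
  hits <- niche_contains(prod, c(temperature = 6, precipitation = 50))
  direct <- prod$niches$x_temperature <= 6 & prod$niches$y_temperature >= 6 &
    prod$niches$x_precipitation <= 50 & prod$niches$y_precipitation >= 50
  expect_equal(hits, direct)
})

test_that("containment counts peak at the climatic mid-domain", {
  # strict midpoint maximality for the pools whose midpoint lies on the
  # start lattice (the toy and both published parameter families)
  for (spec in list(toy_spec(), precipitation_axis_spec(),
                    precipitation_axis_spec(mu = 400, s = 200))) {
    pool <- build_axis_niches(spec)
    mid <- (spec$rho_min + spec$rho_max) / 2
    grid <- seq(spec$rho_min, spec$rho_max, length.out = 101)
    expect_gte(count_containing(pool, mid), max(count_containing(pool, grid)))
  }
})

test_that("containment counts are symmetric about the construction centre", {
  # the invariant behind the mid-domain effect: for lattice-commensurate
  # specs the interval family is symmetric about (rho_min+rho_max+s)/2
  set.seed(5)
  for (k in 1:8) {
    spec <- random_symmetric_spec()
    pool <- build_axis_niches(spec)
    centre <- (spec$rho_min + spec$rho_max + spec$s) / 2
    v <- seq(spec$rho_min, spec$rho_max, by = spec$s)
    expect_equal(count_containing(pool, v),
                 count_containing(pool, 2 * centre - v))
  }
})

test_that("invalid axis specifications are rejected", {
  expect_error(niche_axis_spec("temperature", 5, 5, 1, 1, 1),
               class = "nichescape_config_error")
  expect_error(niche_axis_spec("temperature", 0, 10, 0, 1, 1),
               class = "nichescape_config_error")
  expect_error(niche_axis_spec("temperature", 0, 10, 11, 1, 1),
               class = "nichescape_config_error")
})
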