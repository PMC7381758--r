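# Combinatorial construction of rectangular climatic niches. All
# amplitude/start arithmetic runs on integer multiples of a base unit
# (0.1 degC, 1 mm by default) because the floor operations in the
# counting formulas are sensitive to accumulated floating point; exact
# arithmetic makes the pool counts reproducible bit for bit.

#' Specification of one niche axis
#'
#' Defines the tolerance-interval family on a single climatic axis: all
#' rectangular niches with amplitudes `alpha_1, alpha_1 + mu, ...` up to
#' the domain width, each slid along the axis in steps of `s` starting at
#' `rho_min`. Interval ends may overshoot `rho_max` by construction; such
#' niches are retained (the published pool counts require them).
#'
#' @param axis_id `"temperature"` or `"precipitation"`.
#' @param rho_min,rho_max Domain bounds (degC or mm).
#' @param alpha_1 Smallest niche amplitude.
#' @param mu Amplitude increment.
#' @param s Start (overlap) step.
#' @param unit Base unit for exact integer arithmetic; by default the
#'   smallest power of ten that makes every parameter an integer multiple.
#' @return A `niche_axis_spec` object.
#' @examples
#' thermal_axis_spec()
#' niche_axis_spec("precipitation", 0, 3000, 100, 100, 50)
#' @export
niche_axis_spec <- function(axis_id, rho_min, rho_max, alpha_1, mu, s,
                            unit = NULL) {
  axis_id <- match.arg(axis_id, c("temperature", "precipitation"))
  vals <- c(rho_min = rho_min, rho_max = rho_max, alpha_1 = alpha_1,
            mu = mu, s = s)
  if (!(rho_min < rho_max)) {
    abort("rho_min must be < rho_max", class = "nichescape_config_error")
  }
  if (alpha_1 <= 0 || mu <= 0 || s <= 0) {
    abort("alpha_1, mu and s must be positive",
          class = "nichescape_config_error")
  }
  if (alpha_1 > rho_max - rho_min) {
    abort("alpha_1 exceeds the domain width alpha_max",
          class = "nichescape_config_error")
  }
  if (is.null(unit)) unit <- infer_unit(vals)
  iv <- round(vals / unit)
  if (max(abs(iv * unit - vals)) > 1e-8 * max(1, abs(vals))) {
    abort("parameters are not integer multiples of the base unit",
          class = "nichescape_config_error")
  }
  structure(list(axis_id = axis_id, rho_min = rho_min, rho_max = rho_max,
                 alpha_1 = alpha_1, mu = mu, s = s, unit = unit,
                 int = as.list(iv)),
            class = "niche_axis_spec")
}

infer_unit <- function(vals) {
  for (k in 0:6) {
    unit <- 10^(-k)
    scaled <- vals / unit
    if (max(abs(scaled - round(scaled))) < 1e-6) return(unit)
  }
  abort("could not find a decimal base unit for the axis parameters",
        class = "nichescape_config_error")
}

#' @rdname niche_axis_spec
#' @export
thermal_axis_spec <- function(rho_min = -1.8, rho_max = 44, alpha_1 = 1,
                              mu = 0.1, s = 0.1) {
  niche_axis_spec("temperature", rho_min, rho_max, alpha_1, mu, s)
}

#' @rdname niche_axis_spec
#' @param mu,s See above; the two published precipitation settings are
#'   (100, 50) for the fine pool and (400, 200) for the coarse one.
#' @export
precipitation_axis_spec <- function(rho_min = 0, rho_max = 3000,
                                    alpha_1 = 100, mu = 100, s = 50) {
  niche_axis_spec("precipitation", rho_min, rho_max, alpha_1, mu, s)
}

#' @export
print.niche_axis_spec <- function(x, ...) {
  cat(sprintf("<niche_axis_spec> %s: [%g, %g], alpha_1=%g, mu=%g, s=%g (unit %g)\n",
              x$axis_id, x$rho_min, x$rho_max, x$alpha_1, x$mu, x$s, x$unit))
  invisible(x)
}

#' Niche amplitudes of an axis
#'
#' The arithmetic progression `alpha_1, alpha_1 + mu, ...` not exceeding
#' the domain width `alpha_max = rho_max - rho_min`, evaluated in exact
#' scaled-integer arithmetic.
#'
#' @param spec A [niche_axis_spec()].
#' @return Numeric vector of amplitudes (axis units).
#' @export
build_amplitudes <- function(spec) {
  stopifnot(inherits(spec, "niche_axis_spec"))
  it <- spec$int
  amax <- it$rho_max - it$rho_min
  p <- (amax - it$alpha_1) %/% it$mu + 1
  (it$alpha_1 + it$mu * (seq_len(p) - 1)) * spec$unit
}

#' Enumerate all niches of one axis
#'
#' For each amplitude `alpha_i` the niche start slides from `rho_min` in
#' steps of `s`; the number of starts is
#' `q_i = floor((alpha_max + s - alpha_i)/s + 1)` and each end is
#' `y = x + alpha_i`. Counting and coordinates use exact scaled integers.
#'
#' @param spec A [niche_axis_spec()].
#' @return A [niche_pool] with one row per niche (`niche_id, x, y, alpha`)
#'   ordered by (amplitude, start); the total count is `Sum q_i`.
#' @examples
#' nrow(build_axis_niches(precipitation_axis_spec()))       # 930
#' nrow(build_axis_niches(precipitation_axis_spec(mu = 400, s = 200))) # 72
#' @export
build_axis_niches <- function(spec) {
  stopifnot(inherits(spec, "niche_axis_spec"))
  it <- spec$int
  amax <- it$rho_max - it$rho_min
  a_int <- round(build_amplitudes(spec) / spec$unit)
  q <- (amax + it$s - a_int) %/% it$s + 1
  x_int <- it$rho_min + it$s *
    (unlist(lapply(q, seq_len), use.names = FALSE) - 1)
  a_rep <- rep(a_int, q)
  niches <- tibble(
    niche_id = seq_along(x_int),
    x = x_int * spec$unit,
    y = (x_int + a_rep) * spec$unit,
    alpha = a_rep * spec$unit
  )
  new_niche_pool(niches, specs = setNames(list(spec), spec$axis_id),
                 axes = spec$axis_id, R_full = nrow(niches))
}

new_niche_pool <- function(niches, specs, axes, R_full, kind = "axis",
                           axis_pools = NULL, sampled_fraction = 1,
                           phi = 1, seed = NULL) {
  structure(
    list(niches = niches, specs = specs, axes = axes, R_full = R_full,
         kind = kind, axis_pools = axis_pools,
         sampled_fraction = sampled_fraction, phi = phi, seed = seed),
    class = "niche_pool"
  )
}

#' Pool of niches on one or two climatic axes
#'
#' A `niche_pool` holds the (possibly sampled) set of rectangular niches
#' being simulated, the axis specifications, the full combinatorial count
#' `R`, and the sampling correction `phi = 1/sampled_fraction`. Pools over
#' two axes built with [build_product_pool()] are kept lazy (the Cartesian
#' product can reach ~1e8 niches) until [sample_pool()] materializes a
#' subset.
#'
#' @name niche_pool
#' @seealso [build_axis_niches()], [build_product_pool()], [sample_pool()]
NULL

#' @export
print.niche_pool <- function(x, ...) {
  cat(sprintf("<niche_pool> axes: %s\n", paste(x$axes, collapse = " x ")))
  cat(sprintf("  full pool R = %s niches", format(x$R_full, big.mark = ",")))
  if (is.null(x$niches)) {
    cat(" (lazy product, not materialized)\n")
  } else {
    cat(sprintf("; materialized %s (fraction %.4g, phi = %.4g)\n",
                format(nrow(x$niches), big.mark = ","),
                x$sampled_fraction, x$phi))
  }
  invisible(x)
}

#' @export
glance.niche_pool <- function(x, ...) {
  tibble(axes = paste(x$axes, collapse = "+"),
         R_full = x$R_full,
         n_niches = if (is.null(x$niches)) NA_integer_ else nrow(x$niches),
         sampled_fraction = x$sampled_fraction,
         phi = x$phi,
         seed = x$seed %||% NA_integer_)
}

#' @export
tidy.niche_pool <- function(x, ...) {
  if (is.null(x$niches)) {
    abort("lazy product pools have no materialized niches; sample_pool() first",
          class = "nichescape_config_error")
  }
  if (length(x$axes) == 1) {
    out <- x$niches
    out$axis <- x$axes
    dplyr::relocate(out, "axis", .after = "niche_id")
  } else {
    x$niches |>
      tidyr::pivot_longer(-"niche_id",
                          names_to = c(".value", "axis"),
                          names_pattern = "^(x|y|alpha)_(.*)$")
  }
}

#' Number of niches carried by a pool
#'
#' The materialized count when the pool is materialized, otherwise the
#' full combinatorial `R`.
#' @param pool A [niche_pool].
#' @export
pool_size <- function(pool) {
  if (is.null(pool$niches)) pool$R_full else nrow(pool$niches)
}

#' Cartesian product pool over temperature and precipitation
#'
#' Every 2-D niche pairs one thermal interval with one precipitation
#' interval, so the full count is `R = r_t * r_p`. The product is not
#' materialized: monthly richness for the full pool factorizes over axes,
#' and [sample_pool()] draws members directly by index.
#'
#' @param spec_t,spec_p [niche_axis_spec()]s for the two axes.
#' @return A lazy `niche_pool` over both axes.
#' @export
build_product_pool <- function(spec_t, spec_p) {
  pt <- build_axis_niches(spec_t)
  pp <- build_axis_niches(spec_p)
  new_niche_pool(
    niches = NULL,
    specs = c(pt$specs, pp$specs),
    axes = c(spec_t$axis_id, spec_p$axis_id),
    R_full = nrow(pt$niches) * nrow(pp$niches),
    kind = "product",
    axis_pools = list(pt$niches, pp$niches) |> setNames(c(spec_t$axis_id, spec_p$axis_id))
  )
}

#' Seeded uniform subsample of a niche pool
#'
#' Draws `round(R * fraction)` niches without replacement, uniformly over
#' the full pool, and records the sampling correction `phi = 1/fraction`
#' used later to rescale total pseudo-species counts. Product pools are
#' materialized by mapping sampled global indices back to their axis
#' intervals (enumeration order: thermal niche major, precipitation niche
#' minor, each ordered by amplitude then start).
#'
#' @param pool A [niche_pool].
#' @param fraction Fraction in (0, 1]; `1` keeps every niche.
#' @param seed Integer RNG seed (required when `fraction < 1`).
#' @return A materialized `niche_pool`.
#' @export
sample_pool <- function(pool, fraction, seed = NULL) {
  stopifnot(inherits(pool, "niche_pool"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "nichescape_config_error")
  }
  R <- pool$R_full
  n <- round(R * fraction)
  if (n > 5e6) {
    abort(paste0("materializing ", n, " niches would exhaust memory; ",
                 "use a smaller fraction (full product pools support the ",
                 "separable monthly-richness path without sampling)"),
          class = "nichescape_config_error")
  }
  ids <- if (fraction == 1) {
    seq_len(R)
  } else {
    if (is.null(seed)) abort("sampling needs a seed",
                             class = "nichescape_config_error")
    withr_seed(seed, sort(sample.int(R, n)))
  }
  niches <- materialize_ids(pool, ids)
  new_niche_pool(niches, specs = pool$specs, axes = pool$axes,
                 R_full = R, kind = "sampled",
                 sampled_fraction = fraction, phi = 1 / fraction,
                 seed = seed)
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

materialize_ids <- function(pool, ids) {
  if (pool$kind == "product") {
    ax <- pool$axes
    t_tab <- pool$axis_pools[[ax[1]]]
    p_tab <- pool$axis_pools[[ax[2]]]
    rp <- nrow(p_tab)
    it <- (ids - 1) %/% rp + 1
    ip <- (ids - 1) %% rp + 1
    out <- tibble(niche_id = ids)
    for (col in c("x", "y", "alpha")) {
      out[[paste0(col, "_", ax[1])]] <- t_tab[[col]][it]
      out[[paste0(col, "_", ax[2])]] <- p_tab[[col]][ip]
    }
    out
  } else {
    pool$niches[match(ids, pool$niches$niche_id), ]
  }
}

#' Niche membership of climate values
#'
#' Tests, for every niche in a materialized pool, whether the supplied
#' per-axis values fall inside the niche's closed tolerance interval(s)
#' on all axes (intervals are closed on both ends: a value exactly at an
#' interval end is contained).
#'
#' @param pool A materialized [niche_pool].
#' @param values Named numeric vector, one value per axis (names matching
#'   the pool's axes); for single-axis pools an unnamed scalar works.
#' @return Logical vector, one flag per niche.
#' @examples
#' toy <- build_axis_niches(niche_axis_spec("temperature", 0, 10, 2, 4, 5))
#' sum(niche_contains(toy, 6))
#' @export
niche_contains <- function(pool, values) {
  stopifnot(inherits(pool, "niche_pool"))
  if (is.null(pool$niches)) {
    abort("pool is lazy; sample_pool() first",
          class = "nichescape_config_error")
  }
  if (any(!is.finite(values))) {
    abort("values must be finite", class = "nichescape_dimension_error")
  }
  if (length(pool$axes) == 1) {
    if (length(values) != 1) {
      abort("one value expected for a single-axis pool",
            class = "nichescape_dimension_error")
    }
    v <- unname(values)
    return(pool$niches$x <= v & v <= pool$niches$y)
  }
  if (!all(pool$axes %in% names(values))) {
    abort("values must be named for every pool axis",
          class = "nichescape_dimension_error")
  }
  ok <- rep(TRUE, nrow(pool$niches))
  for (ax in pool$axes) {
    v <- values[[ax]]
    ok <- ok & pool$niches[[paste0("x_", ax)]] <= v &
      v <= pool$niches[[paste0("y_", ax)]]
  }
  ok
}

#' Count niches containing each value (fast path)
#'
#' Order-statistics counting for a set of closed intervals: the number of
#' intervals containing `v` is `#(starts <= v) - #(ends < v)`. Used to
#' evaluate monthly richness for whole grids at once.
#'
#' @param pool A materialized single-axis [niche_pool] (or an axis tibble).
#' @param v Numeric vector of axis values.
#' @return Integer vector of counts, same length as `v`.
#' @export
count_containing <- function(pool, v) {
  tab <- if (inherits(pool, "niche_pool")) {
    if (length(pool$axes) != 1 || is.null(pool$niches)) {
      abort("count_containing() needs a materialized single-axis pool",
            class = "nichescape_dimension_error")
    }
    pool$niches
  } else {
    pool
  }
  interval_counts(tab$x, tab$y, v)
}

interval_counts <- function(x, y, v) {
  xs <- sort(x)
  ys <- sort(y)
  out <- rep(NA_integer_, length(v))
  ok <- !is.na(v)
  out[ok] <- findInterval(v[ok], xs) -
    findInterval(v[ok], ys, left.open = TRUE)
  out
}
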