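# Monthly climate-envelope colonization. A pseudo-species is present in a
# cell in a given month iff the cell's climate value(s) that month fall
# inside its niche interval(s) on every axis. Monthly richness counts are
# evaluated by order-statistics counting (single axis, and the separable
# product fast path for full two-axis pools); the union field Phi needs
# per-niche presence and is evaluated in niche chunks to bound memory.

#' Presence policy for colonization and speciation
#'
#' `per_month` (the default) evaluates presence month by month: annual
#' richness is the 12-month mean and the union field counts species
#' present in at least one month. `all_months` is a strict residency rule
#' (present only if every month is tolerated), kept for sensitivity
#' analysis: under it the monthly stability index is identically 1, which
#' is incompatible with the range of stability values the per-month rule
#' produces.
#'
#' @param mode `"per_month"` or `"all_months"`.
#' @export
presence_policy <- function(mode = c("per_month", "all_months")) {
  match.arg(mode)
}

#' Simulate colonization and map pseudo-species richness
#'
#' @param pool A [niche_pool]; materialized, or a lazy product pool (fast
#'   separable path; the union field is then unavailable).
#' @param climate A [climatology_grid()] for single-axis pools, or a named
#'   list of grids (one per pool axis, e.g.
#'   `list(temperature = ..., precipitation = ...)`).
#' @param zone Optional `zone_mask` restricting the simulated cells.
#' @param policy See [presence_policy()].
#' @param compute_union Evaluate the union field `Phi` (species present in
#'   at least one month)? Needed for the stability index; skip it for
#'   large single-axis mapping runs where only monthly counts matter.
#' @param chunk_size Niches per chunk in the union evaluation.
#' @return A `richness_field` with per-cell monthly counts `phi_m`, the
#'   annual mean `D`, and (when available) the union count `Phi`.
#' @export
richness_field <- function(pool, climate, zone = NULL,
                           policy = c("per_month", "all_months"),
                           compute_union = TRUE, chunk_size = 512L) {
  stopifnot(inherits(pool, "niche_pool"))
  policy <- presence_policy(match.arg(policy))
  grids <- climate_grid_list(pool, climate)
  g1 <- grids[[1]]
  valid <- Reduce(`&`, lapply(grids, function(g) g$mask))
  if (!is.null(zone)) {
    stopifnot(inherits(zone, "zone_mask"))
    if (!identical(dim(zone$member), dim(valid))) {
      abort("zone mask is not on the climate geometry",
            class = "nichescape_config_error")
    }
    valid <- valid & zone$member
  }
  nla <- length(g1$lat)
  nlo <- length(g1$lon)
  ncell <- sum(valid)
  vmat <- lapply(grids, function(g) {
    matrix(g$values[rep(valid, 12)], ncell, 12)
  })

  monthly <- matrix(0, ncell, 12)
  union_counts_v <- NULL
  if (policy == "all_months") {
    cnt <- all_months_counts(pool, vmat)
    monthly <- matrix(cnt, ncell, 12)
    union_counts_v <- cnt
  } else if (pool$kind == "product" && is.null(pool$niches)) {
    ax <- pool$axes
    for (m in 1:12) {
      c1 <- interval_counts(pool$axis_pools[[ax[1]]]$x,
                            pool$axis_pools[[ax[1]]]$y, vmat[[ax[1]]][, m])
      c2 <- interval_counts(pool$axis_pools[[ax[2]]]$x,
                            pool$axis_pools[[ax[2]]]$y, vmat[[ax[2]]][, m])
      monthly[, m] <- as.numeric(c1) * as.numeric(c2)
    }
    # Phi is not separable over axes for a lazy product pool
    union_counts_v <- NULL
  } else if (length(pool$axes) == 1) {
    tab <- pool$niches
    for (m in 1:12) {
      monthly[, m] <- interval_counts(tab$x, tab$y, vmat[[1]][, m])
    }
    if (compute_union) {
      union_counts_v <- chunked_union_counts(
        list(list(x = tab$x, y = tab$y)), vmat[1], chunk_size)
    }
  } else {
    tab <- pool$niches
    boxes <- lapply(pool$axes, function(ax) {
      list(x = tab[[paste0("x_", ax)]], y = tab[[paste0("y_", ax)]])
    })
    names(boxes) <- pool$axes
    vm <- vmat[pool$axes]
    res <- chunked_presence(boxes, vm, chunk_size, union = compute_union)
    monthly <- res$monthly
    union_counts_v <- res$union
  }

  expand <- function(v) {
    m <- matrix(NA_real_, nla, nlo)
    m[valid] <- v
    m
  }
  monthly_arr <- array(NA_real_, c(nla, nlo, 12))
  for (m in 1:12) monthly_arr[, , m] <- expand(monthly[, m])
  structure(
    list(lat = g1$lat, lon = g1$lon,
         monthly = monthly_arr,
         annual = expand(rowMeans(monthly)),
         union = if (is.null(union_counts_v)) NULL else expand(union_counts_v),
         valid = valid,
         zone_id = if (is.null(zone)) NA_character_ else zone$zone_id,
         policy = policy,
         n_niches = pool_size(pool), phi = pool$phi),
    class = "richness_field"
  )
}

climate_grid_list <- function(pool, climate) {
  if (inherits(climate, "climatology_grid")) climate <- list(climate)
  if (length(pool$axes) != length(climate)) {
    abort("one climate grid per pool axis is required",
          class = "nichescape_config_error")
  }
  if (length(pool$axes) > 1) {
    if (is.null(names(climate)) || !all(pool$axes %in% names(climate))) {
      abort("multi-axis climate lists must be named by axis",
            class = "nichescape_config_error")
    }
    climate <- climate[pool$axes]
  } else {
    names(climate) <- pool$axes
  }
  geom <- lapply(climate, function(g) list(g$lat, g$lon))
  if (length(unique(geom)) != 1) {
    abort("climate grids must share one geometry",
          class = "nichescape_config_error")
  }
  climate
}

all_months_counts <- function(pool, vmat) {
  if (pool$kind == "product" && is.null(pool$niches)) {
    counts <- lapply(pool$axes, function(ax) {
      tab <- pool$axis_pools[[ax]]
      vmin <- apply(vmat[[ax]], 1, min)
      vmax <- apply(vmat[[ax]], 1, max)
      chunked_cover_counts(tab$x, tab$y, vmin, vmax)
    })
    Reduce(`*`, counts)
  } else if (length(pool$axes) == 1) {
    tab <- pool$niches
    chunked_cover_counts(tab$x, tab$y,
                         apply(vmat[[1]], 1, min), apply(vmat[[1]], 1, max))
  } else {
    tab <- pool$niches
    boxes <- lapply(pool$axes, function(ax) {
      list(x = tab[[paste0("x_", ax)]], y = tab[[paste0("y_", ax)]])
    })
    names(boxes) <- pool$axes
    vmin <- lapply(vmat[pool$axes], function(m) apply(m, 1, min))
    vmax <- lapply(vmat[pool$axes], function(m) apply(m, 1, max))
    ncell <- length(vmin[[1]])
    out <- numeric(ncell)
    n <- length(boxes[[1]]$x)
    for (ix in chunk_indices(n, 512L)) {
      keep <- rep(TRUE, ncell * length(ix))
      acc <- matrix(TRUE, ncell, length(ix))
      for (ax in names(boxes)) {
        acc <- acc & outer(vmin[[ax]], boxes[[ax]]$x[ix], ">=") &
          outer(vmax[[ax]], boxes[[ax]]$y[ix], "<=")
      }
      out <- out + rowSums(acc)
    }
    out
  }
}

# count intervals covering [vmin, vmax] entirely (all-months residency)
chunked_cover_counts <- function(x, y, vmin, vmax, chunk = 2048L) {
  out <- numeric(length(vmin))
  for (ix in chunk_indices(length(x), chunk)) {
    out <- out + rowSums(outer(vmin, x[ix], ">=") & outer(vmax, y[ix], "<="))
  }
  out
}

chunk_indices <- function(n, chunk) {
  if (n == 0) return(list())
  split(seq_len(n), ceiling(seq_len(n) / chunk))
}

# per-cell count of niches present in >= 1 month (single axis)
chunked_union_counts <- function(boxes, vmat, chunk_size) {
  x <- boxes[[1]]$x
  y <- boxes[[1]]$y
  V <- vmat[[1]]
  ncell <- nrow(V)
  out <- numeric(ncell)
  for (ix in chunk_indices(length(x), chunk_size)) {
    acc <- matrix(FALSE, ncell, length(ix))
    for (m in seq_len(ncol(V))) {
      acc <- acc | (outer(V[, m], x[ix], ">=") & outer(V[, m], y[ix], "<="))
    }
    out <- out + rowSums(acc)
  }
  out
}

# generic chunked presence for materialized multi-axis pools
chunked_presence <- function(boxes, vmat, chunk_size, union = TRUE) {
  ncell <- nrow(vmat[[1]])
  nm <- ncol(vmat[[1]])
  monthly <- matrix(0, ncell, nm)
  ucount <- if (union) numeric(ncell) else NULL
  n <- length(boxes[[1]]$x)
  for (ix in chunk_indices(n, chunk_size)) {
    acc <- if (union) matrix(FALSE, ncell, length(ix))
    for (m in seq_len(nm)) {
      pres <- matrix(TRUE, ncell, length(ix))
      for (ax in names(boxes)) {
        v <- vmat[[ax]][, m]
        pres <- pres & outer(v, boxes[[ax]]$x[ix], ">=") &
          outer(v, boxes[[ax]]$y[ix], "<=")
      }
      monthly[, m] <- monthly[, m] + rowSums(pres)
      if (union) acc <- acc | pres
    }
    if (union) ucount <- ucount + rowSums(acc)
  }
  list(monthly = monthly, union = ucount)
}

#' @export
print.richness_field <- function(x, ...) {
  cat(sprintf("<richness_field> %d x %d cells, %d valid, pool of %s niches (%s)\n",
              dim(x$annual)[1], dim(x$annual)[2], sum(x$valid),
              format(x$n_niches, big.mark = ","), x$policy))
  if (!is.na(x$zone_id)) cat(sprintf("  zone: %s\n", x$zone_id))
  rng <- range(x$annual, na.rm = TRUE)
  cat(sprintf("  annual mean richness D in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @rdname richness_field
#' @param x A `richness_field`.
#' @param ... Unused.
#' @export
tidy.richness_field <- function(x, ...) {
  tab <- tidyr::expand_grid(lon = x$lon, lat = x$lat) |>
    dplyr::mutate(
      annual = as.vector(x$annual),
      union = if (is.null(x$union)) NA_real_ else as.vector(x$union)
    ) |>
    dplyr::select("lat", "lon", "annual", "union")
  dplyr::filter(tab, !is.na(.data$annual))
}

#' Monthly stability of pseudo-species richness
#'
#' Per-cell index `sum_m(phi_m) / (12 * Phi)`: 1 when every month carries
#' the full annual species set, dropping toward `1/12` when the whole set
#' turns over to a single month. Undefined (NA) where no species occurs.
#'
#' @param field A [richness_field()] computed with `compute_union = TRUE`.
#' @return Matrix of per-cell stability values in `(0, 1]`.
#' @export
stability_index <- function(field) {
  stopifnot(inherits(field, "richness_field"))
  if (is.null(field$union)) {
    abort("stability needs the union field; recompute with compute_union = TRUE",
          class = "nichescape_config_error")
  }
  tot <- apply(field$monthly, c(1, 2), sum)
  out <- tot / (12 * field$union)
  out[!is.na(field$union) & field$union == 0] <- NA_real_
  out
}

#' Light-weighted benthic richness
#'
#' Down-weights annual mean richness `D` by the light response
#' [light_weight()] evaluated at annual-mean seabed light, for the
#' light-requiring neritic benthos.
#'
#' @param field A [richness_field()].
#' @param light A [climatology_grid()] of seabed light on the same
#'   geometry.
#' @param params A [light_weight_params()].
#' @return Matrix of weighted richness `D* = w(light) x D`.
#' @export
weighted_richness <- function(field, light, params = light_weight_params()) {
  stopifnot(inherits(field, "richness_field"),
            inherits(light, "climatology_grid"))
  if (!identical(dim(field$annual), dim(light$mask))) {
    abort("light grid is not on the field geometry",
          class = "nichescape_dimension_error")
  }
  mean_light <- apply(light$values, c(1, 2), mean)
  light_weight(mean_light, params) * field$annual
}
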