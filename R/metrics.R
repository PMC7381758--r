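# Per-zone diversity summary metrics (psi1-psi10) and the scaling of
# total pseudo-biodiversity to catalogued/estimated species counts.
# Total pseudo-species are computed from the OCCUPIED niche count
# (psi2 * psi4 * phi): the published summary tables are internally
# consistent only with that form, so the variant using the full pool size
# is treated as a misprint and not implemented.

#' Total pseudo-species from summary components
#'
#' `psi5 = psi2 * psi4 * phi`: occupied niches times mean pseudo-species
#' per occupied niche, corrected for the sampled fraction of the pool.
#'
#' @param n_occupied Number of niches with at least one pseudo-species.
#' @param mean_per_niche Mean number of range components (species) per
#'   occupied niche.
#' @param phi Sampling correction, the inverse of the sampled fraction.
#' @return Total pseudo-species (absolute count).
#' @export
total_pseudo_species <- function(n_occupied, mean_per_niche, phi = 1) {
  n_occupied * mean_per_niche * phi
}

#' Median range area as a share of the zone area
#'
#' `psi9 = 100 * psi6 / zone_area`, in percent.
#'
#' @param median_area_km2 Median pseudo-species range area (km^2).
#' @param zone_area_km2 Total zone area (km^2).
#' @export
median_area_share <- function(median_area_km2, zone_area_km2) {
  100 * median_area_km2 / zone_area_km2
}

#' Diversity summary of one domain or zone
#'
#' Collapses a speciation run into the ten summary metrics: pool size
#' (psi1, the sampled pool), occupied niches (psi2) and their percentage
#' (psi3), mean pseudo-species per occupied niche (psi4), total
#' pseudo-species (psi5 = psi2*psi4*phi), the median and quartiles of the
#' species range-area distribution (psi6-psi8, linear-interpolation
#' quartiles), the median-area share of the zone (psi9, %), and the
#' zone-mean monthly stability (psi10, unweighted over valid cells, or
#' area-weighted on request).
#'
#' @param pool The materialized [niche_pool] that was simulated.
#' @param species_records Tibble from [enumerate_pseudo_species()].
#' @param richness_field Optional [richness_field()] with a union layer,
#'   for psi10.
#' @param zone Optional `zone_mask` (provides the zone id and area).
#' @param zone_area_km2 Zone area override when no mask is given.
#' @param area_weighted_stability Weight psi10 by cell area?
#' @return A one-row tibble (class `diversity_summary`) with columns
#'   `zone_id, psi1..psi10, phi, zone_area_km2`.
#' @export
summarize_zone <- function(pool, species_records, richness_field = NULL,
                           zone = NULL, zone_area_km2 = NULL,
                           area_weighted_stability = FALSE) {
  stopifnot(inherits(pool, "niche_pool"))
  psi1 <- pool_size(pool)
  phi <- pool$phi
  psi2 <- dplyr::n_distinct(species_records$niche_id)
  if (psi2 == 0) {
    warn("no pseudo-species occurred: quartile metrics are undefined")
  }
  psi4 <- if (psi2 > 0) nrow(species_records) / psi2 else NA_real_
  q <- if (psi2 > 0) {
    quantile(species_records$area_km2, c(0.25, 0.5, 0.75), names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  area <- zone_area_km2 %||% (if (!is.null(zone)) zone$area_km2 else NA_real_)
  psi10 <- NA_real_
  if (!is.null(richness_field) && !is.null(richness_field$union)) {
    st <- stability_index(richness_field)
    keep <- !is.na(st)
    if (!is.null(zone)) keep <- keep & zone$member
    if (area_weighted_stability) {
      g <- richness_field
      rr <- c(if (length(g$lat) > 1) diff(g$lat[1:2]) else 1,
              if (length(g$lon) > 1) diff(g$lon[1:2]) else 1)
      w <- matrix(cell_area(g$lat, rr), length(g$lat), length(g$lon))
      psi10 <- sum(st[keep] * w[keep]) / sum(w[keep])
    } else {
      psi10 <- mean(st[keep])
    }
  }
  out <- tibble(
    zone_id = if (!is.null(zone)) zone$zone_id else NA_character_,
    psi1 = psi1,
    psi2 = psi2,
    psi3 = 100 * psi2 / psi1,
    psi4 = psi4,
    psi5 = total_pseudo_species(psi2, psi4, phi),
    psi6 = q[2],
    psi7 = q[1],
    psi8 = q[3],
    psi9 = median_area_share(q[2], area),
    psi10 = psi10,
    phi = phi,
    zone_area_km2 = area
  )
  class(out) <- c("diversity_summary", class(out))
  out
}

#' Reference eukaryotic species counts
#'
#' Catalogued and estimated totals per realm used to scale total
#' pseudo-biodiversity: 1,233,500 catalogued terrestrial plus 193,756
#' marine species (total 1,427,256), and estimated totals of 8,740,000
#' and 2,210,000 (10,950,000).
#'
#' @return A tibble with columns `reference, terrestrial, marine, total`.
#' @export
reference_species_counts <- function() {
  tibble(
    reference = c("catalogued", "estimated"),
    terrestrial = c(1233500, 8740000),
    marine = c(193756, 2210000),
    total = c(1233500 + 193756, 8740000 + 2210000)
  )
}

#' Scale total pseudo-biodiversity to a reference species count
#'
#' Earth pseudo-biodiversity is the terrestrial total plus the sum of the
#' marine-zone totals; dividing by the reference count gives a scale
#' factor `k`, and each realm's scaled count is its pseudo-total divided
#' by `k`, so scaled terrestrial + scaled marine equals the reference
#' exactly by construction.
#'
#' @param summaries A tibble of [summarize_zone()] rows (bound together)
#'   with an added `realm` column (`"terrestrial"` or `"marine"`); exactly
#'   one terrestrial row, at least one marine row.
#' @param n_reference Positive reference species count.
#' @return A tibble (class `scaling_result`) with one row per realm:
#'   `realm, theta, scaled`; attributes `theta_total` and `k`.
#' @export
scale_to_reference <- function(summaries, n_reference) {
  if (!is.numeric(n_reference) || n_reference <= 0) {
    abort("n_reference must be positive", class = "nichescape_config_error")
  }
  if (!"realm" %in% names(summaries)) {
    abort("summaries need a realm column (terrestrial/marine)",
          class = "nichescape_config_error")
  }
  if (sum(summaries$realm == "terrestrial") != 1 ||
      sum(summaries$realm == "marine") < 1) {
    abort("need exactly one terrestrial and at least one marine summary",
          class = "nichescape_config_error")
  }
  per_realm <- summaries |>
    dplyr::group_by(.data$realm) |>
    dplyr::summarise(theta = sum(.data$psi5), .groups = "drop")
  theta_total <- sum(per_realm$theta)
  k <- theta_total / n_reference
  out <- dplyr::mutate(per_realm, scaled = .data$theta / k)
  attr(out, "theta_total") <- theta_total
  attr(out, "k") <- k
  class(out) <- c("scaling_result", class(out))
  out
}

#' @export
glance.scaling_result <- function(x, ...) {
  tibble(theta_total = attr(x, "theta_total"), k = attr(x, "k"),
         n_reference = attr(x, "theta_total") / attr(x, "k"))
}
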