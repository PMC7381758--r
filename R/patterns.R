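# Latitudinal biodiversity gradients and map validation. The LBG profile
# is the per-latitude median across longitudes (with a minimum number of
# contributing longitudes); the per-longitude LBG matrix histograms
# globally min-max standardized richness in 0.05 bins per latitude; map
# correlation is per-cell Pearson with the minimal-n* inversion used to
# gauge robustness against spatial autocorrelation.

richness_matrix <- function(x) {
  if (inherits(x, "richness_field")) {
    list(mat = x$annual, lat = x$lat)
  } else {
    list(mat = as.matrix(x), lat = NULL)
  }
}

#' Latitudinal biodiversity gradient (median profile)
#'
#' Per latitude row, the median richness across longitudes; undefined
#' when fewer than `min_longitudes` cells are valid at that latitude.
#'
#' @param richness A [richness_field()] or richness matrix (`[lat, lon]`).
#' @param lat Latitude centres when a bare matrix is given.
#' @param min_longitudes Minimum contributing longitudes (default 5).
#' @return A tibble (class `lbg_profile`): `lat, median_richness,
#'   n_longitudes`.
#' @export
lbg_median <- function(richness, lat = NULL, min_longitudes = 5) {
  rm_ <- richness_matrix(richness)
  mat <- rm_$mat
  lat <- lat %||% rm_$lat %||% seq_len(nrow(mat))
  med <- apply(mat, 1, function(r) median(r, na.rm = TRUE))
  n <- rowSums(!is.na(mat))
  med[n < min_longitudes] <- NA_real_
  out <- tibble(lat = lat, median_richness = med, n_longitudes = n)
  class(out) <- c("lbg_profile", class(out))
  out
}

#' Per-longitude LBG matrix
#'
#' Richness is min-max standardized to `[0, 1]` once over all valid cells
#' of the map, then histogrammed per latitude across longitudes in bins
#' of `bin_width` (the top bin is closed so the global maximum lands in
#' it), expressed as the percentage of contributing longitudes. Each
#' latitude row with data sums to 100.
#'
#' @inheritParams lbg_median
#' @param bin_width Bin width on the standardized scale (default 0.05).
#' @return A tibble (class `lbg_matrix`): `lat, bin_lo, bin_hi, percent,
#'   n_longitudes`.
#' @export
lbg_longitude_matrix <- function(richness, lat = NULL, bin_width = 0.05) {
  rm_ <- richness_matrix(richness)
  mat <- rm_$mat
  lat <- lat %||% rm_$lat %||% seq_len(nrow(mat))
  rng <- range(mat, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    abort("richness map is constant: standardization is undefined",
          class = "nichescape_degenerate_input_error")
  }
  std <- (mat - rng[1]) / diff(rng)
  nbin <- ceiling(1 / bin_width)
  edges_lo <- (seq_len(nbin) - 1) * bin_width
  bin_of <- function(v) pmin(floor(v / bin_width) + 1, nbin)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    v <- std[i, !is.na(std[i, ])]
    counts <- tabulate(bin_of(v), nbin)
    tibble(lat = lat[i],
           bin_lo = edges_lo,
           bin_hi = edges_lo + bin_width,
           percent = if (length(v) > 0) 100 * counts / length(v) else
             rep(NA_real_, nbin),
           n_longitudes = length(v))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lbg_matrix", class(out))
  out
}

#' Correlate two richness maps
#'
#' Pearson correlation over jointly valid cells, with the nominal p-value
#' and the minimum sample size `n*` that would keep the relationship
#' significant at p = .05: the smallest integer `n >= 3` such that
#' `t = r * sqrt((n-2)/(1-r^2))` exceeds the two-sided critical t value
#' with `n - 2` degrees of freedom. A small `n*` indicates a correlation
#' robust to the loss of effective degrees of freedom that spatial
#' autocorrelation causes.
#'
#' @param a,b Richness fields or matrices on one geometry.
#' @return A one-row tibble (class `correlation_report`): `r, n, n_star,
#'   p_value`.
#' @export
correlate_maps <- function(a, b) {
  ma <- richness_matrix(a)$mat
  mb <- richness_matrix(b)$mat
  if (!identical(dim(ma), dim(mb))) {
    abort("maps are not on the same geometry",
          class = "nichescape_dimension_error")
  }
  keep <- !is.na(ma) & !is.na(mb)
  n <- sum(keep)
  if (n < 3) {
    abort("fewer than 3 jointly valid cells",
          class = "nichescape_insufficient_data_error")
  }
  va <- ma[keep]
  vb <- mb[keep]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort("zero variance: correlation undefined",
          class = "nichescape_undefined_correlation_error")
  }
  r <- cor(va, vb)
  p <- cor.test(va, vb)$p.value
  out <- tibble(r = r, n = n, n_star = min_significant_n(r), p_value = p)
  class(out) <- c("correlation_report", class(out))
  out
}

#' Minimum sample size keeping a correlation significant
#'
#' @param r Pearson correlation coefficient.
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_max Search cap; `NA` if no `n <= n_max` is significant.
#' @return Smallest integer `n >= 3` at which `r` stays significant.
#' @export
min_significant_n <- function(r, alpha = 0.05, n_max = 1e6) {
  if (is.na(r) || abs(r) >= 1) return(3L)
  for (n in 3:n_max) {
    tval <- abs(r) * sqrt((n - 2) / (1 - r^2))
    if (tval > qt(1 - alpha / 2, n - 2)) return(as.integer(n))
  }
  NA_integer_
}
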