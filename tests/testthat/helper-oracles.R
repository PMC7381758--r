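# Independent oracles and small fixture builders. These deliberately
# avoid the package's fast paths: the richness oracle is a triple loop
# over (niche, cell, month) and the labeling oracle is a plain flood
# fill, so agreement is a genuine dual-route check.

toy_spec <- function() niche_axis_spec("temperature", 0, 10, 2, 4, 5)
toy_pool <- function() build_axis_niches(toy_spec())

# single-variable climatology from a ncell x 12 matrix of values laid on
# an nr x nc grid (column-major cell order)
grid_from_values <- function(V, nr, nc, lat = NULL, lon = NULL) {
  stopifnot(nrow(V) == nr * nc)
  arr <- array(NA_real_, c(nr, nc, 12))
  for (m in 1:12) arr[, , m] <- matrix(V[, m], nr, nc)
  climatology_grid(arr,
                   lat %||% seq(-80, by = 2, length.out = nr),
                   lon %||% seq(-170, by = 2, length.out = nc))
}

constant_cell_grid <- function(vals12) {
  climatology_grid(array(vals12, c(1, 1, 12)), 0, 0)
}

# brute-force richness: triple loop over niches, cells, months
naive_richness <- function(tab, V) {
  ncell <- nrow(V)
  monthly <- matrix(0L, ncell, 12)
  un <- integer(ncell)
  for (i in seq_len(nrow(tab))) {
    for (cc in seq_len(ncell)) {
      pres <- V[cc, ] >= tab$x[i] & V[cc, ] <= tab$y[i]
      monthly[cc, ] <- monthly[cc, ] + pres
      un[cc] <- un[cc] + any(pres)
    }
  }
  list(monthly = monthly, union = un)
}

# plain recursive-style (explicit stack) flood fill
flood_fill_components <- function(mask, connectivity = 4, wrap = FALSE) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  neighbours <- function(i, j) {
    cand <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    if (connectivity == 8) {
      cand <- c(cand, list(c(i - 1, j - 1), c(i - 1, j + 1),
                           c(i + 1, j - 1), c(i + 1, j + 1)))
    }
    keep <- list()
    for (p in cand) {
      ii <- p[1]; jj <- p[2]
      if (ii < 1 || ii > nr) next
      if (jj < 1) { if (wrap) jj <- nc else next }
      if (jj > nc) { if (wrap) jj <- 1L else next }
      keep[[length(keep) + 1]] <- c(ii, jj)
    }
    keep
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (q in neighbours(p[1], p[2])) {
          if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            stack[[length(stack) + 1]] <- q
          }
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# two labelings describe the same partition (up to label renaming)
same_partition <- function(l1, l2) {
  on1 <- l1 > 0
  if (!identical(on1, l2 > 0)) return(FALSE)
  pairs <- unique(cbind(l1[on1], l2[on1]))
  nrow(pairs) == length(unique(pairs[, 1])) &&
    nrow(pairs) == length(unique(pairs[, 2]))
}

# specs whose start step divides every construction quantity (alpha_1,
# mu, and the domain width), so the containment count is symmetric about
# (rho_min + rho_max + s)/2 on the start lattice; the published thermal
# and precipitation parameter sets are of this kind
random_symmetric_spec <- function() {
  s <- sample(1:4, 1)
  mu <- s * sample(1:3, 1)
  alpha_1 <- s * sample(1:3, 1)
  width <- alpha_1 + s * sample(2:10, 1)
  rho_min <- sample(0:5, 1)
  niche_axis_spec("temperature", rho_min, rho_min + width, alpha_1, mu, s)
}

random_small_spec <- function() {
  repeat {
    rho_min <- sample(0:5, 1)
    width <- sample(5:30, 1)
    alpha_1 <- sample(1:4, 1)
    mu <- sample(1:5, 1)
    s <- sample(1:5, 1)
    if (alpha_1 <= width) {
      return(niche_axis_spec("temperature", rho_min, rho_min + width,
                             alpha_1, mu, s))
    }
  }
}

small_world <- function(...) {
  generate_world(world_config(n_lat = 30, n_lon = 60, resolution = 6, ...))
}
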