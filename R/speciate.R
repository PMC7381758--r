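# Allopatric pseudo-species: one species per spatially connected
# component of a niche's suitable range on the coarse grid. Two suitable
# patches separated by at least one unsuitable cell are two species with
# the same niche (Buffon's Law). Connectivity is rook (4-neighbour) by
# default -- "separated by at least one geographical cell" reads diagonal
# contact as separation -- with queen (8-neighbour) available; the grid
# can wrap in longitude (oceans are zonally continuous), never across the
# poles.

#' Suitability mask of a single niche
#'
#' @param pool A materialized [niche_pool].
#' @param niche Row index of the niche within the pool.
#' @param climate As in [richness_field()].
#' @param zone Optional `zone_mask`.
#' @param policy Under `per_month` a cell is suitable when at least one
#'   month is tolerated; under `all_months` every month must be.
#' @return Logical matrix over the grid.
#' @export
suitability_mask <- function(pool, niche, climate, zone = NULL,
                             policy = c("per_month", "all_months")) {
  policy <- match.arg(policy)
  grids <- climate_grid_list(pool, climate)
  valid <- Reduce(`&`, lapply(grids, function(g) g$mask))
  if (!is.null(zone)) valid <- valid & zone$member
  row <- pool$niches[niche, ]
  inside <- NULL  # joint monthly presence: all axes satisfied the same month
  for (ax in pool$axes) {
    xs <- if (length(pool$axes) == 1) row$x else row[[paste0("x_", ax)]]
    ys <- if (length(pool$axes) == 1) row$y else row[[paste0("y_", ax)]]
    ax_in <- grids[[ax]]$values >= xs & grids[[ax]]$values <= ys
    inside <- if (is.null(inside)) ax_in else inside & ax_in
  }
  mask <- if (policy == "per_month") {
    apply(inside, c(1, 2), any)
  } else {
    apply(inside, c(1, 2), all)
  }
  mask[is.na(mask)] <- FALSE
  mask & valid
}

#' Label spatially connected range components
#'
#' Standard connected-component labeling of a logical suitability mask on
#' the regular grid, built on an adjacency graph: rook (4) or queen (8)
#' connectivity, optional longitudinal wrap joining the first and last
#' columns, never any adjacency across the poles. Labels are contiguous
#' positive integers in order of first occurrence; unsuitable cells are 0.
#'
#' @param mask Logical matrix (`[lat, lon]`).
#' @param connectivity 4 or 8.
#' @param wrap_longitude Treat the first and last columns as adjacent?
#' @return A `range_labeling`: list with integer matrix `labels` and
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 4, wrap_longitude = FALSE) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- !is.na(mask) & mask
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  vs <- which(mask)
  if (length(vs) == 0) {
    return(structure(list(labels = labels, n_components = 0L),
                     class = "range_labeling"))
  }
  id <- matrix(seq_len(nr * nc), nr, nc)
  pair_block <- function(a, b) {
    sel <- mask[a] & mask[b]
    cbind(id[a][sel], id[b][sel])
  }
  edges <- list()
  if (nr > 1) {
    edges <- c(edges, list(pair_block(cbind(rep(1:(nr - 1), nc),
                                            rep(1:nc, each = nr - 1)),
                                      cbind(rep(2:nr, nc),
                                            rep(1:nc, each = nr - 1)))))
  }
  if (nc > 1) {
    edges <- c(edges, list(pair_block(cbind(rep(1:nr, nc - 1),
                                            rep(1:(nc - 1), each = nr)),
                                      cbind(rep(1:nr, nc - 1),
                                            rep(2:nc, each = nr)))))
    if (wrap_longitude && nc > 2) {
      edges <- c(edges, list(pair_block(cbind(1:nr, rep(nc, nr)),
                                        cbind(1:nr, rep(1L, nr)))))
    }
  }
  if (connectivity == 8 && nr > 1 && nc > 1) {
    edges <- c(edges, list(
      pair_block(cbind(rep(1:(nr - 1), nc - 1), rep(1:(nc - 1), each = nr - 1)),
                 cbind(rep(2:nr, nc - 1), rep(2:nc, each = nr - 1))),
      pair_block(cbind(rep(2:nr, nc - 1), rep(1:(nc - 1), each = nr - 1)),
                 cbind(rep(1:(nr - 1), nc - 1), rep(2:nc, each = nr - 1)))
    ))
    if (wrap_longitude && nc > 2) {
      edges <- c(edges, list(
        pair_block(cbind(1:(nr - 1), rep(nc, nr - 1)),
                   cbind(2:nr, rep(1L, nr - 1))),
        pair_block(cbind(2:nr, rep(nc, nr - 1)),
                   cbind(1:(nr - 1), rep(1L, nr - 1)))
      ))
    }
  }
  el <- do.call(rbind, edges)
  rank <- integer(nr * nc)
  rank[vs] <- seq_along(vs)
  memb <- if (is.null(el) || nrow(el) == 0) {
    seq_along(vs)
  } else {
    g <- igraph::graph_from_edgelist(cbind(rank[el[, 1]], rank[el[, 2]]),
                                     directed = FALSE)
    if (igraph::vcount(g) < length(vs)) {
      g <- igraph::add_vertices(g, length(vs) - igraph::vcount(g))
    }
    igraph::components(g)$membership
  }
  labels[vs] <- match(memb, unique(memb))
  structure(list(labels = labels, n_components = max(labels)),
            class = "range_labeling")
}

#' @export
print.range_labeling <- function(x, ...) {
  cat(sprintf("<range_labeling> %d component(s) over %d suitable cells\n",
              x$n_components, sum(x$labels > 0)))
  invisible(x)
}

#' Enumerate allopatric pseudo-species for a whole pool
#'
#' Runs [suitability_mask()] and [label_components()] for every niche of a
#' materialized pool: each connected range component is one pseudo-species
#' with its cell count and area (sum of member [cell_area()]s). Intended
#' for the coarse (2 degree) grid; niches with empty suitable ranges
#' contribute no species.
#'
#' @inheritParams suitability_mask
#' @param connectivity,wrap_longitude See [label_components()].
#' @return A tibble of species records: `species_id, niche_id,
#'   component_id, cell_count, area_km2`.
#' @export
enumerate_pseudo_species <- function(pool, climate, zone = NULL,
                                     policy = c("per_month", "all_months"),
                                     connectivity = 4,
                                     wrap_longitude = TRUE) {
  stopifnot(inherits(pool, "niche_pool"))
  if (is.null(pool$niches)) {
    abort("pool is lazy; sample_pool() first",
          class = "nichescape_config_error")
  }
  policy <- match.arg(policy)
  grids <- climate_grid_list(pool, climate)
  g1 <- grids[[1]]
  valid <- Reduce(`&`, lapply(grids, function(g) g$mask))
  if (!is.null(zone)) valid <- valid & zone$member
  res <- c(if (length(g1$lat) > 1) diff(g1$lat[1:2]) else 1,
           if (length(g1$lon) > 1) diff(g1$lon[1:2]) else 1)
  areas <- matrix(cell_area(g1$lat, res), length(g1$lat), length(g1$lon))

  vmat <- lapply(grids, function(g) matrix(g$values[rep(valid, 12)],
                                           sum(valid), 12))
  tab <- pool$niches
  one_axis <- length(pool$axes) == 1
  recs <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    suit_cells <- rep(TRUE, sum(valid))
    if (policy == "per_month") {
      inside <- matrix(TRUE, sum(valid), 12)
      for (ax in pool$axes) {
        xs <- if (one_axis) tab$x[k] else tab[[paste0("x_", ax)]][k]
        ys <- if (one_axis) tab$y[k] else tab[[paste0("y_", ax)]][k]
        inside <- inside & (vmat[[ax]] >= xs & vmat[[ax]] <= ys)
      }
      suit_cells <- rowSums(inside) > 0
    } else {
      for (ax in pool$axes) {
        xs <- if (one_axis) tab$x[k] else tab[[paste0("x_", ax)]][k]
        ys <- if (one_axis) tab$y[k] else tab[[paste0("y_", ax)]][k]
        suit_cells <- suit_cells &
          rowSums(vmat[[ax]] >= xs & vmat[[ax]] <= ys) == 12
      }
    }
    if (!any(suit_cells)) next
    mask <- matrix(FALSE, length(g1$lat), length(g1$lon))
    mask[which(valid)[suit_cells]] <- TRUE
    lab <- label_components(mask, connectivity, wrap_longitude)
    sizes <- tabulate(lab$labels[lab$labels > 0], lab$n_components)
    comp_area <- as.vector(rowsum(areas[lab$labels > 0],
                                  lab$labels[lab$labels > 0]))
    recs[[k]] <- tibble(niche_id = tab$niche_id[k],
                        component_id = seq_len(lab$n_components),
                        cell_count = sizes,
                        area_km2 = comp_area)
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    return(tibble(species_id = integer(), niche_id = integer(),
                  component_id = integer(), cell_count = integer(),
                  area_km2 = numeric()))
  }
  dplyr::mutate(out, species_id = dplyr::row_number(), .before = 1)
}
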