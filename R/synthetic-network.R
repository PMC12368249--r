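#' Generate a planar cell network for wave-propagation simulations
#'
#' Places `n_cells` somata uniformly at random inside the field of view
#' (with a margin so each cell's pixel footprint fits), wires them as an
#' Erdos-Renyi graph with the requested mean degree, and assigns each edge an
#' independent conduction delay. One cell is designated as the optically
#' stimulated cell; its activation propagates along shortest-delay paths.
#'
#' @param n_cells number of cells (>= 1).
#' @param field_shape integer vector `c(height, width)` of the field of view
#'   in pixels.
#' @param mean_degree target mean degree of the connectivity graph
#'   (< `n_cells`); ignored for `n_cells = 1`.
#' @param delay_range numeric `c(min, max)` per-edge conduction delay in
#'   seconds; both > 0.
#' @param seed integer seed; identical seeds give identical networks.
#' @param cell_radius soma radius in pixels used for the margin and for the
#'   pixel masks rendered by [simulate_calcium_movie()].
#' @return an object of class `network_model` with fields `cell_positions`
#'   (n x 2 matrix of `(row, col)` pixel coordinates), `adjacency` (logical
#'   matrix, zero diagonal), `conduction_delay` (numeric matrix, seconds, `NA`
#'   off the edges), `stimulated_cell` (index), `field_shape`, `cell_radius`.
#' @export
generate_network <- function(n_cells, field_shape = c(64L, 64L),
                             mean_degree = 4, delay_range = c(0.2, 0.8),
                             seed = 1L, cell_radius = 2.5) {
  if (n_cells < 1) stop_param("`n_cells` must be >= 1")
  field_shape <- as.integer(field_shape)
  if (length(field_shape) != 2L || any(field_shape < ceiling(2 * cell_radius + 2)))
    stop_param("`field_shape` is degenerate for the given cell radius")
  if (n_cells > 1 && mean_degree >= n_cells)
    stop_param("`mean_degree` must be < `n_cells`")
  if (length(delay_range) != 2L || any(delay_range <= 0) ||
      delay_range[2L] < delay_range[1L])
    stop_param("`delay_range` must be positive with min <= max")

  set.seed(derive_seed(seed, "network"))
  margin <- ceiling(cell_radius) + 1
  # rejection-sample positions so somata do not overlap (distinct pixel masks)
  min_sep <- 2 * cell_radius + 1
  pos <- matrix(NA_real_, n_cells, 2L, dimnames = list(NULL, c("row", "col")))
  placed <- 0L
  for (attempt in seq_len(n_cells * 2000L)) {
    cand <- c(stats::runif(1, margin, field_shape[1L] - margin),
              stats::runif(1, margin, field_shape[2L] - margin))
    if (placed == 0L ||
        min(sqrt((pos[seq_len(placed), 1L] - cand[1L])^2 +
                 (pos[seq_len(placed), 2L] - cand[2L])^2)) >= min_sep) {
      placed <- placed + 1L
      pos[placed, ] <- cand
      if (placed == n_cells) break
    }
  }
  if (placed < n_cells)
    stop_param("field of view too small for %d non-overlapping cells", n_cells)

  adj <- matrix(FALSE, n_cells, n_cells)
  if (n_cells > 1) {
    p <- mean_degree / (n_cells - 1)
    up <- upper.tri(adj)
    adj[up] <- stats::runif(sum(up)) < p
    adj <- adj | t(adj)
  }
  delay <- matrix(NA_real_, n_cells, n_cells)
  ne <- sum(adj[upper.tri(adj)])
  if (ne > 0) {
    d <- stats::runif(ne, delay_range[1L], delay_range[2L])
    delay[upper.tri(delay)][adj[upper.tri(adj)]] <- d
    delay[lower.tri(delay)] <- t(delay)[lower.tri(delay)]
  }
  stim <- sample.int(n_cells, 1L)

  structure(
    list(cell_positions = pos, adjacency = adj, conduction_delay = delay,
         stimulated_cell = stim, field_shape = field_shape,
         cell_radius = cell_radius),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  n <- nrow(x$cell_positions)
  cat(sprintf(
    "<network_model> %d cells on %dx%d px, %d edges, stimulated cell #%d\n",
    n, x$field_shape[1L], x$field_shape[2L],
    sum(x$adjacency[upper.tri(x$adjacency)]), x$stimulated_cell))
  invisible(x)
}

## Shortest-path conduction delay (seconds) from the stimulated cell to every
## cell; Inf for cells not reachable.
network_delays <- function(network) {
  n <- nrow(network$cell_positions)
  if (n == 1L) return(0)
  w <- network$conduction_delay
  edges <- which(network$adjacency & upper.tri(network$adjacency), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$weight <- w[edges]
  }
  as.numeric(igraph::distances(g, v = network$stimulated_cell))
}

## Disk pixel mask (linear indices into a height x width field) for one cell.
cell_mask_indices <- function(center, radius, field_shape) {
  r0 <- max(1L, floor(center[1L] - radius)); r1 <- min(field_shape[1L], ceiling(center[1L] + radius))
  c0 <- max(1L, floor(center[2L] - radius)); c1 <- min(field_shape[2L], ceiling(center[2L] + radius))
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- (grid$row - center[1L])^2 + (grid$col - center[2L])^2 <= radius^2
  grid <- grid[keep, , drop = FALSE]
  as.integer(grid$row + (grid$col - 1L) * field_shape[1L])
}
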