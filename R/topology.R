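#' Fixed Voronoi-neighbor interaction topology
#'
#' Computes the first shell of spatial neighbors of each particle (pairs
#' whose Voronoi cells share an edge, equivalently the Delaunay edges of the
#' point set) and prunes edges longer than `max_edge_factor * r0`. Pruning
#' removes the spurious hull-spanning edges that Delaunay triangulation
#' produces along the open boundary of a free-standing sheet. The topology
#' is fixed: it is built once from the initial configuration and never
#' updated during a simulation (no neighbor switching).
#'
#' Adjacency is decided exactly, per candidate pair, by a perpendicular-
#' bisector feasibility test: two sites are Voronoi neighbors iff a segment
#' of positive length on their bisector is closest to both sites, and every
#' other site contributes one linear inequality in the bisector coordinate.
#'
#' @param positions Numeric matrix of particle positions (n x 2), n >= 3 and
#'   not all collinear.
#' @param max_edge_factor Edges longer than `max_edge_factor * r0` are
#'   dropped. Use `Inf` for the raw Voronoi adjacency.
#' @param r0 Reference length for the pruning cutoff.
#' @return An object of class `neighbor_topology` with an `edges` matrix
#'   (two columns, `i < j`, each unordered neighbor pair once) and `n`, the
#'   particle count.
#' @examples
#' st <- init_hex_disc(19, seed = 1)
#' top <- build_topology(st$positions)
#' table(topology_degree(top))
#' @export
build_topology <- function(positions, max_edge_factor = 1.8, r0 = 1) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 3) stop("degenerate geometry: need at least 3 points")
  ctr <- sweep(positions, 2, colMeans(positions))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1)) {
    stop("degenerate geometry: points are collinear or coincident")
  }
  cutoff <- max_edge_factor * r0
  if (is.finite(cutoff)) {
    d <- as.matrix(dist(positions))
    cand <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (any(d[upper.tri(d)] == 0)) {
      stop("degenerate geometry: duplicated points")
    }
  } else {
    cand <- t(utils::combn(n, 2))
    dvec <- sqrt(rowSums((positions[cand[, 1], , drop = FALSE] -
                            positions[cand[, 2], , drop = FALSE])^2))
    if (any(dvec == 0)) stop("degenerate geometry: duplicated points")
  }
  if (nrow(cand) == 0) {
    edges <- matrix(integer(0), 0, 2)
  } else {
    keep <- voronoi_pairs_cpp(positions, cand - 1L)
    edges <- cand[keep, , drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(edges = unname(edges), n = n), class = "neighbor_topology")
}

#' Degree of each particle in a topology
#' @param topology A `neighbor_topology`.
#' @return Integer vector of neighbor counts.
#' @export
topology_degree <- function(topology) {
  tabulate(c(topology$edges[, 1], topology$edges[, 2]), nbins = topology$n)
}

#' @export
print.neighbor_topology <- function(x, ...) {
  cat(sprintf("neighbor_topology: %d particles, %d edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}
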