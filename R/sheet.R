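#' Sheet state: particle positions and headings
#'
#' @param positions Numeric matrix, one row per particle, columns x and y.
#' @param headings Numeric vector of polar heading angles, wrapped to
#'   `(-pi, pi]`.
#' @param time Simulation time of the state.
#' @return An object of class `sheet_state`.
#' @export
sheet_state <- function(positions, headings, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("'positions' must have two columns")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (nrow(positions) != length(headings)) {
    stop("lengths of positions and headings differ")
  }
  structure(list(positions = unname(positions),
                 headings = wrap_angle(as.numeric(headings)),
                 time = time),
            class = "sheet_state")
}

#' @export
print.sheet_state <- function(x, ...) {
  cat(sprintf("sheet_state: %d particles at t = %g\n",
              nrow(x$positions), x$time))
  invisible(x)
}

#' Initialize a hexagonal-lattice disc of particles
#'
#' Builds the equilibrium configuration used to start simulations: a
#' triangular (hexagonally packed) lattice at spacing `r0`, clipped to a
#' disc by keeping the `n_target` sites closest to the lattice centre.
#' Headings are drawn independently and uniformly on `(-pi, pi]`.
#'
#' @param n_target Number of particles (>= 7).
#' @param r0 Lattice spacing.
#' @param seed Optional seed; when supplied the global RNG is seeded first,
#'   otherwise the current RNG stream is used.
#' @return A [sheet_state()].
#' @examples
#' st <- init_hex_disc(7, seed = 1)
#' nrow(st$positions)
#' @export
init_hex_disc <- function(n_target, r0 = 1, seed = NULL) {
  if (n_target < 7) stop("'n_target' must be >= 7")
  if (!is.null(seed)) set.seed(seed)
  m <- ceiling(sqrt(n_target / pi) * 1.6) + 2
  rows <- -m:m
  pts <- do.call(rbind, lapply(rows, function(j) {
    x <- (-m:m) * r0 + (j %% 2) * r0 / 2
    cbind(x, j * r0 * sqrt(3) / 2)
  }))
  d2 <- pts[, 1]^2 + pts[, 2]^2
  # deterministic order: distance from centre, then angle
  ord <- order(round(d2, 9), atan2(pts[, 2], pts[, 1]))
  pts <- pts[ord[seq_len(n_target)], , drop = FALSE]
  sheet_state(pts, runif(n_target, -pi, pi), time = 0)
}
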