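#' Specification for a synthetic affine-plus-noise vector field
#'
#' Describes a synthetic flow field mimicking per-frame tissue optical-flow
#' measurements: points scattered in a disc with velocity composed of a
#' weighted mixture of the three affine modes (uniform translation,
#' solid-body rotation about the centre of mass, radial expansion) plus
#' isotropic Gaussian fluctuation noise carrying a prescribed fraction of
#' the total velocity power.
#'
#' @param weights Named numeric weights for `translation`, `rotation`,
#'   `expansion` (relative power of each affine mode; any may be 0, not
#'   all simultaneously when `noise_power < 1`).
#' @param noise_power Fraction of total velocity power in the noise,
#'   in `[0, 1]`.
#' @param n_points Number of tracked regions (>= 3).
#' @param radius Footprint disc radius.
#' @param speed RMS speed of the field (sets the overall scale).
#' @param seed RNG seed.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(weights = c(translation = 1, rotation = 0,
                                     expansion = 0),
                         noise_power = 0, n_points = 500, radius = 10,
                         speed = 1, seed = 1L) {
  w <- c(translation = 0, rotation = 0, expansion = 0)
  if (is.null(names(weights))) names(weights) <- names(w)[seq_along(weights)]
  bad <- setdiff(names(weights), names(w))
  if (length(bad)) stop("unknown weight names: ", paste(bad, collapse = ", "))
  w[names(weights)] <- weights
  if (any(w < 0) || any(!is.finite(w))) {
    stop("invalid weights: must be finite and >= 0")
  }
  if (noise_power < 0 || noise_power > 1) stop("'noise_power' must be in [0, 1]")
  if (sum(w) == 0 && noise_power < 1) {
    stop("all affine weights are zero but noise_power < 1")
  }
  if (n_points < 3) stop("'n_points' must be >= 3")
  structure(list(weights = w, noise_power = noise_power,
                 n_points = as.integer(n_points), radius = radius,
                 speed = speed, seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Generate a synthetic affine-plus-noise velocity field
#'
#' Samples `n_points` positions uniformly in a disc and builds velocities
#' as the weighted sum of the three affine modes plus isotropic Gaussian
#' noise. Each mode and the noise are scaled to unit root-mean-square speed
#' over the realized points before weighting, so the `noise_power` fraction
#' of the field's velocity power is carried by the noise by construction
#' and the measured noise proxy `eta*` converges to `noise_power` as
#' `n_points` grows. Pure functions of the spec: the same spec always
#' yields the same field.
#'
#' @param spec A [mixture_spec()].
#' @return A [velocity_field()] with a 64-gon disc footprint.
#' @examples
#' f <- gen_affine_field(mixture_spec(c(rotation = 1), n_points = 300))
#' unified_order(f)$O # 1: pure affine motion
#' @export
gen_affine_field <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_points
  th <- runif(n, -pi, pi)
  rad <- spec$radius * sqrt(runif(n))
  pos <- cbind(rad * cos(th), rad * sin(th))
  com <- colMeans(pos)
  rv <- sweep(pos, 2, com)
  unit_rms <- function(m) {
    p <- sqrt(mean(rowSums(m^2)))
    if (p > 0) m / p else m
  }
  modes <- list(
    translation = matrix(rep(c(1, 0), each = n), n, 2),
    rotation = unit_rms(cbind(-rv[, 2], rv[, 1])),
    expansion = unit_rms(rv))
  w <- spec$weights
  aff <- matrix(0, n, 2)
  if (sum(w) > 0) {
    w <- w / sum(w)
    for (nm in names(w)) aff <- aff + sqrt(w[[nm]]) * modes[[nm]]
    aff <- unit_rms(aff)
  }
  noise <- unit_rms(matrix(rnorm(2 * n), n, 2))
  p <- spec$noise_power
  vel <- spec$speed * (sqrt(1 - p) * aff + sqrt(p) * noise)
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  footprint <- cbind(spec$radius * cos(ang), spec$radius * sin(ang))
  velocity_field(pos, vel, time = 0, footprint = footprint)
}

#' Equivalent-circle diameter
#'
#' Diameter of the circle whose area equals the given footprint area:
#' `D = 2 sqrt(area / pi)`.
#'
#' @param area Footprint area (> 0).
#' @return Diameter in the corresponding length unit.
#' @export
equivalent_diameter <- function(area) {
  if (any(area <= 0)) stop("'area' must be > 0")
  2 * sqrt(area / pi)
}

#' Filter frames by footprint area
#'
#' Keeps only frames whose observed footprint area is at least
#' `threshold_fraction` of the maximum observed area, suppressing frames
#' where out-of-plane buckling shrinks the apparent footprint.
#'
#' @param frame_areas Per-frame areas (>= 1 value).
#' @param threshold_fraction Fraction of the maximum area (default 0.80).
#' @return Integer indices of the kept frames.
#' @export
area_filter <- function(frame_areas, threshold_fraction = 0.80) {
  if (length(frame_areas) == 0) stop("'frame_areas' is empty")
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("'threshold_fraction' must be in (0, 1]")
  }
  which(frame_areas >= threshold_fraction * max(frame_areas))
}

# shoelace polygon area (vertices in order, implicitly closed)
polygon_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# minimum distance from points to a polygon boundary (point-to-segment)
polygon_boundary_distance <- function(points, poly) {
  m <- nrow(poly)
  j <- c(seq_len(m)[-1], 1)
  ax <- poly[, 1]
  ay <- poly[, 2]
  bx <- poly[j, 1]
  by <- poly[j, 2]
  ex <- bx - ax
  ey <- by - ay
  el2 <- ex^2 + ey^2
  apply(points, 1, function(p) {
    t <- pmin(1, pmax(0, ((p[1] - ax) * ex + (p[2] - ay) * ey) / el2))
    min(sqrt((p[1] - (ax + t * ex))^2 + (p[2] - (ay + t * ey))^2))
  })
}

#' Exclude entries near the footprint boundary
#'
#' Removes velocity vectors closer to the footprint boundary than
#' `fraction` of the equivalent-circle diameter, the standard guard against
#' optical-flow edge artifacts.
#'
#' @param field A [velocity_field()] with a footprint polygon.
#' @param fraction Band width as a fraction of the equivalent diameter
#'   (default 0.10; must satisfy `0 <= fraction < 0.5`).
#' @return The filtered [velocity_field()] (warns when empty).
#' @export
edge_exclusion <- function(field, fraction = 0.10) {
  if (is.null(field$footprint)) {
    stop("field has no footprint polygon; edge exclusion undefined")
  }
  if (fraction < 0 || fraction >= 0.5) stop("'fraction' must be in [0, 0.5)")
  if (fraction == 0) return(field)
  diam <- equivalent_diameter(polygon_area(field$footprint))
  d <- polygon_boundary_distance(field$positions, field$footprint)
  keep <- d >= fraction * diam
  if (!any(keep)) warning("edge exclusion removed every entry")
  velocity_field(field$positions[keep, , drop = FALSE],
                 field$velocities[keep, , drop = FALSE],
                 time = field$time, footprint = field$footprint)
}
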