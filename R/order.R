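#' Velocity field container
#'
#' A per-frame flow field: one position and one velocity vector per tracked
#' region (or simulated particle). This is the common currency between the
#' simulator, the synthetic-field generator, empirical optical-flow imports
#' and all order/fluctuation/correlation analyses.
#'
#' @param positions Numeric matrix (n x 2) of region positions.
#' @param velocities Numeric matrix (n x 2) of instantaneous velocities.
#' @param time Frame time.
#' @param footprint Optional polygon (m x 2 matrix of vertices, implicitly
#'   closed) outlining the tissue footprint; required by [edge_exclusion()].
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(positions, velocities, time = NA_real_,
                           footprint = NULL) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  if (ncol(positions) != 2 || ncol(velocities) != 2) {
    stop("'positions' and 'velocities' must have two columns")
  }
  if (nrow(positions) != nrow(velocities)) {
    stop("'positions' and 'velocities' must have equal lengths")
  }
  if (!all(is.finite(positions)) || !all(is.finite(velocities))) {
    stop("velocity field entries must be finite")
  }
  structure(list(positions = unname(positions),
                 velocities = unname(velocities),
                 time = time, footprint = footprint),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d vectors at t = %s\n",
              nrow(x$positions), format(x$time)))
  invisible(x)
}

# unit velocity vectors; drops zero-velocity entries (undefined direction)
unit_velocities <- function(field) {
  sp <- sqrt(rowSums(field$velocities^2))
  keep <- sp > 0
  if (sum(keep) < 2) {
    stop("undefined order: fewer than 2 nonzero velocity vectors")
  }
  list(vhat = field$velocities[keep, , drop = FALSE] / sp[keep], keep = keep)
}

# unit vectors from the field's (unweighted) centre of mass to each entry
radial_units <- function(field, keep) {
  com <- colMeans(field$positions)
  rvec <- sweep(field$positions[keep, , drop = FALSE], 2, com)
  rlen <- sqrt(rowSums(rvec^2))
  ok <- rlen > 0
  list(rhat = rvec[ok, , drop = FALSE] / rlen[ok], ok = ok)
}

#' Polarization order parameter
#'
#' `P = || (1/N) sum_i vhat_i ||`, the magnitude of the mean unit velocity:
#' 1 for perfectly parallel motion, near 0 for disordered motion.
#' Zero-velocity entries have no direction and are excluded (reducing `N`).
#'
#' @param field A [velocity_field()].
#' @return Scalar in `[0, 1]`.
#' @export
polarization <- function(field) {
  u <- unit_velocities(field)
  sqrt(sum(colMeans(u$vhat)^2))
}

#' Rotation (vorticity) order parameter
#'
#' `R = (1/N) sum_i (rhat_ic x vhat_i)_z`, the mean z-component of the cross
#' product between the unit vector from the field's centre of mass to entry
#' `i` and the entry's unit velocity. Signed: +1 is solid-body
#' counterclockwise rotation, -1 clockwise. Entries at the exact centre of
#' mass are excluded.
#'
#' @param field A [velocity_field()].
#' @return Signed scalar in `[-1, 1]`.
#' @export
rotation_order <- function(field) {
  u <- unit_velocities(field)
  r <- radial_units(field, u$keep)
  if (nrow(r$rhat) == 0) stop("undefined order: all entries at the centre of mass")
  v <- u$vhat[r$ok, , drop = FALSE]
  mean(r$rhat[, 1] * v[, 2] - r$rhat[, 2] * v[, 1])
}

#' Dilatation (expansion/contraction) order parameter
#'
#' `Delta = (1/N) sum_i rhat_ic . vhat_i`, the mean radial projection of the
#' unit velocities: +1 pure expansion, -1 pure contraction.
#'
#' @param field A [velocity_field()].
#' @return Signed scalar in `[-1, 1]`.
#' @export
dilatation_order <- function(field) {
  u <- unit_velocities(field)
  r <- radial_units(field, u$keep)
  if (nrow(r$rhat) == 0) stop("undefined order: all entries at the centre of mass")
  v <- u$vhat[r$ok, , drop = FALSE]
  mean(rowSums(r$rhat * v))
}

#' Unified collective order
#'
#' Combines the three order parameters into a single collective-order
#' measure `O = sqrt(P^2 + R^2 + Delta^2)`: 0 for completely disordered
#' motion, 1 for a pure affine (solid-body) transformation. For strongly
#' asymmetric footprints a pure translation can carry small nonzero mean
#' rotation/dilatation terms, so `O` may marginally exceed 1; the raw value
#' is returned, never clamped.
#'
#' @param field A [velocity_field()].
#' @return An object of class `order_sample` with elements `P`, `R_signed`,
#'   `Delta_signed`, `O` and `time`.
#' @examples
#' th <- runif(100, -pi, pi)
#' pos <- cbind(cos(th), sin(th)) * sqrt(runif(100))
#' com <- colMeans(pos)
#' rv <- sweep(pos, 2, com)
#' vrot <- cbind(-rv[, 2], rv[, 1]) / sqrt(rowSums(rv^2))
#' unified_order(velocity_field(pos, vrot))$R_signed # 1: solid-body rotation
#' @export
unified_order <- function(field) {
  P <- polarization(field)
  R <- rotation_order(field)
  Delta <- dilatation_order(field)
  structure(list(P = P, R_signed = R, Delta_signed = Delta,
                 O = sqrt(P^2 + R^2 + Delta^2), time = field$time),
            class = "order_sample")
}

#' @export
print.order_sample <- function(x, ...) {
  cat(sprintf("order_sample: P = %.4f, R = %+.4f, Delta = %+.4f, O = %.4f\n",
              x$P, x$R_signed, x$Delta_signed, x$O))
  invisible(x)
}

#' Order time series over a sequence of velocity fields
#'
#' @param fields List of [velocity_field()] objects.
#' @return A list of class `order_series`: `samples` (data frame with
#'   columns `time`, `P`, `R`, `Delta`, `O`), `mean_O`, and `se_O` (standard
#'   error of the mean across frames).
#' @export
order_series <- function(fields) {
  if (length(fields) == 0) stop("'fields' must contain at least one field")
  rows <- lapply(fields, function(f) {
    s <- unified_order(f)
    data.frame(time = s$time, P = s$P, R = s$R_signed, Delta = s$Delta_signed,
               O = s$O)
  })
  samples <- do.call(rbind, rows)
  n <- nrow(samples)
  se <- if (n > 1) sd(samples$O) / sqrt(n) else 0
  structure(list(samples = samples, mean_O = mean(samples$O), se_O = se),
            class = "order_series")
}

#' @export
print.order_series <- function(x, ...) {
  cat(sprintf("order_series: %d frames, mean O = %.4f (SE %.4f)\n",
              nrow(x$samples), x$mean_O, x$se_O))
  invisible(x)
}
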