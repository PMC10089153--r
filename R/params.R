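#' Model parameters for the elastic SPP sheet
#'
#' Bundles every constant of the overdamped elastic self-propelled-particle
#' model. Lengths are expressed in units of the equilibrium spacing `r0`
#' (one particle stands for a disc of tissue roughly 20 micrometres across,
#' the typical fiber-cell separation), times in units of the heading
#' relaxation time scale, so the dynamics are dimensionless.
#'
#' @param k Spring coupling strength (force per unit extension). The sole
#'   control parameter scanned to move the sheet between disordered and
#'   ordered locomotion.
#' @param r0 Equilibrium interparticle distance. Default 1, which rescales
#'   all other parameters.
#' @param v0 Self-propulsion speed (length/time).
#' @param mu Mobility of a particle. Default 1 (absorbed into `k`).
#' @param tau Relaxation time of the heading toward the local elastic force
#'   direction.
#' @param D Angular noise intensity (rad^2/time) of the Gaussian white noise
#'   on the heading. The default 0.35 is calibrated (with `v0 = tau = 1`)
#'   so that the finite-size susceptibility peak of the order-disorder
#'   transition falls inside the scanned coupling range, near `k ~ 3-4`.
#' @param dt Integration time step. Must satisfy `dt <= tau/10`; default
#'   `min(0.01, tau/10)`.
#' @param n_particles Number of particles in the sheet.
#' @param seed Integer RNG seed recorded with the parameters.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(k = 3.5, n_particles = 400)
#' p$dt
#' @export
model_params <- function(k, r0 = 1, v0 = 1, mu = 1, tau = 1, D = 0.35,
                         dt = min(0.01, tau / 10), n_particles = 400,
                         seed = 1L) {
  stopifnot(is.numeric(k), length(k) == 1)
  if (k < 0) stop("'k' must be >= 0")
  if (r0 <= 0) stop("'r0' must be > 0")
  if (v0 < 0) stop("'v0' must be >= 0")
  if (tau <= 0) stop("'tau' must be > 0")
  if (D < 0) stop("'D' must be >= 0")
  if (dt <= 0) stop("'dt' must be > 0")
  if (dt > tau / 10) {
    stop("'dt' must be <= tau/10 for a stable heading update (dt = ", dt,
         ", tau = ", tau, ")")
  }
  if (n_particles < 7) stop("'n_particles' must be >= 7")
  structure(list(k = k, r0 = r0, v0 = v0, mu = mu, tau = tau, D = D,
                 dt = dt, n_particles = as.integer(n_particles),
                 seed = as.integer(seed)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Elastic SPP sheet parameters\n")
  cat(sprintf("  k = %g, r0 = %g, v0 = %g, mu = %g, tau = %g, D = %g\n",
              x$k, x$r0, x$v0, x$mu, x$tau, x$D))
  cat(sprintf("  dt = %g, n_particles = %d, seed = %d\n",
              x$dt, x$n_particles, x$seed))
  invisible(x)
}
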