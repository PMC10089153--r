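#' Linear spring force between two particles
#'
#' The elastic coupling is a linear attraction-repulsion spring:
#' `F = k (|r_j - r_i| - r0) * unit(r_j - r_i)`, the force exerted on
#' particle `i` by particle `j`. It is attractive when the separation
#' exceeds `r0`, repulsive below it, and antisymmetric under exchange of
#' the two particles.
#'
#' @param r_i,r_j Position 2-vectors of the two particles.
#' @param k Spring coupling strength.
#' @param r0 Equilibrium distance.
#' @return Force 2-vector acting on particle `i`.
#' @examples
#' pair_force(c(0, 0), c(1.5, 0), k = 2, r0 = 1) # attractive, magnitude 1
#' @export
pair_force <- function(r_i, r_j, k, r0 = 1) {
  dr <- as.numeric(r_j) - as.numeric(r_i)
  d <- sqrt(sum(dr^2))
  if (d == 0) stop("degenerate geometry: coincident points")
  k * (d - r0) * dr / d
}

# net spring force on every particle; edges from a neighbor_topology
net_forces <- function(positions, edges, k, r0) {
  n <- nrow(positions)
  f <- matrix(0, n, 2)
  if (nrow(edges) == 0 || k == 0) return(f)
  e1 <- edges[, 1]
  e2 <- edges[, 2]
  dr <- positions[e2, , drop = FALSE] - positions[e1, , drop = FALSE]
  d <- sqrt(rowSums(dr^2))
  if (any(d == 0)) stop("degenerate geometry: coincident particles")
  fe <- dr * (k * (d - r0) / d)
  idx <- c(e1, e2)
  val <- rbind(fe, -fe)
  acc <- rowsum(val, idx)
  f[as.integer(rownames(acc)), ] <- acc
  f
}

#' One Euler-Maruyama step of the elastic SPP sheet
#'
#' Advances positions and headings by one time step `dt`:
#' positions move with the self-propulsion plus the mobility-scaled net
#' spring force; each heading relaxes toward the polar angle of its net
#' spring force with rate `1/tau` (the relaxation term is zero for a
#' particle whose net force vanishes) and receives additive angular noise
#' `sqrt(2 D dt) * xi` with standard-normal `xi`. Noise is drawn from the
#' global RNG, one `rnorm(n)` vector per step.
#'
#' @param state A [sheet_state()].
#' @param topology A [build_topology()] result for the same particle count.
#' @param params A [model_params()].
#' @return The advanced `sheet_state`.
#' @export
step_sheet <- function(state, topology, params) {
  if (topology$n != nrow(state$positions)) {
    stop("topology was built for a different particle count")
  }
  p <- params
  f <- net_forces(state$positions, topology$edges, p$k, p$r0)
  vhat <- cbind(cos(state$headings), sin(state$headings))
  pos <- state$positions + p$dt * (p$v0 * vhat + p$mu * f)
  if (!all(is.finite(pos))) {
    stop("integration instability: non-finite positions (dt = ", p$dt,
         " may be too large for k = ", p$k, ")")
  }
  # |f| <= 1e-10 treated as zero: atan2 of a roundoff-level force is
  # ill-conditioned and the relaxation term vanishes with the force
  has_f <- f[, 1]^2 + f[, 2]^2 > 1e-20
  relax <- numeric(topology$n)
  theta <- atan2(f[has_f, 2], f[has_f, 1])
  relax[has_f] <- sin(theta - state$headings[has_f]) / p$tau
  phi <- state$headings + p$dt * relax +
    sqrt(2 * p$D * p$dt) * rnorm(topology$n)
  sheet_state(pos, phi, time = state$time + p$dt)
}

#' Simulate an elastic SPP sheet
#'
#' Initializes a hexagonal disc of `params$n_particles` particles with
#' uniform random headings, builds the fixed Voronoi topology once, and
#' integrates the overdamped dynamics for `n_steps` steps, sampling a frame
#' every `sample_every` steps after `burn_in` steps. The inner loop runs in
#' compiled code but draws its noise from R's RNG in the same order as
#' [step_sheet()], so runs are bitwise reproducible for a fixed seed.
#'
#' @param params A [model_params()].
#' @param n_steps Total number of integration steps (> `burn_in`).
#' @param burn_in Steps discarded before sampling starts.
#' @param sample_every Sampling stride in steps.
#' @param seed Seed for the run; defaults to `params$seed`.
#' @param state Optional initial [sheet_state()]; by default a hexagonal
#'   disc with random headings.
#' @param max_edge_factor Pruning factor passed to [build_topology()].
#' @return An object of class `trajectory`: sampled frames (each a
#'   `sheet_state`), frame times, the parameters, topology, seed and the
#'   sampling interval.
#' @examples
#' p <- model_params(k = 2, n_particles = 50, seed = 7)
#' tr <- simulate_sheet(p, n_steps = 200, burn_in = 100, sample_every = 50)
#' length(tr$frames)
#' @export
simulate_sheet <- function(params, n_steps, burn_in = 0, sample_every = 1,
                     seed = params$seed, state = NULL,
                     max_edge_factor = 1.8) {
  if (n_steps <= burn_in) stop("'n_steps' must exceed 'burn_in'")
  set.seed(seed)
  if (is.null(state)) {
    state <- init_hex_disc(params$n_particles, params$r0)
  }
  topology <- build_topology(state$positions, max_edge_factor, params$r0)
  res <- sim_run_cpp(state$positions, state$headings, topology$edges - 1L,
                     params$k, params$r0, params$v0, params$mu, params$tau,
                     params$D, params$dt, as.integer(n_steps),
                     as.integer(burn_in), as.integer(sample_every))
  if (!res$ok) {
    stop("integration instability at step ", res$bad_step,
         ": non-finite positions (dt = ", params$dt, " may be too large)")
  }
  frames <- Map(function(p, ph, t) sheet_state(p, ph, time = t),
                res$positions, res$headings, as.list(res$times))
  structure(list(frames = frames, times = as.numeric(res$times),
                 params = params, topology = topology, seed = seed,
                 sample_interval = sample_every * params$dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames of %d particles, dt_frame = %g, k = %g\n",
              length(x$frames), x$topology$n, x$sample_interval, x$params$k))
  invisible(x)
}

#' Finite-difference velocity fields from a trajectory
#'
#' Computes per-frame instantaneous velocities
#' `v_i = (r_i(t + lag * dt_frame) - r_i(t)) / (lag * dt_frame)`, one
#' velocity field per usable frame pair, anchored at the earlier frame's
#' positions and time.
#'
#' @param traj A [simulate_sheet()] trajectory.
#' @param lag Frame lag (>= 1).
#' @return A list of [velocity_field()] objects.
#' @export
frame_velocities <- function(traj, lag = 1) {
  nf <- length(traj$frames)
  if (lag < 1) stop("'lag' must be >= 1")
  if (lag >= nf) stop("'lag' must be smaller than the number of frames")
  dt <- traj$sample_interval * lag
  lapply(seq_len(nf - lag), function(t) {
    p0 <- traj$frames[[t]]$positions
    p1 <- traj$frames[[t + lag]]$positions
    velocity_field(p0, (p1 - p0) / dt, time = traj$times[t])
  })
}
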