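#' Control settings for sweep simulations
#'
#' Time-unit run lengths used by [criticality_sweep()] (converted to steps
#' with the parameter set's `dt`): `t_burn` time units are discarded,
#' frames are then sampled every `frame_dt` for `t_sample` time units.
#' Correlation profiles are computed on `corr_frames` evenly spaced frame
#' pairs and averaged before extracting `lambda_v` and `chi`.
#'
#' @param t_burn Burn-in, time units.
#' @param t_sample Sampled duration, time units.
#' @param frame_dt Frame sampling interval, time units.
#' @param corr_frames Number of frame pairs used for correlation profiles.
#' @param bin_width Distance bin width for correlation profiles.
#' @param objective Affine-fit objective for the fluctuation analysis.
#' @return A named list of class `sweep_control`.
#' @export
sweep_control <- function(t_burn = 100, t_sample = 80, frame_dt = 1,
                          corr_frames = 8, bin_width = 0.5,
                          objective = "l2") {
  structure(list(t_burn = t_burn, t_sample = t_sample, frame_dt = frame_dt,
                 corr_frames = corr_frames, bin_width = bin_width,
                 objective = objective),
            class = "sweep_control")
}

# deterministic per-run seed derivation (counter-based, < 2^31)
derive_seed <- function(base_seed, counter) {
  as.integer((as.numeric(base_seed) + 7919 * counter) %% 2147483647L) + 1L
}

# full single-run analysis: order series, susceptibility, noise proxy,
# averaged velocity-correlation profile and its summary
analyze_run <- function(params, seed, control) {
  dt <- params$dt
  burn <- round(control$t_burn / dt)
  stride <- max(1L, round(control$frame_dt / dt))
  n_frames <- max(2L, round(control$t_sample / control$frame_dt))
  traj <- simulate_sheet(params, n_steps = burn + stride * n_frames,
                         burn_in = burn, sample_every = stride, seed = seed)
  fields <- frame_velocities(traj, lag = 1)
  os <- order_series(fields)
  flucts <- lapply(seq_along(fields), function(t) {
    fluctuations(traj$frames[[t]]$positions, traj$frames[[t + 1]]$positions,
                 dt = traj$sample_interval, objective = control$objective)
  })
  eta <- vapply(flucts, `[[`, numeric(1), "eta_star")
  pick <- unique(round(seq(1, length(flucts),
                           length.out = min(control$corr_frames,
                                            length(flucts)))))
  profs <- lapply(flucts[pick], correlation_profile,
                  bin_width = control$bin_width)
  summ <- profile_summary(average_profiles(profs))
  O <- os$samples$O
  o_prime <- if (length(O) >= 20 && var(eta) > 0) {
    order_noise_steepness(O, eta)
  } else {
    NA_real_
  }
  list(mean_O = os$mean_O, se_O = os$se_O,
       chi0 = order_susceptibility(O, params$n_particles),
       mean_eta_star = mean(eta), lambda_v = summ$lambda_v, chi = summ$chi,
       o_prime = o_prime, O = O, eta_star = eta)
}

#' Parameter sweep over coupling strength and system size
#'
#' Runs the full simulate-and-analyze pipeline over a grid of spring
#' couplings `k` and particle counts `N` with replicate runs, recording for
#' every grid cell the time-mean unified order, the order susceptibility
#' `chi0`, the mean noise proxy `eta*`, the velocity correlation length
#' `lambda_v`, the correlation integral `chi`, and the per-run steepness
#' `O'(eta*)`. Replicate seeds are derived from `seed` by a counter, so the
#' sweep is deterministic; a failing cell is recorded (`NA` row) without
#' aborting the sweep.
#'
#' @param k_values Couplings to scan (>= 2 values).
#' @param n_values Particle counts to scan.
#' @param replicates Replicate runs per grid cell (>= 1).
#' @param base_params A [model_params()] supplying all other constants.
#' @param seed Base seed for the sweep.
#' @param control A [sweep_control()].
#' @return Data frame with one row per (k, N, replicate): columns `k`,
#'   `n_particles`, `replicate`, `seed`, `mean_O`, `se_O`, `chi0`,
#'   `mean_eta_star`, `lambda_v`, `chi`, `o_prime`, `diameter`. The per-run
#'   `(O, eta*)` series are attached as attribute `"series"`.
#' @export
criticality_sweep <- function(k_values, n_values, replicates = 1,
                              base_params = model_params(k = 1),
                              seed = 1L, control = sweep_control()) {
  if (length(k_values) < 1) stop("need at least one k value")
  if (replicates < 1) stop("'replicates' must be >= 1")
  grid <- expand.grid(replicate = seq_len(replicates), k = k_values,
                      n_particles = n_values)
  rows <- vector("list", nrow(grid))
  series <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- base_params
    p$k <- grid$k[g]
    p$n_particles <- as.integer(grid$n_particles[g])
    run_seed <- derive_seed(seed, g)
    res <- tryCatch(analyze_run(p, run_seed, control),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[g]] <- data.frame(
        k = p$k, n_particles = p$n_particles,
        replicate = grid$replicate[g], seed = run_seed, mean_O = NA_real_,
        se_O = NA_real_, chi0 = NA_real_, mean_eta_star = NA_real_,
        lambda_v = NA_real_, chi = NA_real_, o_prime = NA_real_,
        diameter = sheet_diameter(p$n_particles, p$r0),
        failed = TRUE)
      warning("sweep cell (k = ", p$k, ", N = ", p$n_particles,
              ", replicate ", grid$replicate[g], ") failed: ",
              conditionMessage(res))
    } else {
      rows[[g]] <- data.frame(
        k = p$k, n_particles = p$n_particles,
        replicate = grid$replicate[g], seed = run_seed,
        mean_O = res$mean_O, se_O = res$se_O, chi0 = res$chi0,
        mean_eta_star = res$mean_eta_star, lambda_v = res$lambda_v,
        chi = res$chi, o_prime = res$o_prime,
        diameter = sheet_diameter(p$n_particles, p$r0), failed = FALSE)
      series[[g]] <- data.frame(k = p$k, n_particles = p$n_particles,
                                replicate = grid$replicate[g],
                                O = res$O, eta_star = res$eta_star)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "series") <- do.call(rbind, series)
  out
}

#' Equivalent-circle diameter of a simulated sheet
#'
#' The footprint area of an `n`-particle hexagonal sheet is `n` times the
#' area per lattice site, `sqrt(3)/2 * r0^2`; the diameter is that of the
#' circle of equivalent area, making simulated and empirical size scales
#' commensurable.
#'
#' @param n Particle count.
#' @param r0 Equilibrium spacing.
#' @return Diameter in the same units as `r0`.
#' @export
sheet_diameter <- function(n, r0 = 1) {
  equivalent_diameter(n * sqrt(3) / 2 * r0^2)
}

#' Locate the critical coupling from a sweep
#'
#' Finds the coupling `k` that maximizes the replicate-averaged order
#' susceptibility `chi0` at a given system size, refined by quadratic
#' interpolation through the grid maximum and its two neighbors. A peak at
#' a grid edge is returned but flagged (with a warning): the true maximum
#' may lie outside the scanned range.
#'
#' @param sweep_df Result of [criticality_sweep()].
#' @param n System size to analyze.
#' @return List of class `critical_estimate`: `k_c`, `interior`, `k_grid`,
#'   `chi0_mean`.
#' @export
locate_critical <- function(sweep_df, n) {
  df <- sweep_df[sweep_df$n_particles == n & !is.na(sweep_df$chi0), ]
  if (nrow(df) == 0) stop("no sweep rows for N = ", n)
  agg <- aggregate(chi0 ~ k, data = df, FUN = mean)
  agg <- agg[order(agg$k), ]
  if (nrow(agg) < 5) stop("need at least 5 k values at N = ", n)
  i <- which.max(agg$chi0)
  interior <- i > 1 && i < nrow(agg)
  k_c <- agg$k[i]
  if (interior) {
    x <- agg$k[(i - 1):(i + 1)]
    y <- agg$chi0[(i - 1):(i + 1)]
    b <- coef(lm(y ~ x + I(x^2)))
    if (is.finite(b[3]) && b[3] < 0) {
      vertex <- -b[2] / (2 * b[3])
      if (vertex >= x[1] && vertex <= x[3]) k_c <- unname(vertex)
    }
  } else {
    warning("susceptibility peak is at the edge of the k grid (k = ",
            k_c, "); estimate flagged non-interior")
  }
  structure(list(k_c = k_c, interior = interior, k_grid = agg$k,
                 chi0_mean = agg$chi0),
            class = "critical_estimate")
}

#' @export
print.critical_estimate <- function(x, ...) {
  cat(sprintf("critical_estimate: k_c = %.3f (%s peak)\n", x$k_c,
              if (x$interior) "interior" else "edge"))
  invisible(x)
}

#' Steepness of the order-noise relation for one run
#'
#' Ordinary least-squares slope of the instantaneous unified order `O` on
#' the instantaneous noise proxy `eta*` across the frames of a single run.
#' More negative slopes mean a steeper effective phase transition.
#'
#' @param O Per-frame unified order values (>= 20).
#' @param eta_star Matching per-frame noise-proxy values.
#' @return Scalar slope `O'(eta*)`.
#' @export
order_noise_steepness <- function(O, eta_star) {
  if (length(O) != length(eta_star)) stop("lengths differ")
  if (length(O) < 20) stop("insufficient data: need at least 20 frames")
  if (var(eta_star) == 0) stop("insufficient variation: eta* is constant")
  unname(coef(lm(O ~ eta_star))[2])
}

#' Logarithmic fit of transition steepness against system size
#'
#' Fits `slope = a + b log(size)`. A negative `b` reproduces the
#' finite-size phenomenology in which the order-noise relation steepens
#' (becomes more negative) with organism size.
#'
#' @param slopes Per-run steepness values `O'(eta*)`.
#' @param sizes Matching system sizes (particle counts or diameters).
#' @return List with `a`, `b`, `adj_r2`, `p_b` and the `lm` fit.
#' @export
steepness_size_fit <- function(slopes, sizes) {
  if (length(unique(sizes)) < 4) {
    stop("insufficient data: need at least 4 distinct sizes")
  }
  fit <- lm(slopes ~ log(sizes))
  s <- summary(fit)
  list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
       adj_r2 = s$adj.r.squared, p_b = s$coefficients[2, 4], fit = fit)
}

#' Sublinear power-law fit of the correlation integral against diameter
#'
#' Nonlinear least squares for `chi = alpha * D^beta + gamma`, initialized
#' from a log-log pre-fit (`beta` from the slope of
#' `log(chi - min(chi) + 1)` on `log(D)`, `gamma` from the small-`D`
#' intercept). `beta < 1` is reported as sublinear. A constant-`chi` input
#' is degenerate (`alpha * D^0` is indistinguishable from `gamma`) and is
#' returned flagged instead of fitted.
#'
#' @param chi_values Correlation integrals.
#' @param diameters Matching diameters (> 0).
#' @return List with `alpha`, `beta`, `gamma`, `sublinear`, `degenerate`
#'   and the fit object (`NULL` when degenerate).
#' @export
chi_scaling_fit <- function(chi_values, diameters) {
  if (length(chi_values) < 4) stop("need at least 4 points")
  if (any(diameters <= 0)) stop("'diameters' must be > 0")
  if (sd(chi_values) < 1e-12 * (abs(mean(chi_values)) + 1)) {
    return(list(alpha = 0, beta = 0, gamma = mean(chi_values),
                sublinear = TRUE, degenerate = TRUE, fit = NULL))
  }
  pre <- lm(log(chi_values - min(chi_values) + 1) ~ log(diameters))
  beta0 <- max(0.05, min(3, unname(coef(pre)[2])))
  io <- order(diameters)[1]
  alpha0 <- (max(chi_values) - min(chi_values)) /
    max(max(diameters)^beta0 - min(diameters)^beta0, 1e-9)
  gamma0 <- chi_values[io] - alpha0 * diameters[io]^beta0
  df <- data.frame(chi = chi_values, D = diameters)
  fit <- minpack.lm::nlsLM(chi ~ alpha * D^beta + gamma, data = df,
                           start = list(alpha = alpha0, beta = beta0,
                                        gamma = gamma0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
       gamma = unname(cf["gamma"]), sublinear = unname(cf["beta"]) < 1,
       degenerate = FALSE, fit = fit)
}

#' Linear regression of collective order on diameter
#'
#' OLS fit of mean unified order against system diameter; the slope, its
#' t statistic and p value, and the adjusted R-squared quantify whether
#' larger systems are less ordered.
#'
#' @param mean_O Mean unified order per system.
#' @param diameters Matching diameters.
#' @return List with `slope`, `intercept`, `t`, `p`, `adj_r2`, `fit`.
#' @export
order_size_fit <- function(mean_O, diameters) {
  if (length(mean_O) < 4) stop("need at least 4 points")
  fit <- lm(mean_O ~ diameters)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       t = s$coefficients[2, 3], p = s$coefficients[2, 4],
       adj_r2 = s$adj.r.squared, fit = fit)
}
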