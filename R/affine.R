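#' Optimal similarity (affine) transformation between two frames
#'
#' Finds the translation `T`, rotation angle and isotropic dilatation that
#' best map the positions `y_t` onto `y_tdt` (point correspondence by row
#' index), the "collective" component of the frame-to-frame motion. The
#' residuals `u_i = y_i(t+dt) - T - scale * R y_i(t)` are the velocity
#' fluctuations (before division by the frame interval) and their summed
#' magnitude is the residual `epsilon = sum_i |u_i|`.
#'
#' The `"l2"` objective minimizes `sum |u_i|^2` and has the closed-form
#' similarity-Procrustes solution (both frames are centred on their means
#' before estimating rotation and scale, which the reported `T` then
#' absorbs). The `"l1"` objective minimizes `sum |u_i|` directly by
#' Nelder-Mead refinement over (T, angle, log scale) initialized at the L2
#' solution. `epsilon` is reported as `sum |u_i|` for both objectives.
#'
#' @param y_t,y_tdt Position matrices (n x 2), n >= 3, not collinear.
#' @param objective `"l2"` (default, closed form) or `"l1"`.
#' @return An object of class `affine_fit`: `T` (length-2 translation),
#'   `angle` (radians, counterclockwise), `scale` (> 0), `R` (2 x 2 rotation
#'   matrix), `epsilon`, `residuals` (n x 2), `objective`.
#' @examples
#' y <- cbind(runif(10), runif(10))
#' f <- fit_affine(y, y + rep(c(3.2, -1.7), each = 10))
#' f$T; f$epsilon # recovers the translation; epsilon ~ 0
#' @export
fit_affine <- function(y_t, y_tdt, objective = c("l2", "l1")) {
  objective <- match.arg(objective)
  y_t <- as.matrix(y_t)
  y_tdt <- as.matrix(y_tdt)
  if (nrow(y_t) != nrow(y_tdt)) stop("frame pair has unequal point counts")
  if (nrow(y_t) < 3) stop("degenerate fit: need at least 3 points")
  m0 <- colMeans(y_t)
  m1 <- colMeans(y_tdt)
  x0 <- sweep(y_t, 2, m0)
  x1 <- sweep(y_tdt, 2, m1)
  sv <- svd(x0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1)) {
    stop("degenerate fit: points are collinear")
  }
  # closed-form similarity Procrustes (rotation restricted to det +1)
  A <- crossprod(x1, x0)
  s <- svd(A)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, d)) %*% t(s$v)
  scale <- sum(s$d * c(1, d)) / sum(x0^2)
  par <- c(angle = atan2(R[2, 1], R[1, 1]), scale = scale)
  if (objective == "l1") {
    obj <- function(p) {
      Rp <- rot2(p[3])
      res <- y_tdt - tcrossprod(y_t, exp(p[4]) * Rp)
      res <- sweep(res, 2, c(p[1], p[2]))
      sum(sqrt(rowSums(res^2)))
    }
    Tr0 <- m1 - scale * as.numeric(R %*% m0)
    opt <- stats::optim(c(Tr0, par[["angle"]], log(scale)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    Tr <- opt$par[1:2]
    angle <- wrap_angle(opt$par[3])
    scale <- exp(opt$par[4])
    R <- rot2(angle)
  } else {
    angle <- par[["angle"]]
    Tr <- m1 - scale * as.numeric(R %*% m0)
  }
  res <- y_tdt - sweep(scale * tcrossprod(y_t, R), 2, -Tr)
  structure(list(T = unname(Tr), angle = unname(angle),
                 scale = unname(scale), R = unname(R),
                 epsilon = sum(sqrt(rowSums(res^2))),
                 residuals = unname(res), objective = objective),
            class = "affine_fit")
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf(
    "affine_fit (%s): T = (%.4g, %.4g), angle = %.4g rad, scale = %.6g, epsilon = %.4g\n",
    x$objective, x$T[1], x$T[2], x$angle, x$scale, x$epsilon))
  invisible(x)
}

#' Velocity fluctuations of a frame pair
#'
#' Removes the optimal affine (similarity) transform between two frames and
#' returns the residual motion as velocity fluctuations `u_i` (residual
#' displacement divided by the frame interval `dt`), their unit vectors
#' `w_i` (entries with `|u_i| = 0` excluded), and the speed fluctuations
#' `eta_i = |u_i| - mean |u|` relative to the global mean fluctuation
#' speed. The fluctuation power fraction `eta_star` (see [noise_proxy()])
#' is included.
#'
#' @param y_t,y_tdt Position matrices of the frame pair.
#' @param dt Frame interval (> 0).
#' @param objective Passed to [fit_affine()].
#' @return An object of class `fluctuation_field`: `u` (n x 2 velocities),
#'   `w` (unit vectors of the nonzero `u`), `w_index` (their row indices),
#'   `speed_fluct` (`eta_i`, all entries), `eta_star`, `pure_affine` flag,
#'   `fit` (the [fit_affine()] result), `positions` (`y_t`) and `dt`.
#' @export
fluctuations <- function(y_t, y_tdt, dt, objective = c("l2", "l1")) {
  if (dt <= 0) stop("'dt' must be > 0")
  fit <- fit_affine(y_t, y_tdt, objective)
  u <- fit$residuals / dt
  mag <- sqrt(rowSums(u^2))
  v <- (as.matrix(y_tdt) - as.matrix(y_t)) / dt
  vpow <- mean(rowSums(v^2))
  tol <- 1e-12 * max(sqrt(vpow), 1)
  pure <- all(mag <= tol)
  nz <- which(mag > tol)
  eta_star <- if (vpow > 0) mean(mag^2) / vpow else NA_real_
  structure(list(u = u, w = u[nz, , drop = FALSE] / mag[nz], w_index = nz,
                 speed_fluct = mag - mean(mag), eta_star = eta_star,
                 pure_affine = pure, fit = fit,
                 positions = unname(as.matrix(y_t)), dt = dt),
            class = "fluctuation_field")
}

#' @export
print.fluctuation_field <- function(x, ...) {
  cat(sprintf("fluctuation_field: %d entries, eta* = %s%s\n",
              nrow(x$u), format(x$eta_star, digits = 4),
              if (x$pure_affine) " (pure affine)" else ""))
  invisible(x)
}

#' Noise proxy: fluctuation share of the velocity power
#'
#' `eta* = <|u|^2> / <|v|^2>`, the mean squared fluctuation magnitude over
#' the mean squared full velocity. 0 means the motion is a pure affine
#' (collective) transformation; 1 means the optimal affine transform is the
#' identity and the fluctuations are the entire motion, i.e. no collective
#' movement component. Serves as a per-frame proxy for the intrinsic noise
#' level, which cannot be manipulated directly in living tissue.
#'
#' @param field A [velocity_field()] for the frame pair (its `velocities`
#'   are the full velocities `v_i`).
#' @param fluct The matching [fluctuations()] result.
#' @return Scalar in `[0, 1]` (up to numerical tolerance).
#' @export
noise_proxy <- function(field, fluct) {
  if (nrow(field$velocities) != nrow(fluct$u)) {
    stop("field and fluctuations have different entry counts")
  }
  vpow <- mean(rowSums(field$velocities^2))
  if (vpow == 0) stop("undefined noise proxy: all velocities are zero")
  mean(rowSums(fluct$u^2)) / vpow
}
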