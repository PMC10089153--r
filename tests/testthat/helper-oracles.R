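# Independent oracles and fixture builders shared across the suite.

# Brute-force Delaunay adjacency via the empty-circumcircle property:
# an edge belongs to the Delaunay triangulation iff it is part of a triangle
# whose circumcircle contains no other point. O(n^4); small n only.
bf_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        ax <- pts[i, 1]; ay <- pts[i, 2]
        bx <- pts[j, 1]; by <- pts[j, 2]
        cx <- pts[k, 1]; cy <- pts[k, 2]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) next # collinear triple
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
                 (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
                 (cx^2 + cy^2) * (bx - ax)) / d
        r2 <- (ax - ux)^2 + (ay - uy)^2
        d2 <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2
        d2[c(i, j, k)] <- Inf
        if (all(d2 >= r2 * (1 - 1e-9))) {
          edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
        }
      }
    }
  }
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

edge_key <- function(edges) paste(edges[, 1], edges[, 2], sep = "-")

# Brute-force similarity-transform optimizer: Nelder-Mead over
# (Tx, Ty, angle, log scale) from several starts, minimizing the summed
# squared residuals. Independent of the closed-form Procrustes path.
bf_affine <- function(y0, y1) {
  obj <- function(p) {
    R <- matrix(c(cos(p[3]), sin(p[3]), -sin(p[3]), cos(p[3])), 2, 2)
    res <- y1 - sweep(exp(p[4]) * tcrossprod(y0, R), 2, -p[1:2])
    sum(res^2)
  }
  starts <- list(c(0, 0, 0, 0), c(colMeans(y1) - colMeans(y0), 0, 0),
                 c(0, 0, 0.2, 0.05), c(0, 0, -0.2, -0.05))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  R <- matrix(c(cos(p[3]), sin(p[3]), -sin(p[3]), cos(p[3])), 2, 2)
  res <- y1 - sweep(exp(p[4]) * tcrossprod(y0, R), 2, -p[1:2])
  list(T = p[1:2], angle = p[3], scale = exp(p[4]),
       epsilon = sum(sqrt(rowSums(res^2))))
}

# points scattered in a disc (deterministic given seed)
disc_points <- function(n, radius = 10, seed = 1) {
  set.seed(seed)
  th <- runif(n, -pi, pi)
  rad <- radius * sqrt(runif(n))
  cbind(rad * cos(th), rad * sin(th))
}

# solid-body rotation field: unit velocities perpendicular to the radius
# from the centre of mass
solid_rotation_field <- function(n = 500, radius = 10, seed = 1) {
  pos <- disc_points(n, radius, seed)
  rv <- sweep(pos, 2, colMeans(pos))
  vel <- cbind(-rv[, 2], rv[, 1]) / sqrt(rowSums(rv^2))
  velocity_field(pos, vel)
}

# Mirror fixture with zero net affine component: point pairs at +-p with
# velocities +-q, where q has its net rotation and dilatation projections
# removed, so the optimal similarity transform of the frame pair
# (y, y + v dt) is exactly the identity and eta* = 1.
mirror_fluct_pair <- function(n_pairs = 100, radius = 5, dt = 0.5,
                              seed = 1) {
  set.seed(seed)
  p <- disc_points(n_pairs, radius, seed)
  q <- matrix(rnorm(2 * n_pairs), n_pairs, 2)
  # remove the best-fit rotation and dilatation generators from q
  p2 <- sum(p^2)
  omega <- sum(p[, 1] * q[, 2] - p[, 2] * q[, 1]) / p2
  e <- sum(rowSums(p * q)) / p2
  q <- q - e * p - omega * cbind(-p[, 2], p[, 1])
  pos <- rbind(p, -p)
  vel <- rbind(q, -q)
  list(y0 = pos, y1 = pos + vel * dt, dt = dt,
       field = velocity_field(pos, vel))
}

# hand-constructible correlation profile (bypasses correlation_profile)
synthetic_profile <- function(r, values, counts = rep(10, length(r)),
                              kind = "velocity", bin_width = diff(r[1:2])) {
  structure(list(bin_centers = r, values = values, pair_counts = counts,
                 c0 = 1, kind = kind, bin_width = bin_width),
            class = "correlation_profile")
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
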