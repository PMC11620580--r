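# Independent oracles used across the suite.

# Invert tan(beta) = (b/a) tan(phi) for phi in (0, pi/2) by bisection,
# vectorised over the inputs. Independent of the closed form under test.
bisect_phi_beta <- function(a, b, beta, tol = 1e-14) {
  lo <- rep(0, length(beta))
  hi <- rep(pi / 2 - 1e-12, length(beta))
  target <- tan(beta)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f <- (b / a) * tan(mid) - target
    up <- f < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

# exhaustive between-class-variance threshold search over all observed levels
brute_force_otsu <- function(gray) {
  v <- sort(unique(as.vector(gray)))
  best <- -Inf
  best_t <- v[1]
  for (t in v[-length(v)]) {
    g0 <- gray[gray <= t]
    g1 <- gray[gray > t]
    s <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
    if (s > best) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

# implicit ellipse-equation residual of a point in a cell's frame
ellipse_residual <- function(cell, p) {
  dx <- p[1] - cell$centre[1]
  dy <- p[2] - cell$centre[2]
  u <- dx * cos(cell$orientation) + dy * sin(cell$orientation)
  v <- -dx * sin(cell$orientation) + dy * cos(cell$orientation)
  (u / cell$type_params$half_length)^2 +
    (v / cell$type_params$half_width)^2 - 1
}

# assemble a colony object by hand from cell coordinates (all sated)
manual_colony <- function(x, y, theta, params) {
  structure(list(x = x, y = y, theta = theta,
                 type = rep(0L, length(x)),
                 mother = rep(0L, length(x)),
                 has_pd = rep(FALSE, length(x)),
                 used = rep(0L, length(x)),
                 n = length(x), params = params,
                 aborts = 0, stalled = FALSE),
            class = "colony")
}

fig10b_theta <- c(0.67, 0.14, 0.25, 0.58, 0.12)

# rotate a y-up mask matrix by 90 degrees anticlockwise
rot90_mask <- function(M) t(M)[ncol(M):1, , drop = FALSE]
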