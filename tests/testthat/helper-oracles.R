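# Independent oracles, deliberately written along different code paths from
# the package implementation.

# Brute-force local-polynomial smoother: neighbourhood by full sort of
# distances (ties included), tricube weights, and an explicit normal-
# equations solve of the weighted polynomial fit (the production path uses a
# QR factorisation instead). The basis is centred at x for conditioning, so
# the fitted value at x is the intercept.
oracle_loess <- function(times, values, span = 0.06, degree = 2,
                         grid_points = 1001, min_neighbors = degree + 2) {
  n <- length(times)
  q <- max(min_neighbors, ceiling(span * n))
  grid <- seq(min(times), max(times), length.out = grid_points)
  vapply(grid, function(x) {
    d <- abs(times - x)
    d_q <- sort(d)[q]
    sel <- d <= d_q
    ds <- d[sel]; ts <- times[sel]; ys <- values[sel]
    d_max <- max(ds)
    if (d_max == 0) return(mean(ys))
    w <- (1 - (ds / d_max)^3)^3
    if (sum(w) == 0) return(mean(ys))
    X <- vapply(0:degree, function(p) (ts - x)^p, numeric(length(ts)))
    A <- t(X) %*% (w * X)
    b <- t(X) %*% (w * ys)
    beta <- solve(A, b)
    beta[1]
  }, numeric(1))
}

# Scalar even-odd point-in-polygon via explicit edge x-intersections.
oracle_point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  crossings <- 0L
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] <= y && vy[j] > y) || (vy[j] <= y && vy[i] > y)) {
      xint <- vx[i] + (y - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (x < xint) crossings <- crossings + 1L
    }
    j <- i
  }
  crossings %% 2L == 1L
}

# High-resolution trapezoid quadrature of an arbitrary function.
oracle_quadrature <- function(f, lower, upper, n = 1e6) {
  x <- seq(lower, upper, length.out = n)
  y <- f(x)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

# Analytic gamma-variate, written independently of the package.
oracle_gamma <- function(t, A, t0, tp, alpha) {
  out <- numeric(length(t))
  pos <- t > t0
  u <- (t[pos] - t0) / tp
  out[pos] <- A * exp(alpha * log(u) + alpha * (1 - u))
  out
}

# Permutation-null two-sided p-value for a Pearson correlation.
oracle_permutation_p <- function(x, y, n_perm = 40000, seed = 1) {
  withr::with_seed(seed, {
    r_obs <- abs(cor(x, y))
    r_null <- replicate(n_perm, abs(cor(x, sample(y))))
    (1 + sum(r_null >= r_obs)) / (n_perm + 1)
  })
}

# Minimal smoothed-curve object for metric tests with known fitted values.
make_curve <- function(grid, fitted) {
  structure(list(grid_times = grid, fitted = fitted, n_source = length(grid),
                 raw_times = grid, raw_values = fitted,
                 params = smooth_params(span = 1, degree = 0),
                 diagnostics = list(q = length(grid), degree_fallback_at = integer(0))),
            class = "smoothed_tic")
}
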