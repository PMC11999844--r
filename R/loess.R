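# Local polynomial regression with tricube weights, evaluated exactly at
# every point of a uniform grid. This is the smoother the TIC metrics are
# read from, so it is computed directly (no interpolation surface): at each
# grid point the q nearest raw points get tricube weights and a weighted
# least-squares polynomial is solved. Deterministic and oracle-checkable.

#' Smoothing parameters
#'
#' @param span Fraction of points in each local neighbourhood, in (0, 1].
#'   Default 0.06 — with ~30 s clips at video frame rate this keeps the
#'   neighbourhood to roughly a second of data, tight enough to track the
#'   bolus upslope without chasing frame noise.
#' @param degree Local polynomial degree, 0, 1 or 2 (default 2).
#' @param grid_points Number of evaluation points (uniform over the data
#'   range), default 1001; at least 51.
#' @param min_neighbors Lower bound on the neighbourhood size, default
#'   `degree + 2`, guarding against singular local fits on short clips.
#' @return A list of class `smooth_params`.
#' @export
smooth_params <- function(span = 0.06, degree = 2, grid_points = 1001,
                          min_neighbors = degree + 2) {
  stopifnot_scalar_number(span, "span", positive = TRUE)
  if (span > 1) abort_validation("`span` must be in (0, 1].")
  if (!degree %in% 0:2) abort_validation("`degree` must be 0, 1 or 2.")
  stopifnot_scalar_number(grid_points, "grid_points")
  if (grid_points < 51) abort_validation("`grid_points` must be at least 51.")
  stopifnot_scalar_number(min_neighbors, "min_neighbors")
  structure(list(span = span, degree = as.integer(degree),
                 grid_points = as.integer(grid_points),
                 min_neighbors = as.integer(min_neighbors)),
            class = "smooth_params")
}

#' Fit a tricube-weighted local polynomial to a time-intensity trace
#'
#' For each of `grid_points` uniformly spaced times x spanning the data
#' range, the `q = max(min_neighbors, ceiling(span * n))` raw points nearest
#' to x (ties in distance all included) receive tricube weights
#' `w_i = (1 - (d_i / d_max)^3)^3`, with `d_max` the largest selected
#' distance, and the fitted value is the weighted least-squares polynomial of
#' the requested degree evaluated at x. If all selected points coincide with
#' x (`d_max = 0`) the fitted value is their plain mean. A locally singular
#' design triggers a one-step degree reduction at that grid point, recorded
#' in the returned diagnostics. No robustness iterations are performed
#' (gaussian-family behaviour).
#'
#' @param times Strictly increasing times in seconds.
#' @param values Intensities in decibels, same length as `times`.
#' @param span,degree,grid_points,min_neighbors See [smooth_params()];
#'   ignored when `params` is given.
#' @param params Optional [smooth_params()] object.
#' @return An object of class `smoothed_tic`: list with `grid_times`,
#'   `fitted`, `n_source`, `raw_times`, `raw_values`, `params`, and
#'   `diagnostics` (`q`, integer vector `degree_fallback_at` of grid indices
#'   where the degree was reduced).
#' @export
#' @examples
#' t <- seq(0, 30, by = 1 / 15)
#' y <- gamma_variate(t, amplitude = 10, arrival = 2, rise = 5, shape = 2)
#' fit <- fit_loess(t, y, span = 0.06)
#' compute_metrics(fit)
fit_loess <- function(times, values, span = 0.06, degree = 2,
                      grid_points = 1001, min_neighbors = degree + 2,
                      params = NULL) {
  p <- params %||% smooth_params(span, degree, grid_points, min_neighbors)
  n <- length(times)
  if (length(values) != n) abort_validation("`times` and `values` lengths differ.")
  if (n < 2L || any(diff(times) <= 0)) {
    abort_validation("`times` must be strictly increasing with at least 2 points.")
  }
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    abort_validation("`times` and `values` must be finite.")
  }
  q <- max(p$min_neighbors, ceiling(p$span * n))
  if (n < q) {
    abort_validation(sprintf(
      "too few points (%d) for the local neighbourhood size q = %d.", n, q))
  }
  grid <- seq(min(times), max(times), length.out = p$grid_points)
  fitted <- numeric(p$grid_points)
  fallback_at <- integer(0)

  for (g in seq_along(grid)) {
    x <- grid[g]
    d <- abs(times - x)
    d_q <- sort.int(d, partial = q)[q]
    sel <- which(d <= d_q)          # includes all distance ties
    ds <- d[sel]
    d_max <- max(ds)
    ys <- values[sel]
    if (d_max == 0) {
      fitted[g] <- mean(ys)
      next
    }
    w <- (1 - (ds / d_max)^3)^3
    if (sum(w) == 0) {              # all selected points sit exactly at d_max
      fitted[g] <- mean(ys)
      next
    }
    tc <- times[sel] - x            # centred predictor: intercept = fit at x
    deg <- p$degree
    repeat {
      X <- outer(tc, 0:deg, `^`)
      fit <- tryCatch(suppressWarnings(lm.wfit(X, ys, w)), error = function(e) NULL)
      ok <- !is.null(fit) && fit$rank == deg + 1L && is.finite(fit$coefficients[1])
      if (ok || deg == 0L) break
      deg <- deg - 1L
      fallback_at <- c(fallback_at, g)
    }
    fitted[g] <- if (ok) fit$coefficients[1] else sum(w * ys) / sum(w)
  }

  structure(list(grid_times = grid, fitted = fitted, n_source = n,
                 raw_times = times, raw_values = values, params = p,
                 diagnostics = list(q = q, degree_fallback_at = unique(fallback_at))),
            class = "smoothed_tic")
}

#' Evaluate a smoothed curve at arbitrary times
#'
#' Linear interpolation between adjacent grid points of a [fit_loess()] fit.
#'
#' @param curve A `smoothed_tic` object.
#' @param t Times in seconds, all within the fitted grid range.
#' @return Interpolated intensities in decibels.
#' @export
evaluate <- function(curve, t) {
  stopifnot(inherits(curve, "smoothed_tic"))
  rng <- range(curve$grid_times)
  if (any(t < rng[1] | t > rng[2])) {
    abort_validation(sprintf("evaluation time outside fitted range [%.6g, %.6g].",
                             rng[1], rng[2]))
  }
  approx(curve$grid_times, curve$fitted, xout = t, method = "linear")$y
}

#' @export
print.smoothed_tic <- function(x, ...) {
  cat(sprintf(
    "<smoothed_tic> %d raw frames over [%.3g, %.3g] s; span %.3g, degree %d, %d grid points\n",
    x$n_source, min(x$raw_times), max(x$raw_times),
    x$params$span, x$params$degree, x$params$grid_points))
  if (length(x$diagnostics$degree_fallback_at)) {
    cat(sprintf("  degree fallback at %d grid point(s)\n",
                length(x$diagnostics$degree_fallback_at)))
  }
  invisible(x)
}

#' Tidy a smoothed curve into its evaluation grid
#'
#' @param x A `smoothed_tic` object.
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `fitted_db`.
#' @export
tidy.smoothed_tic <- function(x, ...) {
  tibble::tibble(time_s = x$grid_times, fitted_db = x$fitted)
}

#' One-row summary of a smoothed curve fit
#'
#' @param x A `smoothed_tic` object.
#' @param ... Unused.
#' @return Tibble with `n_source`, `span`, `degree`, `grid_points`,
#'   `neighborhood`, `n_degree_fallback`.
#' @export
glance.smoothed_tic <- function(x, ...) {
  tibble::tibble(n_source = x$n_source, span = x$params$span,
                 degree = x$params$degree, grid_points = x$params$grid_points,
                 neighborhood = x$diagnostics$q,
                 n_degree_fallback = length(x$diagnostics$degree_fallback_at))
}
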