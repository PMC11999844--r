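# Extraction of the TIC metrics from a smoothed curve: peak intensity (PI),
# time-to-peak (TTP), area under the curve, and the time until a stated
# fraction of peak (the "time-to-peak proportion", 90% by default). All
# metrics are read from the smoothed curve, not the raw frames.

#' Compute curve metrics from a smoothed time-intensity curve
#'
#' Peak intensity is the maximum fitted value over the evaluation grid
#' (clamped below at zero — contrast intensity is physically non-negative,
#' so small negative smoother overshoot near time zero is ignored).
#' Time-to-peak is the earliest grid time attaining that maximum;
#' `time_to_fraction_s` is the earliest grid time at which the curve reaches
#' `fraction * PI` (on the rising limb, hence always <= TTP); the AUC is the
#' trapezoidal integral of the clamped curve over the grid.
#'
#' @param curve A [fit_loess()] object.
#' @param fraction Fraction of peak for the time-to-fraction metric, in
#'   (0, 1); default 0.9, i.e. time until 90% of peak intensity.
#' @return One-row tibble: `peak_intensity_db`, `time_to_peak_s`,
#'   `auc_db_s`, `time_to_fraction_s`, `fraction`.
#' @export
compute_metrics <- function(curve, fraction = 0.9) {
  stopifnot(inherits(curve, "smoothed_tic"))
  stopifnot_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    abort_validation("`fraction` must be strictly between 0 and 1.")
  }
  y <- pmax(curve$fitted, 0)
  tg <- curve$grid_times
  pi_db <- max(y)
  if (pi_db <= 0) {
    abort_degenerate("flat zero curve: no peak exists, time-to-peak is undefined.")
  }
  ttp <- tg[which.max(y)]                       # which.max -> earliest maximiser
  ttf <- tg[which(y >= fraction * pi_db)[1]]
  auc <- trapezoid(tg, y)
  tibble::tibble(peak_intensity_db = pi_db, time_to_peak_s = ttp,
                 auc_db_s = auc, time_to_fraction_s = ttf, fraction = fraction)
}

# Trapezoidal rule; clamping to zero happens in the caller because it is
# part of the metric definition, not of the quadrature.
trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Smooth and extract metrics for every trace of a recording
#'
#' The per-recording pipeline: each (kidney, ROI) trace is smoothed with
#' [fit_loess()] and summarised with [compute_metrics()]. The fitted curves
#' are attached as an attribute so report plots can be drawn without
#' refitting.
#'
#' @param tic A `ceus_tic` tibble (see [as_tic()], [read_tic_table()]).
#' @param span,degree,grid_points Smoothing parameters, see [smooth_params()].
#' @param fraction Fraction of peak for the time-to-fraction metric.
#' @return Tibble of class `ceus_metrics`, one row per (kidney, ROI), with
#'   the [compute_metrics()] columns; attribute `fits` is a named list
#'   (`"<kidney>|<roi>"`) of `smoothed_tic` objects.
#' @export
#' @examples
#' sim <- simulate_cohort(n_kidneys = 3, seed = 7)
#' m <- analyze_tic(sim$tic)
#' m
analyze_tic <- function(tic, span = 0.06, degree = 2, grid_points = 1001,
                        fraction = 0.9) {
  p <- smooth_params(span = span, degree = degree, grid_points = grid_points)
  pieces <- tic |>
    dplyr::group_by(.data$kidney_id, .data$roi) |>
    dplyr::group_map(function(d, key) {
      fit <- fit_loess(d$time_s, d$intensity_db, params = p)
      list(key = key, fit = fit,
           row = dplyr::bind_cols(key, compute_metrics(fit, fraction = fraction)))
    })
  out <- dplyr::bind_rows(lapply(pieces, `[[`, "row"))
  fits <- lapply(pieces, `[[`, "fit")
  names(fits) <- vapply(pieces, function(x) paste(x$key$kidney_id, x$key$roi, sep = "|"),
                        character(1))
  attr(out, "fits") <- fits
  class(out) <- c("ceus_metrics", class(out))
  out
}
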