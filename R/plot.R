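# Report plots: raw frames as points, the smoothed curve as a line, and
# dashed/dotted guide lines at peak intensity / time-to-peak and at the
# fraction-of-peak point.

#' Plot a smoothed time-intensity curve with its metrics
#'
#' Raw frame intensities are drawn as points, the local-polynomial fit as a
#' red line; dashed blue guides mark peak intensity and time-to-peak, dotted
#' green guides the fraction-of-peak intensity and the time it is first
#' reached.
#'
#' @param object A [fit_loess()] object.
#' @param metrics Optional one-row metrics tibble from [compute_metrics()];
#'   computed on the fly when omitted.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smoothed_tic <- function(object, metrics = NULL, ...) {
  m <- metrics %||% compute_metrics(object)
  raw <- tibble::tibble(time_s = object$raw_times, intensity_db = object$raw_values)
  ggplot2::ggplot(raw, ggplot2::aes(.data$time_s, .data$intensity_db)) +
    ggplot2::geom_point(colour = "black", size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = tidy(object),
                       ggplot2::aes(.data$time_s, .data$fitted_db),
                       colour = "red", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = m$peak_intensity_db,
                        colour = "blue", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = m$time_to_peak_s,
                        colour = "blue", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = m$fraction * m$peak_intensity_db,
                        colour = "darkgreen", linetype = "dotted") +
    ggplot2::geom_vline(xintercept = m$time_to_fraction_s,
                        colour = "darkgreen", linetype = "dotted") +
    ggplot2::labs(x = "Time (s)", y = "Mean contrast intensity (dB)") +
    ggplot2::theme_minimal()
}

#' Plot every fitted trace of an analysed recording
#'
#' One panel per (kidney, ROI) with the same annotation as
#' [autoplot.smoothed_tic()].
#'
#' @param metrics A [analyze_tic()] result (its `fits` attribute supplies
#'   the curves).
#' @return A ggplot object faceted by kidney and ROI.
#' @export
plot_tic_report <- function(metrics) {
  fits <- attr(metrics, "fits")
  if (is.null(fits)) abort_validation("`metrics` carries no fitted curves; use analyze_tic().")
  raw <- purrr::imap(fits, function(f, key) {
    tibble::tibble(key = key, time_s = f$raw_times, intensity_db = f$raw_values)
  }) |> dplyr::bind_rows()
  fitted <- purrr::imap(fits, function(f, key) {
    dplyr::mutate(tidy(f), key = key)
  }) |> dplyr::bind_rows()
  marks <- metrics |>
    dplyr::mutate(key = paste(.data$kidney_id, .data$roi, sep = "|"))
  ggplot2::ggplot(raw, ggplot2::aes(.data$time_s, .data$intensity_db)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::geom_line(data = fitted, ggplot2::aes(.data$time_s, .data$fitted_db),
                       colour = "red") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$time_to_peak_s),
                        colour = "blue", linetype = "dashed") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$time_to_fraction_s),
                        colour = "darkgreen", linetype = "dotted") +
    ggplot2::facet_wrap(~key, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Mean contrast intensity (dB)") +
    ggplot2::theme_minimal()
}

#' Scatter plots of score-outcome correlations
#'
#' @param scores_wide Per-kidney wide table (see [widen_scores()]).
#' @param outcomes Long outcome table (`kidney_id, outcome_name, value`).
#' @param score_col Which column of `scores_wide` to plot (default
#'   `"overall_score"`).
#' @return A ggplot object, one panel per outcome, annotated with r and p.
#' @export
plot_score_outcome <- function(scores_wide, outcomes, score_col = "overall_score") {
  joined <- dplyr::inner_join(scores_wide, outcomes, by = "kidney_id")
  labels <- joined |>
    dplyr::group_by(.data$outcome_name) |>
    dplyr::summarise(lab = {
      res <- pearson(.data[[score_col]], .data$value)
      sprintf("r = %.3f, p = %.3f", res$r, res$p)
    }, .groups = "drop")
  ggplot2::ggplot(joined, ggplot2::aes(.data[[score_col]], .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::facet_wrap(~outcome_name, scales = "free_y") +
    ggplot2::geom_text(data = labels, ggplot2::aes(label = .data$lab),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = score_col, y = "Outcome value") +
    ggplot2::theme_minimal()
}
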