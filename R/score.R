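# The composite CEUS score. Peak intensity and time-to-peak live on
# different scales, so each is z-scored against a cohort reference; a
# region's score is z(PI) - z(TTP) (high peaks and early peaks are both
# good), and the overall score for a kidney is the sum over cortex, outer
# medulla and inner medulla.

#' Build a cohort reference table of PI / TTP means and SDs
#'
#' Per region, the mean and sample standard deviation (n - 1 denominator) of
#' peak intensity and time-to-peak across the cohort. Every kidney must
#' contribute all three canonical regions.
#'
#' @param metrics A metrics tibble ([analyze_tic()] / [read_metrics_table()])
#'   whose `roi` values include the three canonical regions.
#' @return Tibble of class `ceus_reference`:
#'   `region, mean_pi, sd_pi, mean_ttp, sd_ttp, n`.
#' @export
build_cohort_reference <- function(metrics) {
  m <- check_region_completeness(metrics)
  n_kid <- dplyr::n_distinct(m$kidney_id)
  if (n_kid < 2L) {
    abort_validation("a cohort reference needs at least 2 kidneys.")
  }
  ref <- m |>
    dplyr::group_by(region = .data$roi) |>
    dplyr::summarise(mean_pi = mean(.data$peak_intensity_db),
                     sd_pi = sd(.data$peak_intensity_db),
                     mean_ttp = mean(.data$time_to_peak_s),
                     sd_ttp = sd(.data$time_to_peak_s),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$region, CANONICAL_REGIONS))
  bad <- ref$sd_pi <= 0 | ref$sd_ttp <= 0
  if (any(bad)) {
    abort_degenerate(sprintf(
      "zero variance in region %s: z-scores are undefined for an all-identical cohort.",
      ref$region[which(bad)[1]]))
  }
  class(ref) <- c("ceus_reference", class(ref))
  ref
}

check_region_completeness <- function(metrics) {
  m <- dplyr::filter(metrics, .data$roi %in% CANONICAL_REGIONS)
  have <- m |>
    dplyr::distinct(.data$kidney_id, .data$roi) |>
    dplyr::count(.data$kidney_id)
  incomplete <- have$kidney_id[have$n < 3L]
  dup <- m |>
    dplyr::count(.data$kidney_id, .data$roi) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort_validation(sprintf("duplicated region %s for kidney %s.",
                             dup$roi[1], dup$kidney_id[1]))
  }
  if (length(incomplete)) {
    abort_validation(sprintf(
      "kidney(s) missing one of the three regions (%s): %s",
      paste(CANONICAL_REGIONS, collapse = ", "),
      paste(incomplete, collapse = ", ")))
  }
  m
}

#' Score one region's metrics against a cohort reference
#'
#' `score = z(PI) - z(TTP)` with `z(PI) = (PI - mean_PI) / sd_PI` and
#' `z(TTP) = (TTP - mean_TTP) / sd_TTP`: higher and earlier peaks (better
#' microvascular perfusion) both raise the score.
#'
#' @param peak_intensity_db,time_to_peak_s The region's metrics.
#' @param reference A [build_cohort_reference()] tibble (or one read with
#'   [read_reference_table()]).
#' @param region Region label, one of [ceus_regions()] (or any label present
#'   in the reference).
#' @return One-row tibble: `region, z_pi, z_ttp, region_score`.
#' @export
region_score <- function(peak_intensity_db, time_to_peak_s, reference, region) {
  r <- reference[reference$region == region, ]
  if (nrow(r) != 1L) {
    abort_validation(sprintf("region `%s` not found in the reference table.", region))
  }
  z_pi <- (peak_intensity_db - r$mean_pi) / r$sd_pi
  z_ttp <- (time_to_peak_s - r$mean_ttp) / r$sd_ttp
  tibble::tibble(region = region, z_pi = z_pi, z_ttp = z_ttp,
                 region_score = z_pi - z_ttp)
}

#' Region and overall CEUS scores for a cohort of kidneys
#'
#' Scores every kidney's three regions against `reference` and appends an
#' `overall` row per kidney holding the sum of its three region scores.
#' With `reference = NULL` (the self-referenced mode used in the study) the
#' reference is built from the scored cohort itself, in which case each
#' region's z-scores have mean 0 and sd 1 and all scores sum to zero across
#' the cohort. Supplying a saved reference instead scores new kidneys
#' against a historical cohort.
#'
#' @param metrics Metrics tibble covering all three regions per kidney.
#' @param reference A `ceus_reference` tibble, or `NULL` for self-reference.
#' @return Tibble of class `ceus_scores`:
#'   `kidney_id, region, z_pi, z_ttp, region_score`, with one
#'   `region = "overall"` row per kidney (`z_pi`/`z_ttp` are `NA` there).
#'   Attribute `reference` holds the reference used.
#' @export
#' @examples
#' sim <- simulate_cohort(n_kidneys = 4, seed = 11)
#' scores <- analyze_tic(sim$tic) |> ceus_scores()
#' scores
ceus_scores <- function(metrics, reference = NULL) {
  m <- check_region_completeness(metrics)
  ref <- reference %||% build_cohort_reference(m)
  per_region <- m |>
    dplyr::group_by(.data$kidney_id) |>
    dplyr::group_map(function(d, key) {
      rows <- purrr::pmap(list(d$peak_intensity_db, d$time_to_peak_s, d$roi),
                          function(pi, ttp, roi) region_score(pi, ttp, ref, roi))
      dplyr::bind_cols(key, dplyr::bind_rows(rows))
    }) |>
    dplyr::bind_rows()
  overall <- per_region |>
    dplyr::group_by(.data$kidney_id) |>
    dplyr::summarise(region = "overall", z_pi = NA_real_, z_ttp = NA_real_,
                     region_score = sum(.data$region_score), .groups = "drop")
  out <- dplyr::bind_rows(per_region, overall) |>
    dplyr::arrange(.data$kidney_id,
                   match(.data$region, c(CANONICAL_REGIONS, "overall")))
  attr(out, "reference") <- ref
  class(out) <- c("ceus_scores", class(out))
  out
}

#' Pivot scores to one row per kidney
#'
#' Convenience reshape for correlation against per-kidney outcomes: columns
#' `<region>_score` and `overall_score`.
#'
#' @param scores A [ceus_scores()] tibble.
#' @return Wide tibble keyed by `kidney_id`.
#' @export
widen_scores <- function(scores) {
  scores |>
    dplyr::mutate(name = paste0(.data$region, "_score")) |>
    dplyr::select("kidney_id", "name", "region_score") |>
    tidyr::pivot_wider(names_from = "name", values_from = "region_score")
}

#' Pivot metrics to one row per kidney
#'
#' Columns are `<roi>_<metric>` for each of the four curve metrics.
#'
#' @param metrics A metrics tibble.
#' @return Wide tibble keyed by `kidney_id`.
#' @export
widen_metrics <- function(metrics) {
  metrics |>
    dplyr::select("kidney_id", "roi", "peak_intensity_db", "time_to_peak_s",
                  "auc_db_s", "time_to_fraction_s") |>
    tidyr::pivot_longer(-c("kidney_id", "roi")) |>
    dplyr::mutate(name = paste(.data$roi, .data$name, sep = "_")) |>
    dplyr::select(-"roi") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
}

#' Write / read a cohort reference table
#'
#' Comma-delimited with header `region,mean_pi,sd_pi,mean_ttp,sd_ttp,n` —
#' the machine-readable form of a cohort's normalisation constants, so that
#' new kidneys can be scored against a historical cohort.
#'
#' @param reference A `ceus_reference` tibble.
#' @param path File path.
#' @return `write_reference_table()` returns `path` invisibly;
#'   `read_reference_table()` the reference tibble.
#' @export
write_reference_table <- function(reference, path) {
  readr::write_csv(reference, path)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(region = readr::col_character(),
                                                 .default = readr::col_double()))
  needed <- c("region", "mean_pi", "sd_pi", "mean_ttp", "sd_ttp", "n")
  if (!all(needed %in% names(ref))) {
    abort_validation(sprintf("reference table must have columns %s",
                             paste(needed, collapse = ",")))
  }
  if (any(ref$sd_pi <= 0 | ref$sd_ttp <= 0)) {
    abort_degenerate("reference table contains non-positive standard deviations.")
  }
  class(ref) <- c("ceus_reference", class(ref))
  ref
}

#' Write a score table
#'
#' Comma-delimited `kidney_id,region,z_pi,z_ttp,region_score` including the
#' per-kidney `overall` rows.
#'
#' @param scores A [ceus_scores()] tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}
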