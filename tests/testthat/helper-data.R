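# Small fixture builders; everything is generated in code at test time.

write_long_tic <- function(df, path = tempfile(fileext = ".csv"),
                           cols = c("time", "roi", "intensity")) {
  names(df)[seq_along(cols)] <- cols
  readr::write_csv(df, path)
  path
}

write_wide_tic <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# A well-behaved 8-frame cortex trace.
tiny_trace <- function(roi = "cortex") {
  tibble::tibble(time = seq(0, 0.7, by = 0.1), roi = roi,
                 intensity = c(0, 2, 5, 7, 8, 8, 7, 6))
}

# Synthetic per-kidney metrics for score tests: random but valid.
random_metrics <- function(n_kidneys, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(kidney_id = sprintf("K%02d", seq_len(n_kidneys)),
                       roi = ceus_regions()) |>
      dplyr::mutate(peak_intensity_db = runif(dplyr::n(), 4, 12),
                    time_to_peak_s = runif(dplyr::n(), 5, 15),
                    auc_db_s = runif(dplyr::n(), 40, 120),
                    time_to_fraction_s = time_to_peak_s - runif(dplyr::n(), 0.5, 2),
                    fraction = 0.9)
  })
}
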