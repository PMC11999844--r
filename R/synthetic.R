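# Synthetic bolus data with ground truth. The first-pass kinetics of an
# intravascular contrast bolus are modelled by the gamma-variate curve in
# its peak-normalised form: zero before arrival, rising to amplitude A
# exactly at arrival + rise, then washing out. Cohorts couple a latent
# injury value to lower amplitude and slower rise, plus an outcome variable
# (an injury biomarker such as urinary NGAL) driven by the same injury, so
# the full analysis pipeline can be exercised against known truth.

#' Gamma-variate bolus curve
#'
#' `0` for `t <= arrival`, else
#' `A * ((t - arrival) / rise)^shape * exp(shape * (1 - (t - arrival) / rise))`.
#' The maximum equals `amplitude` exactly at `t = arrival + rise`.
#'
#' @param t Times in seconds (vectorised).
#' @param amplitude Peak intensity A in decibels, > 0.
#' @param arrival Bolus arrival time t0 in seconds.
#' @param rise Arrival-to-peak interval in seconds, > 0.
#' @param shape Unitless shape parameter alpha, > 0; larger values give a
#'   narrower bolus.
#' @return Intensities in decibels, same length as `t`.
#' @export
#' @examples
#' gamma_variate(c(2, 7, 12), amplitude = 10, arrival = 2, rise = 5, shape = 2)
gamma_variate <- function(t, amplitude, arrival, rise, shape) {
  stopifnot_scalar_number(amplitude, "amplitude", positive = TRUE)
  stopifnot_scalar_number(rise, "rise", positive = TRUE)
  stopifnot_scalar_number(shape, "shape", positive = TRUE)
  u <- (t - arrival) / rise
  ifelse(u <= 0, 0, amplitude * u^shape * exp(shape * (1 - u)))
}

#' Bolus simulation parameters
#'
#' @inheritParams gamma_variate
#' @param noise_sd Standard deviation of additive zero-mean gaussian frame
#'   noise, in decibels (>= 0).
#' @param frame_rate Sampling rate in Hz (video frame rate).
#' @param duration Clip length in seconds; must exceed `arrival + rise` so
#'   the peak lies inside the clip.
#' @param seed Integer seed; all randomness is drawn from it and the global
#'   RNG state is left untouched.
#' @return A list of class `bolus_params`.
#' @export
bolus_params <- function(amplitude = 10, arrival = 2, rise = 5, shape = 2,
                         noise_sd = 0.5, frame_rate = 15, duration = 30,
                         seed = 1L) {
  stopifnot_scalar_number(amplitude, "amplitude", positive = TRUE)
  stopifnot_scalar_number(rise, "rise", positive = TRUE)
  stopifnot_scalar_number(shape, "shape", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort_validation("`noise_sd` must be >= 0.")
  stopifnot_scalar_number(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  if (duration <= arrival + rise) {
    abort_validation("`duration` must exceed `arrival + rise` (peak inside the clip).")
  }
  structure(list(amplitude = amplitude, arrival = arrival, rise = rise,
                 shape = shape, noise_sd = noise_sd, frame_rate = frame_rate,
                 duration = duration, seed = as.integer(seed)),
            class = "bolus_params")
}

#' Simulate one time-intensity trace
#'
#' Samples the gamma-variate at `1/frame_rate` intervals on `[0, duration]`,
#' adds zero-mean gaussian noise from the seeded generator, and clamps below
#' at zero (contrast mode has a non-negative noise floor).
#'
#' @param params A [bolus_params()] object.
#' @param roi_label ROI label for the trace.
#' @param kidney_id Kidney identifier.
#' @return A `ceus_tic` tibble with one trace.
#' @export
simulate_trace <- function(params, roi_label = "cortex", kidney_id = "kidney") {
  stopifnot(inherits(params, "bolus_params"))
  t <- seq(0, params$duration, by = 1 / params$frame_rate)
  y <- gamma_variate(t, params$amplitude, params$arrival, params$rise, params$shape)
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(params$seed, rnorm(length(t), 0, params$noise_sd))
    y <- y + noise
  }
  as_tic(tibble::tibble(kidney_id = kidney_id, roi = roi_label,
                        time_s = t, intensity_db = pmax(y, 0)))
}

# Default per-region bolus distributions: the cortex enhances first and
# brightest; outer then inner medulla peak later and dimmer. Means reflect a
# healthy baseline; sds are the residual kidney-to-kidney spread left after
# the injury coupling (same species, standardised perfusion and imaging).
default_region_params <- function() {
  tibble::tibble(
    roi = CANONICAL_REGIONS,
    mean_A = c(10, 7, 5), sd_A = c(0.8, 0.8, 0.8),
    mean_t0 = c(3, 4, 5), sd_t0 = c(0.3, 0.3, 0.3),
    mean_tp = c(4, 6, 8), sd_tp = c(0.5, 0.5, 0.5),
    mean_alpha = c(2, 2, 2), sd_alpha = c(0, 0, 0)
  )
}

#' Simulate a cohort of kidneys with ground truth and an outcome
#'
#' Each kidney draws a latent injury value `injury ~ U(0, 1)`. Per region,
#' amplitude is multiplied by `1 - amplitude_loss * injury` and the rise
#' time by `1 + rise_slowdown * injury` — injured kidneys enhance less and
#' more slowly, the microvascular-perfusion signature the score is designed
#' to capture. The outcome (an injury biomarker on an NGAL-like scale) is
#' `outcome_scale * injury` plus gaussian noise, so that worse perfusion
#' accompanies a higher biomarker level.
#'
#' @param n_kidneys Number of kidneys (>= 3).
#' @param region_params Per-region tibble of bolus parameter means/sds
#'   (columns `roi, mean_A, sd_A, mean_t0, sd_t0, mean_tp, sd_tp,
#'   mean_alpha, sd_alpha`); see `ceustic:::default_region_params()`.
#' @param injury_gradient Overall coupling strength in `[0, 1]` scaling both
#'   effects; `0` decouples curves from outcome entirely.
#' @param amplitude_loss,rise_slowdown Maximal fractional amplitude loss and
#'   rise-time slowdown at `injury = 1` (defaults 0.4 and 0.6).
#' @param outcome_scale Outcome units per unit injury (default 100).
#' @param outcome_noise_sd Outcome noise sd (default 10).
#' @param noise_sd,frame_rate,duration Trace sampling settings (defaults
#'   0.5 dB, 15 Hz, 30 s).
#' @param seed Integer seed; everything is reproducible from it.
#' @return List with `tic` (a `ceus_tic` tibble for all kidneys and
#'   regions), `truth` (per kidney/region: injury and the realised
#'   `amplitude`, `arrival`, `rise`, `shape`), and `outcomes`
#'   (`kidney_id, outcome_name, value`).
#' @export
#' @examples
#' sim <- simulate_cohort(n_kidneys = 3, seed = 42)
#' head(sim$truth)
simulate_cohort <- function(n_kidneys = 10, region_params = default_region_params(),
                            injury_gradient = 1, amplitude_loss = 0.4,
                            rise_slowdown = 0.6, outcome_scale = 100,
                            outcome_noise_sd = 10, noise_sd = 0.5,
                            frame_rate = 15, duration = 30, seed = 1L) {
  if (n_kidneys < 3L) abort_validation("`n_kidneys` must be at least 3.")
  if (any(c(region_params$sd_A, region_params$sd_t0, region_params$sd_tp,
            region_params$sd_alpha) < 0)) {
    abort_validation("all region-parameter sds must be >= 0.")
  }
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("K%02d", seq_len(n_kidneys))
    injury <- runif(n_kidneys)
    truth <- tidyr::expand_grid(kidney_id = ids, region_params) |>
      dplyr::mutate(injury = injury[match(.data$kidney_id, ids)]) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        amplitude = max(0.5, rnorm(1, .data$mean_A, .data$sd_A)) *
          (1 - amplitude_loss * injury_gradient * .data$injury),
        arrival = max(0.2, rnorm(1, .data$mean_t0, .data$sd_t0)),
        rise = max(0.5, rnorm(1, .data$mean_tp, .data$sd_tp)) *
          (1 + rise_slowdown * injury_gradient * .data$injury),
        shape = max(1, rnorm(1, .data$mean_alpha, .data$sd_alpha))
      ) |>
      dplyr::ungroup() |>
      dplyr::select("kidney_id", "roi", "injury", "amplitude", "arrival",
                    "rise", "shape")
    t <- seq(0, duration, by = 1 / frame_rate)
    tic <- truth |>
      dplyr::rowwise() |>
      dplyr::reframe(kidney_id = .data$kidney_id, roi = .data$roi, time_s = t,
                     intensity_db = pmax(
                       gamma_variate(t, .data$amplitude, .data$arrival,
                                     .data$rise, .data$shape) +
                         rnorm(length(t), 0, noise_sd), 0))
    outcomes <- tibble::tibble(
      kidney_id = ids, outcome_name = "injury_marker",
      value = outcome_scale * injury + rnorm(n_kidneys, 0, outcome_noise_sd))
    list(tic = as_tic(tic), truth = truth, outcomes = outcomes)
  })
}
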