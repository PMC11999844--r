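# Reading, validating, aligning and truncating time-intensity recordings,
# plus the delimited-text writers/readers for metric tables.

#' Construct a validated time-intensity tibble
#'
#' A CEUS time-intensity recording is held as a long tibble with one row per
#' (kidney, region-of-interest, frame): columns `kidney_id`, `roi`, `time_s`
#' (seconds) and `intensity_db` (mean contrast intensity in decibels).
#' Validation enforces, per (kidney, roi) trace: strictly increasing times,
#' at least 8 frames, finite non-negative intensities, and — within each
#' kidney — an identical time vector across ROIs (frames are shared because
#' every ROI is read off the same cine loop).
#'
#' @param df Data frame with columns `kidney_id`, `roi`, `time_s`,
#'   `intensity_db` (missing `kidney_id` is filled with `"kidney"`).
#' @param lenient If `TRUE`, small negative intensities are clamped to zero
#'   instead of raising an error (some vendors export slightly negative
#'   background values; contrast mode should give a non-negative floor).
#' @return A tibble of class `ceus_tic`, rows ordered by kidney, roi, time.
#' @export
as_tic <- function(df, lenient = FALSE) {
  df <- tibble::as_tibble(df)
  if (!"kidney_id" %in% names(df)) df$kidney_id <- "kidney"
  needed <- c("kidney_id", "roi", "time_s", "intensity_db")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort_validation(sprintf("missing required column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  df <- dplyr::select(df, dplyr::all_of(needed))
  if (!is.numeric(df$time_s) || !is.numeric(df$intensity_db)) {
    abort_validation("`time_s` and `intensity_db` must be numeric.")
  }
  if (anyNA(df)) abort_validation("missing values are not allowed in a TIC table.")
  if (any(df$time_s < 0)) abort_validation("times must be non-negative seconds.")

  neg <- which(df$intensity_db < 0)
  if (length(neg)) {
    if (lenient) {
      df$intensity_db[neg] <- 0
    } else {
      abort_validation(sprintf(
        "negative intensity at row %d (%.4g dB); use `lenient = TRUE` to clamp to zero.",
        neg[1], df$intensity_db[neg[1]]))
    }
  }

  df$.row <- seq_len(nrow(df))
  validate_trace <- function(d, key) {
    dt <- diff(d$time_s)
    bad <- which(dt <= 0)
    if (length(bad)) {
      verb <- if (d$time_s[bad[1] + 1L] == d$time_s[bad[1]]) "duplicated" else "non-monotone"
      abort_validation(sprintf(
        "%s timestamp in trace %s/%s at input row %d (t = %.6g s).",
        verb, key$kidney_id, key$roi, d$.row[bad[1] + 1L], d$time_s[bad[1] + 1L]))
    }
    if (nrow(d) < 8L) {
      abort_validation(sprintf("trace %s/%s has %d frames; at least 8 are required.",
                               key$kidney_id, key$roi, nrow(d)))
    }
    invisible(NULL)
  }
  df |>
    dplyr::group_by(.data$kidney_id, .data$roi) |>
    dplyr::group_walk(validate_trace)

  # shared time vector across ROIs of a kidney
  df |>
    dplyr::group_by(.data$kidney_id) |>
    dplyr::group_walk(function(d, key) {
      tv <- split(d$time_s, d$roi)
      if (length(tv) > 1L) {
        ref <- tv[[1]]
        same <- vapply(tv, function(x) length(x) == length(ref) && all(x == ref), logical(1))
        if (!all(same)) {
          abort_validation(sprintf(
            "ROIs of kidney %s do not share an identical time vector (%s differs).",
            key$kidney_id, names(tv)[which(!same)[1]]))
        }
      }
    })

  out <- df |>
    dplyr::select(-".row") |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$kidney_id, .data$roi, .data$time_s)
  class(out) <- c("ceus_tic", class(out))
  out
}

#' Read a time-intensity table from delimited text
#'
#' Reads the per-frame ROI mean-intensity export of an ultrasound
#' quantification package. Two layouts are supported: *long* — columns
#' (time, roi, intensity), one row per frame per ROI — and *wide* — a time
#' column plus one intensity column per ROI. Comma- and tab-delimited files
#' are auto-detected; a header row is required. Non-monotone or duplicated
#' timestamps are rejected with the offending input row named (a QLAB-style
#' export has one row per frame, so duplicates indicate a corrupted file).
#'
#' @param path Path to a delimited UTF-8 text file.
#' @param layout `"long"` or `"wide"`.
#' @param column_map Named list renaming input columns; recognised names are
#'   `time`, `roi`, `intensity` (long layout), and `kidney` for an optional
#'   kidney-id column (a column literally named `kidney` is picked up
#'   automatically). E.g. `list(time = "Time(ms)", intensity = "MeanIntensity")`.
#' @param time_unit `"s"` (default) or `"ms"`; times are converted to seconds.
#' @param kidney_id Kidney identifier used when the file has no kidney column.
#' @param lenient Clamp negative intensities to zero instead of erroring.
#' @return A validated [as_tic()] tibble.
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("time,roi,intensity", "0,cortex,0", "0.1,cortex,2",
#'              "0.2,cortex,5", "0.3,cortex,7", "0.4,cortex,8",
#'              "0.5,cortex,8", "0.6,cortex,7", "0.7,cortex,6"), p)
#' read_tic_table(p, layout = "long")
read_tic_table <- function(path, layout = c("long", "wide"), column_map = list(),
                           time_unit = c("s", "ms"), kidney_id = "kidney",
                           lenient = FALSE) {
  layout <- match.arg(layout)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  map <- utils::modifyList(list(time = "time", roi = "roi", intensity = "intensity",
                                kidney = NULL), column_map)
  if (is.null(map$kidney) && "kidney" %in% names(raw)) map$kidney <- "kidney"

  need_col <- function(nm, role) {
    if (!nm %in% names(raw)) {
      abort_validation(sprintf("required %s column `%s` not found in %s", role, nm, path))
    }
    raw[[nm]]
  }
  scale <- if (time_unit == "ms") 1e-3 else 1

  if (layout == "long") {
    df <- tibble::tibble(
      kidney_id = if (!is.null(map$kidney)) as.character(need_col(map$kidney, "kidney id"))
                  else kidney_id,
      roi = as.character(need_col(map$roi, "roi")),
      time_s = as.numeric(need_col(map$time, "time")) * scale,
      intensity_db = as.numeric(need_col(map$intensity, "intensity"))
    )
  } else {
    tcol <- map$time
    need_col(tcol, "time")
    roi_cols <- setdiff(names(raw), c(tcol, map$kidney))
    if (!length(roi_cols)) abort_validation("wide layout needs at least one ROI column.")
    df <- raw |>
      dplyr::rename(time_s = dplyr::all_of(tcol)) |>
      tidyr::pivot_longer(dplyr::all_of(roi_cols), names_to = "roi",
                          values_to = "intensity_db") |>
      dplyr::mutate(
        kidney_id = if (!is.null(map$kidney)) as.character(.data[[map$kidney]]) else kidney_id,
        time_s = as.numeric(.data$time_s) * scale,
        intensity_db = as.numeric(.data$intensity_db)
      ) |>
      dplyr::arrange(.data$roi) |>
      dplyr::select("kidney_id", "roi", "time_s", "intensity_db")
  }
  as_tic(df, lenient = lenient)
}

#' Detect contrast arrival (time zero) in a trace
#'
#' In the study design, time zero is the frame at which contrast is first
#' seen in the segmental/interlobar arteries. This function is a
#' deterministic automated surrogate: the baseline level is the mean
#' intensity of the first `baseline_frames` frames, and arrival is the first
#' frame whose intensity exceeds baseline + `delta_db` and stays above that
#' threshold for `sustain_frames` consecutive frames (so single-frame noise
#' spikes are not mistaken for arrival). A manual time zero can always be
#' passed straight to [rebase_and_truncate()] instead.
#'
#' @param tic A `ceus_tic` tibble, or a numeric time vector (then `intensity`
#'   must be given).
#' @param roi Which ROI to scan when `tic` holds several; defaults to an
#'   `"artery"` ROI when present, else the first ROI.
#' @param intensity Intensity vector when `tic` is a plain time vector.
#' @param baseline_frames,delta_db,sustain_frames Detection parameters;
#'   defaults 10 frames, 1 dB, 2 frames.
#' @return Arrival time in seconds (a value of the input time vector).
#' @export
detect_time_zero <- function(tic, roi = NULL, intensity = NULL,
                             baseline_frames = 10, delta_db = 1.0,
                             sustain_frames = 2) {
  if (is.data.frame(tic)) {
    rois <- unique(tic$roi)
    use <- roi %||% (if ("artery" %in% rois) "artery" else rois[1])
    if (!use %in% rois) abort_validation(sprintf("ROI `%s` not present.", use))
    d <- dplyr::filter(tic, .data$roi == use)
    times <- d$time_s
    intensity <- d$intensity_db
  } else {
    times <- tic
    if (is.null(intensity)) abort_validation("`intensity` required with a time vector.")
  }
  n <- length(times)
  if (n < baseline_frames + sustain_frames) {
    abort_validation("trace shorter than baseline_frames + sustain_frames.")
  }
  threshold <- mean(intensity[seq_len(baseline_frames)]) + delta_db
  above <- intensity > threshold
  run <- 0L
  for (i in rev(seq_len(n))) {      # run[i] = consecutive above-threshold frames from i
    run <- if (above[i]) run + 1L else 0L
    above[i] <- run >= sustain_frames
  }
  hit <- which(above)
  if (!length(hit)) {
    abort_degenerate(sprintf(
      "no contrast arrival detected (no frame exceeds baseline %.3g + %.3g dB for %d consecutive frames).",
      threshold - delta_db, delta_db, sustain_frames))
  }
  times[hit[1]]
}

#' Rebase a recording to time zero and truncate to the analysis window
#'
#' Shifts every trace so that `t0` becomes time zero, drops frames before it,
#' and cuts the clip to `window` seconds (default 30 s — long enough for all
#' kidney regions to reach peak intensity after an arterial bolus). No
#' padding occurs when the recording is shorter than the window.
#'
#' @param tic A `ceus_tic` tibble.
#' @param t0 Time zero in the recording's original seconds. Either a single
#'   value or a named vector/list keyed by kidney_id.
#' @param window Analysis window length in seconds after `t0`.
#' @return A `ceus_tic` tibble with times in `[0, window]`.
#' @export
rebase_and_truncate <- function(tic, t0, window = 30) {
  stopifnot_scalar_number(window, "window", positive = TRUE)
  per_kidney <- function(d, key) {
    tz <- if (length(t0) > 1L || !is.null(names(t0))) {
      v <- unlist(t0)[key$kidney_id]
      if (is.na(v)) abort_validation(sprintf("no t0 supplied for kidney %s", key$kidney_id))
      as.numeric(v)
    } else as.numeric(t0)
    if (tz < min(d$time_s) || tz > max(d$time_s)) {
      abort_validation(sprintf("t0 = %.6g s is outside the recorded range [%.6g, %.6g] for kidney %s.",
                               tz, min(d$time_s), max(d$time_s), key$kidney_id))
    }
    d |>
      dplyr::mutate(time_s = .data$time_s - tz) |>
      dplyr::filter(.data$time_s >= 0, .data$time_s <= window) |>
      dplyr::mutate(kidney_id = key$kidney_id)
  }
  out <- tic |>
    dplyr::group_by(.data$kidney_id) |>
    dplyr::group_map(per_kidney) |>
    dplyr::bind_rows()
  short <- out |>
    dplyr::count(.data$kidney_id, .data$roi) |>
    dplyr::filter(.data$n < 8L)
  if (nrow(short)) {
    abort_validation(sprintf(
      "fewer than 8 frames remain after truncation for trace %s/%s.",
      short$kidney_id[1], short$roi[1]))
  }
  as_tic(out)
}

#' Write / read a curve-metrics table
#'
#' Comma-delimited, one row per (kidney, ROI), columns
#' `kidney_id,roi,peak_intensity_db,time_to_peak_s,auc_db_s,time_to_fraction_s,fraction`.
#' Values round-trip losslessly (full double precision is written).
#'
#' @param metrics Metrics tibble as produced by [analyze_tic()].
#' @param path Destination / source file path.
#' @return `write_metrics_table()` returns `path` invisibly;
#'   `read_metrics_table()` returns the metrics tibble.
#' @export
write_metrics_table <- function(metrics, path) {
  cols <- c("kidney_id", "roi", "peak_intensity_db", "time_to_peak_s",
            "auc_db_s", "time_to_fraction_s", "fraction")
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    abort_validation("`metrics` must be a non-empty data frame.")
  }
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols)) {
    abort_validation(sprintf("metrics table lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(dplyr::select(metrics, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    kidney_id = readr::col_character(),
                    roi = readr::col_character(),
                    .default = readr::col_double()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
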