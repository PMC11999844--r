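# Region-of-interest extraction from cine image stacks: rasterise a square
# or polygon ROI (coordinates in mm, image origin top-left, x rightward,
# y downward) to a pixel mask, then average pixel intensities under the mask
# per frame to obtain a time-intensity trace. Membership is decided by the
# pixel centre: even-odd rule for polygons, half-open [min, max) edges for
# squares so adjacent squares never share pixels.

#' Define a region of interest
#'
#' `roi_square()` is the axis-aligned square used for the cortex (the study
#' protocol uses a 5 x 5 mm square); `roi_polygon()` is the freeform polygon
#' used for the medullary regions.
#'
#' @param label ROI label (e.g. `"cortex"`, `"outer_medulla"`).
#' @param center_x_mm,center_y_mm Square centre in mm from the image's
#'   top-left corner (x rightward, y downward).
#' @param side_mm Square side length in mm, > 0.
#' @return A list of class `ceus_roi`.
#' @export
roi_square <- function(label, center_x_mm, center_y_mm, side_mm) {
  stopifnot_scalar_number(side_mm, "side_mm", positive = TRUE)
  structure(list(label = label, shape = "square",
                 center = c(x = center_x_mm, y = center_y_mm), side = side_mm),
            class = "ceus_roi")
}

#' @rdname roi_square
#' @param x_mm,y_mm Polygon vertex coordinates in mm (>= 3 vertices, taken
#'   in order; the polygon is closed implicitly).
#' @export
roi_polygon <- function(label, x_mm, y_mm) {
  if (length(x_mm) != length(y_mm) || length(x_mm) < 3L) {
    abort_validation("a polygon ROI needs >= 3 (x, y) vertex pairs.")
  }
  area <- abs(sum(x_mm * c(y_mm[-1], y_mm[1]) - c(x_mm[-1], x_mm[1]) * y_mm)) / 2
  if (area == 0) abort_validation("polygon ROI has zero area.")
  structure(list(label = label, shape = "polygon",
                 x = as.numeric(x_mm), y = as.numeric(y_mm)),
            class = "ceus_roi")
}

#' Rasterise an ROI to a binary pixel mask
#'
#' A pixel belongs to the mask iff its centre lies inside the shape. Pixel
#' (r, c) has centre x = (c - 0.5) * spacing, y = (r - 0.5) * spacing from
#' the image's top-left corner. Squares use half-open `[min, max)` edges;
#' polygons the even-odd (ray-crossing) rule.
#'
#' @param roi A [roi_square()] / [roi_polygon()] object.
#' @param frame_dims Integer `c(rows, cols)` of the image frames.
#' @param pixel_spacing mm per pixel: a single value, or `c(row_mm, col_mm)`.
#' @return Logical matrix `frame_dims[1] x frame_dims[2]`.
#' @export
#' @examples
#' m <- rasterize_roi(roi_square("cortex", 10, 10, 5), c(40, 40), 0.5)
#' sum(m)   # (5 / 0.5)^2 = 100 pixels
rasterize_roi <- function(roi, frame_dims, pixel_spacing) {
  stopifnot(inherits(roi, "ceus_roi"))
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) abort_validation("`pixel_spacing` must be > 0.")
  rows <- as.integer(frame_dims[1]); cols <- as.integer(frame_dims[2])
  width_mm <- cols * pixel_spacing[2]; height_mm <- rows * pixel_spacing[1]

  bb <- roi_bbox(roi)
  if (bb["xmin"] < 0 || bb["ymin"] < 0 || bb["xmax"] > width_mm || bb["ymax"] > height_mm) {
    abort_validation(sprintf(
      "ROI `%s` extends outside the %.3g x %.3g mm frame.", roi$label, width_mm, height_mm))
  }
  cx <- (seq_len(cols) - 0.5) * pixel_spacing[2]
  cy <- (seq_len(rows) - 0.5) * pixel_spacing[1]
  px <- matrix(cx, rows, cols, byrow = TRUE)
  py <- matrix(cy, rows, cols)

  mask <- if (roi$shape == "square") {
    x0 <- roi$center["x"] - roi$side / 2; y0 <- roi$center["y"] - roi$side / 2
    px >= x0 & px < x0 + roi$side & py >= y0 & py < y0 + roi$side
  } else {
    matrix(point_in_polygon(as.vector(px), as.vector(py), roi$x, roi$y),
           rows, cols)
  }
  if (!any(mask)) abort_validation(sprintf("ROI `%s` rasterises to an empty mask.", roi$label))
  mask
}

roi_bbox <- function(roi) {
  if (roi$shape == "square") {
    h <- roi$side / 2
    c(xmin = unname(roi$center["x"]) - h, xmax = unname(roi$center["x"]) + h,
      ymin = unname(roi$center["y"]) - h, ymax = unname(roi$center["y"]) + h)
  } else {
    c(xmin = min(roi$x), xmax = max(roi$x), ymin = min(roi$y), ymax = max(roi$y))
  }
}

# Even-odd ray casting, vectorised over query points. A point on a
# horizontal ray through a vertex is handled by the usual half-open edge
# rule (yi <= y < yj or yj <= y < yi).
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > y) != (vy[j] > y)) &
      (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Build a frame stack
#'
#' A cine loop held in memory: an ordered set of equally sized grayscale
#' frames (decibel-scaled pixel values) with per-frame timestamps and the
#' physical pixel spacing.
#'
#' @param frames A list of numeric matrices, or a `rows x cols x n` array.
#' @param timestamps Strictly increasing per-frame times in seconds.
#' @param pixel_spacing mm per pixel, single value or `c(row_mm, col_mm)`.
#' @return A list of class `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps, pixel_spacing) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!length(frames)) abort_validation("`frames` is empty.")
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) abort_validation("all frames must share the same dimensions.")
  if (length(timestamps) != length(frames)) {
    abort_validation("`timestamps` length must equal the number of frames.")
  }
  if (any(diff(timestamps) <= 0)) {
    abort_validation("`timestamps` must be strictly increasing.")
  }
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) abort_validation("`pixel_spacing` must be > 0.")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 pixel_spacing = pixel_spacing, dims = d),
            class = "frame_stack")
}

#' Read a frame stack from a multi-page TIFF
#'
#' Pages are taken in file order as frames; timestamps come either from a
#' supplied vector or from a two-column sidecar table (`frame,time_s`).
#' Colour pages are averaged to grayscale.
#'
#' @param path Multi-page TIFF file.
#' @param timestamps Numeric vector of per-frame seconds, or the path to a
#'   comma-delimited sidecar with columns `frame,time_s`.
#' @param pixel_spacing mm per pixel, single value or `c(row_mm, col_mm)`.
#' @param intensity_scale Factor applied to the pixel values read from file
#'   (TIFF stores values in `[0, 1]`; default 1).
#' @return A [frame_stack()].
#' @export
read_stack_tiff <- function(path, timestamps, pixel_spacing, intensity_scale = 1) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    p * intensity_scale
  })
  if (is.character(timestamps)) {
    ts <- readr::read_csv(timestamps, show_col_types = FALSE, progress = FALSE)
    if (!all(c("frame", "time_s") %in% names(ts))) {
      abort_validation("timestamp sidecar needs columns `frame,time_s`.")
    }
    timestamps <- ts$time_s[order(ts$frame)]
  }
  frame_stack(frames, timestamps, pixel_spacing)
}

#' Extract time-intensity traces from a frame stack
#'
#' For each ROI and frame, the arithmetic mean of the pixel values whose
#' centres fall inside the ROI — the quantification step that turns a cine
#' loop plus ROI drawings into per-region TIC tables.
#'
#' @param stack A [frame_stack()].
#' @param rois A list of [roi_square()] / [roi_polygon()] objects (a single
#'   ROI is accepted).
#' @param kidney_id Kidney identifier for the resulting table.
#' @return A `ceus_tic` tibble with one trace per ROI, sharing the stack's
#'   timestamps.
#' @export
extract_tic <- function(stack, rois, kidney_id = "kidney") {
  stopifnot(inherits(stack, "frame_stack"))
  if (inherits(rois, "ceus_roi")) rois <- list(rois)
  traces <- purrr::map(rois, function(roi) {
    mask <- rasterize_roi(roi, stack$dims, stack$pixel_spacing)
    tibble::tibble(
      kidney_id = kidney_id, roi = roi$label, time_s = stack$timestamps,
      intensity_db = vapply(stack$frames, function(f) mean(f[mask]), numeric(1)))
  })
  as_tic(dplyr::bind_rows(traces))
}

#' Simulate a cine stack of gamma-variate ROIs
#'
#' Builds a frame stack in which the pixels of each ROI follow that ROI's
#' gamma-variate bolus curve plus independent per-pixel gaussian noise,
#' while background pixels stay at (clamped) noise level — contrast mode
#' has essentially zero background signal. ROIs must not overlap.
#'
#' @param rois List of ROI definitions.
#' @param params_per_roi List of [bolus_params()] of the same length
#'   (`noise_sd` is applied per pixel; `frame_rate`/`duration` are taken
#'   from the first element).
#' @param frame_dims `c(rows, cols)` in pixels.
#' @param pixel_spacing mm per pixel.
#' @param seed Integer seed.
#' @return A [frame_stack()].
#' @export
simulate_stack <- function(rois, params_per_roi, frame_dims, pixel_spacing,
                           seed = 1L) {
  if (inherits(rois, "ceus_roi")) rois <- list(rois)
  if (length(params_per_roi) != length(rois)) {
    abort_validation("`params_per_roi` must match `rois` in length.")
  }
  masks <- lapply(rois, rasterize_roi, frame_dims = frame_dims,
                  pixel_spacing = pixel_spacing)
  overlap <- Reduce(`+`, lapply(masks, `+`, 0))
  if (any(overlap > 1)) abort_validation("ROIs overlap; masks must be disjoint.")
  p1 <- params_per_roi[[1]]
  t <- seq(0, p1$duration, by = 1 / p1$frame_rate)
  withr::with_seed(as.integer(seed), {
    frames <- lapply(seq_along(t), function(k) {
      f <- matrix(0, frame_dims[1], frame_dims[2])
      for (i in seq_along(rois)) {
        p <- params_per_roi[[i]]
        v <- gamma_variate(t[k], p$amplitude, p$arrival, p$rise, p$shape)
        npx <- sum(masks[[i]])
        noise <- if (p$noise_sd > 0) rnorm(npx, 0, p$noise_sd) else 0
        f[masks[[i]]] <- pmax(v + noise, 0)
      }
      f
    })
    frame_stack(frames, t, pixel_spacing)
  })
}

#' Write a frame stack to a multi-page TIFF
#'
#' Pixel values are rescaled into the unit interval by `1 / intensity_scale` for TIFF
#' storage; [read_stack_tiff()] with the same `intensity_scale` restores the
#' decibel scale (up to the file's bit depth).
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param timestamp_path Optional path for a `frame,time_s` sidecar table.
#' @param intensity_scale Decibel value mapped to 1.0 in the file; defaults
#'   to the stack's maximum.
#' @param bits_per_sample TIFF bit depth (default 16).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, timestamp_path = NULL,
                             intensity_scale = NULL, bits_per_sample = 16) {
  stopifnot(inherits(stack, "frame_stack"))
  intensity_scale <- intensity_scale %||% max(1e-12, max(unlist(stack$frames)))
  pages <- lapply(stack$frames, function(f) pmin(pmax(f / intensity_scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  if (!is.null(timestamp_path)) {
    readr::write_csv(tibble::tibble(frame = seq_along(stack$timestamps),
                                    time_s = stack$timestamps), timestamp_path)
  }
  invisible(path)
}
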