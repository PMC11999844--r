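test_that("a 5 x 5 mm square at 0.5 mm/px rasterises to exactly 100 pixels", {
  mask <- rasterize_roi(roi_square("cortex", 10, 10, 5), c(40, 40), 0.5)
  expect_equal(sum(mask), 100L)
  # half-open edges: adjacent squares never share pixels
  left <- rasterize_roi(roi_square("a", 7.5, 10, 5), c(40, 40), 0.5)
  right <- rasterize_roi(roi_square("b", 12.5, 10, 5), c(40, 40), 0.5)
  expect_equal(sum(left & right), 0L)
  expect_equal(sum(left) + sum(right), 200L)
})

test_that("polygon masks equal the per-pixel even-odd oracle", {
  tri <- roi_polygon("medulla", c(2, 18, 10), c(3, 5, 17))
  dims <- c(40, 40); spacing <- 0.5
  mask <- rasterize_roi(tri, dims, spacing)
  oracle <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    for (c in seq_len(dims[2])) {
      oracle[r, c] <- oracle_point_in_polygon((c - 0.5) * spacing, (r - 0.5) * spacing,
                                              tri$x, tri$y)
    }
  }
  expect_identical(mask, oracle)

  # non-convex polygon too
  arrow <- roi_polygon("m", c(2, 10, 18, 10), c(2, 18, 2, 8))
  mask2 <- rasterize_roi(arrow, dims, spacing)
  oracle2 <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    for (c in seq_len(dims[2])) {
      oracle2[r, c] <- oracle_point_in_polygon((c - 0.5) * spacing, (r - 0.5) * spacing,
                                               arrow$x, arrow$y)
    }
  }
  expect_identical(mask2, oracle2)
})

test_that("geometry errors: out-of-frame and degenerate ROIs", {
  expect_error(rasterize_roi(roi_square("x", 30, 10, 5), c(40, 40), 0.5),
               "outside", class = "ceustic_validation")
  expect_error(roi_polygon("flat", c(0, 1, 2), c(0, 0, 0)), "zero area",
               class = "ceustic_validation")
  expect_error(roi_polygon("two", c(0, 1), c(0, 1)), ">= 3",
               class = "ceustic_validation")
})

test_that("mask area converges to the analytic polygon area as pixels shrink", {
  poly <- roi_polygon("m", c(2.3, 16.1, 13.6, 4.4), c(2.2, 4.7, 15.8, 13.1))
  shoelace <- abs(sum(poly$x * c(poly$y[-1], poly$y[1]) -
                        c(poly$x[-1], poly$x[1]) * poly$y)) / 2
  err <- vapply(c(0.5, 0.2, 0.05), function(sp) {
    mask <- rasterize_roi(poly, c(ceiling(20 / sp), ceiling(20 / sp)), sp)
    abs(sum(mask) * sp^2 - shoelace) / shoelace
  }, numeric(1))
  expect_equal(which.min(err), 3L)
  expect_lt(err[3], 0.005)
})

test_that("mean extraction matches brute-force accumulation and is linear", {
  withr::with_seed(61, {
    frames <- lapply(1:12, function(i) matrix(runif(40 * 40, 0, 20), 40, 40))
  })
  stack <- frame_stack(frames, seq(0, 1.1, by = 0.1), 0.5)
  roi <- roi_square("cortex", 10, 10, 5)
  tic <- extract_tic(stack, roi)
  mask <- rasterize_roi(roi, c(40, 40), 0.5)
  brute <- vapply(frames, function(f) {
    acc <- 0; npx <- 0
    for (r in 1:40) for (c in 1:40) if (mask[r, c]) { acc <- acc + f[r, c]; npx <- npx + 1 }
    acc / npx
  }, numeric(1))
  expect_lt(max(abs(tic$intensity_db - brute)), 1e-10)

  # uniform frame -> its value; straddling halves -> midpoint mean
  ustack <- frame_stack(lapply(seq(2, 9), function(v) matrix(v, 40, 40)),
                        seq_len(8), 0.5)
  utic <- extract_tic(ustack, roi)
  expect_equal(utic$intensity_db, as.numeric(seq(2, 9)))
  half <- cbind(matrix(3, 40, 20), matrix(9, 40, 20))
  hstack <- frame_stack(rep(list(half), 8), seq_len(8), 0.5)
  htic <- extract_tic(hstack, roi_square("mid", 10, 10, 5))
  expect_equal(htic$intensity_db, rep(6, 8))

  # permuting pixels within the mask leaves the trace unchanged
  permuted <- lapply(frames, function(f) {
    v <- f[mask]
    f[mask] <- v[c(length(v), seq_len(length(v) - 1))]
    f
  })
  ptic <- extract_tic(frame_stack(permuted, seq(0, 1.1, by = 0.1), 0.5), roi)
  expect_equal(ptic$intensity_db, tic$intensity_db, tolerance = 1e-12)
})

test_that("a noiseless simulated stack round-trips to the analytic curves", {
  rois <- list(roi_square("cortex", 5, 5, 4),
               roi_polygon("outer_medulla", c(10, 18, 18, 10), c(10, 10, 18, 18)))
  params <- list(bolus_params(10, 2, 4, 2, noise_sd = 0, frame_rate = 5, duration = 15),
                 bolus_params(6, 4, 6, 2, noise_sd = 0, frame_rate = 5, duration = 15))
  stack <- simulate_stack(rois, params, c(40, 40), 0.5, seed = 3)
  tic <- extract_tic(stack, rois)
  for (i in 1:2) {
    p <- params[[i]]
    tr <- dplyr::filter(tic, roi == rois[[i]]$label)
    expect_lt(max(abs(tr$intensity_db -
                        gamma_variate(tr$time_s, p$amplitude, p$arrival,
                                      p$rise, p$shape))), 1e-10)
  }
  # background stays at zero
  bg <- extract_tic(stack, roi_square("background", 15, 3, 3))
  expect_true(all(bg$intensity_db == 0))
  # determinism and overlap rejection
  expect_identical(simulate_stack(rois, params, c(40, 40), 0.5, seed = 3)$frames,
                   stack$frames)
  expect_error(simulate_stack(list(roi_square("a", 5, 5, 4), roi_square("b", 6, 5, 4)),
                              params, c(40, 40), 0.5),
               "overlap", class = "ceustic_validation")
})

test_that("frame stacks survive a TIFF round trip", {
  rois <- list(roi_square("cortex", 5, 5, 4))
  params <- list(bolus_params(10, 2, 4, 2, noise_sd = 0.2, frame_rate = 5,
                              duration = 12, seed = 2))
  stack <- simulate_stack(rois, params, c(32, 32), 0.5, seed = 2)
  tif <- tempfile(fileext = ".tif"); sidecar <- tempfile(fileext = ".csv")
  write_stack_tiff(stack, tif, timestamp_path = sidecar, intensity_scale = 12)
  back <- read_stack_tiff(tif, sidecar, 0.5, intensity_scale = 12)
  expect_equal(back$timestamps, stack$timestamps)
  worst <- max(mapply(function(a, b) max(abs(a - b)), back$frames, stack$frames))
  expect_lt(worst, 12 / 2^15)    # within 16-bit quantisation
})
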