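test_that("long and wide layouts parse to identical recordings", {
  t <- seq(0, 2, by = 0.25)
  cortex <- c(0, 1, 3, 6, 8, 8, 6, 4, 3)
  outer <- c(0, 0, 1, 2, 4, 6, 7, 6, 5)
  long <- tibble::tibble(time = rep(t, 2),
                         roi = rep(c("cortex", "outer_medulla"), each = length(t)),
                         intensity = c(cortex, outer))
  wide <- tibble::tibble(time = t, cortex = cortex, outer_medulla = outer)
  rec_long <- read_tic_table(write_long_tic(long), layout = "long")
  rec_wide <- read_tic_table(write_wide_tic(wide), layout = "wide")
  expect_equal(rec_long, rec_wide)
  expect_s3_class(rec_long, "ceus_tic")
  expect_equal(dplyr::n_distinct(rec_long$roi), 2L)
})

test_that("tab-delimited input and millisecond time units are handled", {
  d <- tiny_trace()
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(stats::setNames(d, c("time", "roi", "intensity")), p)
  rec <- read_tic_table(p, layout = "long")
  expect_equal(rec$time_s, d$time)

  d_ms <- dplyr::mutate(d, time = time * 1000)
  rec_ms <- read_tic_table(write_long_tic(d_ms), layout = "long", time_unit = "ms")
  expect_equal(rec_ms$time_s, d$time)
})

test_that("non-monotone and duplicated timestamps are rejected, naming the row", {
  bad <- tibble::tibble(time = c(0, 0.2, 0.1, 0.3, 0.4, 0.5, 0.6, 0.7),
                        roi = "cortex", intensity = 1:8)
  expect_error(read_tic_table(write_long_tic(bad), layout = "long"),
               "row 3", class = "ceustic_validation")
  dup <- dplyr::mutate(bad, time = c(0, 0.1, 0.1, 0.3, 0.4, 0.5, 0.6, 0.7))
  expect_error(read_tic_table(write_long_tic(dup), layout = "long"),
               "duplicated", class = "ceustic_validation")
})

test_that("schema and intensity validation behave as documented", {
  noroi <- tibble::tibble(time = 1:8 / 10, intensity = 1:8)
  expect_error(read_tic_table(write_wide_tic(noroi), layout = "long"), "roi",
               class = "ceustic_validation")

  neg <- dplyr::mutate(tiny_trace(), intensity = replace(intensity, 2, -1))
  expect_error(read_tic_table(write_long_tic(neg), layout = "long"),
               "negative intensity", class = "ceustic_validation")
  lenient <- read_tic_table(write_long_tic(neg), layout = "long", lenient = TRUE)
  expect_equal(lenient$intensity_db[2], 0)

  short <- dplyr::slice(tiny_trace(), 1:5)
  expect_error(read_tic_table(write_long_tic(short), layout = "long"),
               "at least 8", class = "ceustic_validation")
})

test_that("contrast arrival detection applies the baseline + sustain rule", {
  t <- seq(0, 10, by = 0.5)
  clean <- ifelse(t >= 4, 20, 0)
  expect_equal(detect_time_zero(t, intensity = clean), 4.0)

  flat <- rep(0.2, length(t))
  expect_error(detect_time_zero(t, intensity = flat), "no contrast arrival",
               class = "ceustic_degenerate")

  spike <- numeric(length(t))
  spike[t == 2] <- 15                      # single-frame spike: not sustained
  spike[t >= 5] <- 15                      # sustained rise
  expect_equal(detect_time_zero(t, intensity = spike), 5.0)
  # brute-force scan applying the same rule frame by frame
  thr <- mean(spike[1:10]) + 1
  brute <- NA
  for (i in seq_along(t)) {
    if (i + 1 <= length(t) && all(spike[i:(i + 1)] > thr)) { brute <- t[i]; break }
  }
  expect_equal(detect_time_zero(t, intensity = spike), brute)
})

test_that("arrival detection is invariant to a constant intensity offset", {
  t <- seq(0, 12, by = 0.25)
  y <- ifelse(t >= 4.25, 10, 0) + ifelse(t >= 8, 3, 0)
  for (offset in c(0, 1.7, 50)) {
    expect_equal(detect_time_zero(t, intensity = y + offset), 4.25)
  }
})

test_that("rebase_and_truncate shifts, drops and enforces the window", {
  t <- seq(0, 60, by = 0.1)
  tic <- as_tic(tibble::tibble(kidney_id = "K1", roi = "cortex", time_s = t,
                               intensity_db = seq_along(t) / 100))
  out <- rebase_and_truncate(tic, t0 = 5, window = 30)
  expect_equal(range(out$time_s), c(0, 30))
  expect_equal(nrow(out), 301L)

  short <- as_tic(tibble::tibble(kidney_id = "K1", roi = "cortex",
                                 time_s = seq(0, 25, by = 0.1),
                                 intensity_db = 1))
  unchanged <- rebase_and_truncate(short, t0 = 0, window = 30)
  expect_equal(unchanged$time_s, short$time_s)   # no padding beyond the clip

  expect_error(rebase_and_truncate(short, t0 = 40), "outside the recorded range",
               class = "ceustic_validation")
  expect_error(rebase_and_truncate(short, t0 = 24.9, window = 30),
               "fewer than 8", class = "ceustic_validation")
})

test_that("rebasing is idempotent at t0 = 0 with the same window", {
  t <- seq(2, 50, by = 0.2)
  tic <- as_tic(tibble::tibble(kidney_id = "K1", roi = "cortex", time_s = t,
                               intensity_db = pmax(sin(t / 3), 0)))
  once <- rebase_and_truncate(tic, t0 = 4, window = 30)
  twice <- rebase_and_truncate(once, t0 = 0, window = 30)
  expect_equal(twice, once)
})

test_that("metrics tables round-trip losslessly through write/read", {
  withr::with_seed(99, {
    m <- tibble::tibble(
      kidney_id = rep(c("K1", "K2"), each = 3),
      roi = rep(ceus_regions(), 2),
      peak_intensity_db = runif(6, 1, 20),
      time_to_peak_s = runif(6, 2, 25),
      auc_db_s = runif(6, 10, 300),
      time_to_fraction_s = runif(6, 1, 20),
      fraction = 0.9)
  })
  p <- tempfile(fileext = ".csv")
  write_metrics_table(m, p)
  back <- read_metrics_table(p)
  expect_equal(nrow(back), 6L)
  for (col in names(m)[-(1:2)]) {
    expect_equal(back[[col]], m[[col]], tolerance = 1e-12)
  }
  expect_error(write_metrics_table(m[0, ], tempfile()), "non-empty",
               class = "ceustic_validation")
})
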