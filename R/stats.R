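# Pearson association of CEUS metrics/scores with perfusion outcomes. Small
# cohorts are the norm here (5-8 kidneys), so the p-value comes from the
# exact t-transform of r with n - 2 degrees of freedom, two-sided.

#' Two-sided p-value for a Pearson correlation
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to the t-distribution with
#' `n - 2` degrees of freedom, doubled for a two-sided test. `|r| = 1`
#' yields `p = 0` exactly.
#'
#' @param r Pearson correlation coefficient, `|r| <= 1` (vectorised).
#' @param n Number of paired observations, >= 3.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' p_from_r(-0.937, 5)   # 0.019 — a 5-kidney cohort
#' p_from_r(0.90, 8)     # 0.002 — an 8-kidney cohort
p_from_r <- function(r, n) {
  if (any(n < 3)) abort_validation("`n` must be at least 3.")
  if (any(abs(r) > 1)) abort_validation("`r` must lie in [-1, 1].")
  p <- ifelse(abs(r) == 1, 0, {
    t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
    2 * pt(-abs(t_stat), df = n - 2)
  })
  unname(p)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with non-zero
#'   variance.
#' @param x_name,y_name Labels recorded in the result.
#' @return One-row tibble of class `ceus_correlation`:
#'   `x, y, n, r, p`.
#' @export
pearson <- function(x, y, x_name = deparse1(substitute(x)),
                    y_name = deparse1(substitute(y))) {
  if (length(x) != length(y)) abort_validation("`x` and `y` lengths differ.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort_degenerate("fewer than 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_degenerate("zero variance: Pearson correlation is undefined.")
  }
  r <- cor(x, y)
  out <- tibble::tibble(x = x_name, y = y_name, n = n, r = r, p = p_from_r(r, n))
  class(out) <- c("ceus_correlation", class(out))
  out
}

#' Correlate per-kidney metrics or scores with outcomes
#'
#' One Pearson correlation per (metric, outcome) pair over the kidneys
#' present in both tables. Kidneys missing either value are excluded
#' pairwise; every exclusion is recorded in the `exclusions` attribute (and
#' messaged). No multiple-testing correction is applied — correlations are
#' reported per pair with raw p-values — but a note flags tables with more
#' than 10 pairs.
#'
#' @param wide Per-kidney table: a `kidney_id` column plus one numeric
#'   column per metric/score (see [widen_metrics()], [widen_scores()]).
#' @param outcomes Long outcome table with columns
#'   `kidney_id, outcome_name, value`.
#' @return Tibble of class `ceus_correlation` with columns `x, y, n, r, p`,
#'   one row per pair; attributes `exclusions` (tibble of dropped kidneys)
#'   and `note`.
#' @export
#' @examples
#' sim <- simulate_cohort(n_kidneys = 8, seed = 3)
#' scores <- analyze_tic(sim$tic) |> ceus_scores()
#' correlation_table(widen_scores(scores), sim$outcomes)
correlation_table <- function(wide, outcomes) {
  if (!"kidney_id" %in% names(wide)) abort_validation("`wide` needs a `kidney_id` column.")
  needed <- c("kidney_id", "outcome_name", "value")
  if (!all(needed %in% names(outcomes))) {
    abort_validation("`outcomes` needs columns kidney_id, outcome_name, value.")
  }
  metric_cols <- names(wide)[vapply(wide, is.numeric, logical(1))]
  if (!length(metric_cols)) abort_validation("`wide` has no numeric metric columns.")
  pairs <- tidyr::expand_grid(metric = metric_cols,
                              outcome = unique(outcomes$outcome_name))
  exclusions <- list()
  results <- purrr::pmap(pairs, function(metric, outcome) {
    o <- dplyr::filter(outcomes, .data$outcome_name == outcome)
    joined <- dplyr::inner_join(wide[, c("kidney_id", metric)], o, by = "kidney_id")
    ok <- is.finite(joined[[metric]]) & is.finite(joined$value)
    dropped <- union(setdiff(wide$kidney_id, joined$kidney_id), joined$kidney_id[!ok])
    if (length(dropped)) {
      exclusions[[length(exclusions) + 1L]] <<- tibble::tibble(
        x = metric, y = outcome, kidney_id = dropped)
    }
    if (sum(ok) < 3L) {
      abort_degenerate(sprintf(
        "fewer than 3 matched kidneys for pair (%s, %s).", metric, outcome))
    }
    pearson(joined[[metric]][ok], joined$value[ok], x_name = metric, y_name = outcome)
  })
  out <- dplyr::bind_rows(results)
  excl <- dplyr::bind_rows(exclusions)
  if (nrow(excl)) {
    inform(sprintf("%d kidney/pair exclusion(s) due to missing values; see attr(, \"exclusions\").",
                   nrow(excl)))
  }
  attr(out, "exclusions") <- excl
  attr(out, "note") <- if (nrow(out) > 10L) {
    sprintf("%d correlation pairs computed with raw (uncorrected) p-values.", nrow(out))
  } else NA_character_
  class(out) <- c("ceus_correlation", class(out))
  out
}

#' Write a correlation table
#'
#' Comma-delimited with header `x,y,n,r,p`.
#'
#' @param correlations A [correlation_table()] tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(correlations, path) {
  readr::write_csv(correlations, path)
  invisible(path)
}
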