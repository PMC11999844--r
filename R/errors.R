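# Condition classes used throughout: validation/schema problems
# ("ceustic_validation") versus data that is structurally fine but
# statistically degenerate ("ceustic_degenerate"). The CLI maps these to
# distinct exit statuses so pipelines can branch on failure class.

abort_validation <- function(message, ...) {
  abort(message, class = "ceustic_validation", ...)
}

abort_degenerate <- function(message, ...) {
  abort(message, class = "ceustic_degenerate", ...)
}

stopifnot_scalar_number <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", what))
  }
  if (positive && x <= 0) {
    abort_validation(sprintf("`%s` must be > 0.", what))
  }
  invisible(x)
}
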