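# Classed error conditions so callers (and tests) can discriminate failure
# modes without matching message text.

mr_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "microrad_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

err_validation <- function(msg) mr_abort(msg, "microrad_validation_error")
err_io <- function(msg) mr_abort(msg, "microrad_io_error")
err_unsupported <- function(msg) mr_abort(msg, "microrad_unsupported_format_error")
err_schema <- function(msg) mr_abort(msg, "microrad_schema_error")
err_degenerate <- function(msg) mr_abort(msg, "microrad_degenerate_normalization_error")
err_polarity <- function(msg) mr_abort(msg, "microrad_polarity_error")
err_insufficient <- function(msg) mr_abort(msg, "microrad_insufficient_data_error")
err_no_crossing <- function(msg) mr_abort(msg, "microrad_no_crossing_error")
err_alignment <- function(msg) mr_abort(msg, "microrad_alignment_error")

stopifnot_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    err_validation(sprintf("`%s` must be a single non-missing number", name))
  }
  if (finite && !is.finite(x)) {
    err_validation(sprintf("`%s` must be finite", name))
  }
  if (positive && x <= 0) {
    err_validation(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  invisible(x)
}
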