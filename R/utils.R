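# Internal helpers: classed conditions and small shared utilities.

sc_stop <- function(msg, class = "scstructr_error", call. = FALSE) {
  stop(structure(
    class = c(class, "scstructr_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_validation <- function(msg) sc_stop(msg, "scstructr_validation_error")
stop_format     <- function(msg) sc_stop(msg, "scstructr_format_error")
stop_lookup     <- function(msg) sc_stop(msg, "scstructr_lookup_error")
stop_usage      <- function(msg) sc_stop(msg, "scstructr_usage_error")

# Scalar integer-ish check
is_count <- function(x, positive = TRUE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x) &&
    (if (positive) x >= 1 else x >= 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
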