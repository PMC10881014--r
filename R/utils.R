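# Internal error helpers: every user-facing failure carries a class so the
# pipeline wrapper can map it to a categorized exit code.

abort_format <- function(msg, ...) {
  abort(msg, class = "isobeat_error_format", ...)
}

abort_parse <- function(msg, ...) {
  abort(msg, class = "isobeat_error_parse", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "isobeat_error_validation", ...)
}

abort_io <- function(msg, ...) {
  abort(msg, class = "isobeat_error_io", ...)
}

# Scalar checks used across modules.
check_number <- function(x, name, lower = -Inf, allow_zero = TRUE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || (!allow_zero && x == lower)) {
    cmp <- if (allow_zero) ">=" else ">"
    abort_validation(sprintf("`%s` must be %s %g (got %g).", name, cmp, lower, x))
  }
  invisible(x)
}
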