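# Classed conditions shared across the package.  Every user-facing error is a
# subclass of "pillartrap_error" so callers can catch families of failures
# (invalid input, insufficient data, degenerate designs, ...) selectively.

pt_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("pillartrap_error_", class),
                                  "pillartrap_error"), ...)
}

pt_warn <- function(message, class) {
  rlang::warn(message, class = c(paste0("pillartrap_warning_", class),
                                 "pillartrap_warning"))
}

check_number <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    pt_abort(sprintf("`%s` must be a non-missing numeric value.", name),
             "invalid_input")
  }
  if (finite && any(!is.finite(x))) {
    pt_abort(sprintf("`%s` must be finite.", name), "invalid_input")
  }
  if (positive && any(x <= 0)) {
    pt_abort(sprintf("`%s` must be strictly positive.", name), "invalid_input")
  }
  invisible(x)
}

# Euclidean norm of rows of a matrix
row_norms <- function(m) sqrt(rowSums(m * m))
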