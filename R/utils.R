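# Internal helpers shared across modules.

# Consistent error class so the CLI can map failures to exit codes.
pc_abort <- function(message, class = "platecal_error", ...) {
  rlang::abort(message, class = c(class, "platecal_error"), ...)
}

pc_schema_abort <- function(message, ...) {
  pc_abort(message, class = "platecal_schema_error", ...)
}

pc_numeric_abort <- function(message, ...) {
  pc_abort(message, class = "platecal_numeric_error", ...)
}

check_number <- function(x, name, finite = TRUE, positive = FALSE,
                         non_negative = FALSE) {
  if (!is.numeric(x)) {
    pc_abort(sprintf("`%s` must be numeric.", name))
  }
  if (finite && any(!is.finite(x))) {
    pc_abort(sprintf("`%s` must be finite.", name))
  }
  if (positive && any(x <= 0)) {
    pc_abort(sprintf("`%s` must be > 0.", name))
  }
  if (non_negative && any(x < 0)) {
    pc_abort(sprintf("`%s` must be >= 0.", name))
  }
  invisible(x)
}

# Deterministic per-stream seed derivation; keeps results independent of how
# many streams precede this one. Stays inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647
}
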