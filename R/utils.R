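# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a master seed and a counter, so
# per-chemical / per-plate random substreams are stable regardless of how much
# of the screen is generated. Simple LCG-style mixing; must stay < 2^31.
derive_seed <- function(master, counter) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  for (k in as.numeric(counter)) {
    s <- (s * 48271 + k * 16807 + 1) %% m
  }
  as.integer(s)
}

# Stop with a classed condition so tests can assert on error class.
stop_toxscreen <- function(msg, class) {
  abort(msg, class = c(class, "toxscreen_error"))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_toxscreen(
      sprintf(
        "%s is missing required column(s): %s (expected: %s)",
        what, paste(missing, collapse = ", "), paste(cols, collapse = ", ")
      ),
      "toxscreen_input_error"
    )
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
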