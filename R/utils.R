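# Internal helpers shared across modules.

# Typed aborts: every validation failure carries a condition class so callers
# (and the CLI) can distinguish bad input (icfeval_validation_error /
# icfeval_io_error / icfeval_degenerate_error / icfeval_config_error) from bugs.
abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = c("icfeval_validation_error", "icfeval_error"), ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = c("icfeval_io_error", "icfeval_error"), ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = c("icfeval_degenerate_error", "icfeval_error"), ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = c("icfeval_config_error", "icfeval_error"), ...)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG state when `seed` is given, restoring the
# caller's stream afterwards; with seed = NULL the current stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
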