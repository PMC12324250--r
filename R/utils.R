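# Internal helpers shared across modules.

# One root seed, many named substreams: each table/assay draws from its own
# deterministic substream so any single table can be regenerated in isolation.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(name) * (31L^(seq_along(utf8ToInt(name)) %% 7L)))
  as.integer((abs(as.numeric(seed)) + h) %% 2147483587)
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", what))
  }
  invisible(x)
}

assert_count <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must be a positive integer.", what))
  }
  invisible(x)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
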