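# Internal helpers shared across modules.

# Validate a scalar in a closed range, aborting with the field name.
check_range <- function(x, field, lo = -Inf, hi = Inf, integer = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number.", field))
  }
  if (x < lo || x > hi) {
    abort(sprintf("`%s` must lie in [%s, %s], got %s.", field,
                  format(lo), format(hi), format(x)))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number, got %s.", field, format(x)))
  }
  invisible(x)
}

# Seeded evaluation that never leaks RNG state into the caller's session.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_range(seed, "seed", integer = TRUE)
  withr::with_seed(as.integer(seed), code)
}

# Stable derived seed for a named sub-stream of a pipeline seed. Keeps the
# result in the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  chars <- utf8ToInt(stream)
  h <- sum(chars * seq_along(chars) * 2654435761) %% 2147480000
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480000) + 1L
}

# Pearson correlation that refuses constant input instead of returning NA.
safe_cor <- function(x, y, what = "vectors") {
  if (sd(x) == 0 || sd(y) == 0) {
    abort(sprintf("Correlation undefined: one of the %s is constant.", what))
  }
  cor(x, y)
}
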