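# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Population standard deviation (denominator n).  Pinned explicitly so the
# sample-entropy tolerance r = r_coeff * sigma is reproducible to the digit.
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# Invalid-argument / malformed-input signal; carries a condition class so
# the CLI can distinguish user errors (exit 1) from internal ones (exit 2).
stop_invalid <- function(...) {
  stop(errorCondition(sprintf(...), class = "nirsmse_invalid_input"))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid("%s contains non-finite values", what)
  invisible(x)
}
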