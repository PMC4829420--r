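# Internal helpers shared across modules.

# Fold positions into [lo, hi] by specular reflection (triangular-wave map).
# Handles arbitrarily large excursions in one shot, so a single Euler step
# that overshoots a boundary several times is still mapped correctly.
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (any(w <= 0)) abort("reflect_into: interval must have positive width")
  y <- (x - lo) %% (2 * w)
  lo + pmin(y, 2 * w - y)
}

# Draw a 32-bit-safe sub-seed stream of length n from the current RNG state.
derive_subseeds <- function(n) {
  sample.int(.Machine$integer.max, n, replace = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!(is.logical(x) && length(x) == 1 && !is.na(x))) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

# Set the RNG from `seed` unless NULL, restoring nothing: generators own
# their stream so that identical seeds reproduce results bit-for-bit.
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    check_number(seed, "seed", lower = 0, upper = .Machine$integer.max)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
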