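# Small numeric helpers shared across modules.

# Trapezoidal integral of y sampled at uniform step dt.
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

# Cumulative trapezoidal integral, same length as y, starting at 0.
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(rep(0, n))
  c(0, cumsum(dt * (y[-n] + y[-1]) / 2))
}

# Derive a child seed from a base seed and an index, kept within 32-bit
# integer range so set.seed() accepts it on any platform.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(index)) %% 2147483647L)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (allow_equal_lower) "[" else "(", lower, upper,
      if (allow_equal_upper) "]" else ")"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x != as.integer(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

# Draw from a normal distribution truncated below (simple rejection;
# fine for the mild truncations used by the cohort generator).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort("standard deviation must be >= 0")
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1
  }
  pmin(pmax(out, lower), upper)
}
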