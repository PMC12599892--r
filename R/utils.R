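# Internal helpers shared across modules.

# Set the RNG seed for the calling scope, restoring the previous RNG state
# on exit; a NULL seed leaves the global stream untouched.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

# Wrap phase to the half-open interval (-pi, pi].
wrap_phase <- function(x) {
  out <- x - 2 * pi * round(x / (2 * pi))
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) ||
      x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}
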