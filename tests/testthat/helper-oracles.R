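# Independent oracles used to check the package's own implementations.

# Two-sided exact Mann-Whitney p by brute-force enumeration of all
# choose(n+m, n) labelings (independent of the package's DP recursion).
enum_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  all_u <- combn(N, n, u_of)
  u1 <- u_of(seq_len(n))
  p_le <- mean(all_u <= u1 + 1e-9)
  p_ge <- mean(all_u >= u1 - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Kruskal-Wallis H from the rank-mean formula (tie-free data only).
rank_formula_H <- function(samples) {
  pooled <- unlist(samples)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(samples), lengths(samples))
  rbar <- tapply(r, grp, mean)
  ni <- lengths(samples)
  12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
}

# Closed-form least-squares slope via the normal equations.
normal_eq_slope <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) / (sum(x^2) - n * mean(x)^2)
}

# Small, fast OCE configuration for unit tests.
fast_oce_config <- function(...) {
  oce_sim_config(n_depth = 32L, n_frames = 128L, frame_interval = 1e-5, ...)
}
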