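# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: partitions are enumerated by brute force, slopes
# come from the normal equations, and Johnson-Neyman boundaries from a dense
# grid search.

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  rec <- function(k, memb, mx) {
    if (k > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (c in seq_len(mx + 1L)) rec(k + 1L, c(memb, c), max(mx, c))
  }
  rec(2L, 1L, 1L)
  out
}

# Best modularity over every partition (exhaustive search).
exhaustive_best_modularity <- function(A) {
  max(vapply(all_partitions(nrow(A)), function(m) modularity_score(A, m),
             numeric(1)))
}

# OLS slope from the normal equations (X'X)^{-1} X'y.
ols_slope_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[2, 1]
}

# Johnson-Neyman boundaries located by dense grid search: grid points where
# the significance indicator |t(w)| > crit flips.
jn_grid_boundaries <- function(gamma_f, gamma_c, v_ff, v_fc, v_cc, crit,
                               lo, hi, step) {
  w <- seq(lo, hi, by = step)
  tr <- abs(gamma_f + gamma_c * w) / sqrt(v_ff + 2 * w * v_fc + w^2 * v_cc)
  sig <- tr > crit
  flips <- which(diff(sig) != 0)
  (w[flips] + w[flips + 1]) / 2
}

# Mean of a normal truncated to [lo, hi] (closed form).
truncated_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Symmetric adjacency of two disjoint triangles (nodes 1-3 and 4-6).
two_triangles <- function() {
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  }
  A
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

# Random symmetric weight matrix with distinct off-diagonal weights.
random_weights <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  w[ut] <- sample(seq_along(ut)) + stats::runif(length(ut), -0.1, 0.1)
  w + t(w)
}

# Random Erdos-Renyi binary graph, guaranteed at least one edge.
random_binary_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- stats::rbinom(length(ut), 1L, p)
  A <- A + t(A)
  if (sum(A) == 0) A[1, 2] <- A[2, 1] <- 1L
  A
}
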