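# Shared fixtures and independent oracles for the estimator tests.

# random meta-analysis instance with k studies
random_instance <- function(k = sample(2:10, 1), tau2 = runif(1, 0, 2)) {
  s2 <- runif(k, 0.2, 3)
  y <- rnorm(k, 0, sqrt(s2 + tau2))
  list(y = y, s2 = s2)
}

# Coarse-to-fine grid search for the Paule-Mandel root: minimizes |F| over
# tau2 in [0, 50] at step `coarse`, then refines around the minimum at
# step `fine`.  Independent of the package root-finder.
pm_grid_oracle <- function(y, s2, coarse = 0.01, fine = 1e-4) {
  k <- length(y)
  Ffun <- function(t2) {
    w <- 1 / (s2 + t2)
    M <- sum(w * y) / sum(w)
    sum(w * (y - M)^2) - (k - 1)
  }
  if (Ffun(0) <= 0) return(0)
  grid <- seq(0, 50, by = coarse)
  vals <- vapply(grid, Ffun, 0)
  i <- which.min(abs(vals))
  lo <- max(0, grid[i] - coarse); hi <- min(50, grid[i] + coarse)
  grid2 <- seq(lo, hi, by = fine)
  grid2[which.min(abs(vapply(grid2, Ffun, 0)))]
}

# Grid search maximizing the restricted log-likelihood over [0, 50].
reml_grid_oracle <- function(y, s2, coarse = 0.01, fine = 1e-4) {
  grid <- seq(0, 50, by = coarse)
  vals <- vapply(grid, reml_loglik, 0, y = y, s2 = s2)
  i <- which.max(vals)
  lo <- max(0, grid[i] - coarse); hi <- min(50, grid[i] + coarse)
  grid2 <- seq(lo, hi, by = fine)
  grid2[which.max(vapply(grid2, reml_loglik, 0, y = y, s2 = s2))]
}

# Brute-force AUC: proportion of (positive, negative) score pairs that are
# concordant, ties counted half.
mw_auc_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Small benchmark config used where the full benchmark scale is not needed.
small_expr_config <- function(seed, n_per_arm = 10) {
  expr_sim_config(n_genes = 400, n_clusters = 10, cluster_size = 20,
                  n_per_arm = n_per_arm, seed = seed)
}
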