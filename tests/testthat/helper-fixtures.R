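# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; nothing binary is stored.

seeded_matrix <- function(nr, nc, seed, sd = 1) {
  withr::with_seed(seed, matrix(rnorm(nr * nc, sd = sd), nr, nc))
}

# Brute-force scalar prox oracle for 0.5*(x - y)^2 + t*|x|:
# coarse grid then golden-section-style refinement.
scalar_soft_oracle <- function(y, t, tol = 1e-10) {
  f <- function(x) 0.5 * (x - y)^2 + t * abs(x)
  grid <- seq(-abs(y) - 1, abs(y) + 1, length.out = 2001)
  x0 <- grid[which.min(vapply(grid, f, numeric(1)))]
  lo <- x0 - 2e-3; hi <- x0 + 2e-3
  opt <- optimize(f, c(lo, hi), tol = tol)
  # |x| kinks at 0; check 0 explicitly
  if (f(0) < opt$objective) 0 else opt$minimum
}

# Brute-force per-singular-value prox oracle for the weighted SVT problem
# 0.5*(x - sigma)^2 + tau*w*x over x >= 0 (valid under the non-descending
# weight convention, where the problem separates across singular values).
per_sigma_oracle <- function(sigma, w, tau) {
  vapply(seq_along(sigma), function(j) {
    f <- function(x) 0.5 * (x - sigma[j])^2 + tau * w[j] * x
    grid <- seq(0, sigma[j] + 1, length.out = 2001)
    x0 <- grid[which.min(vapply(grid, f, numeric(1)))]
    opt <- optimize(f, c(max(0, x0 - 2e-3), x0 + 2e-3), tol = 1e-12)
    if (f(0) < opt$objective) 0 else opt$minimum
  }, numeric(1))
}

# Objective of the weighted SVT problem for a candidate X (weights paired
# ascending-weight / descending-singular-value).
wsvt_objective <- function(X, Y, w, tau) {
  0.5 * sum((X - Y)^2) + tau * sum(sort(w) * svd(X, nu = 0, nv = 0)$d)
}

fixture_tables <- function() mri_sequence_tables()

# strip image_matrix attributes down to a plain numeric matrix
as_plain <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

# small solver config for fast unit tests
fast_config <- function(...) solver_config(max_iter = 200L, ...)
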