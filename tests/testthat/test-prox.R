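test_that("weighted_svt matches closed forms and conventions", {
  # equal weights reduce to plain singular-value soft-thresholding
  expect_equal(weighted_svt(diag(c(5, 1)), weights = c(1, 1), tau = 2),
               diag(c(3, 0)), tolerance = 1e-12)
  # zero weights: identity
  Y <- seeded_matrix(3, 3, seed = 11)
  expect_equal(weighted_svt(Y, weights = 0, tau = 1), Y, tolerance = 1e-12)
  # scalar weight recycling
  expect_equal(weighted_svt(Y, weights = 0.5, tau = 1),
               weighted_svt(Y, weights = rep(0.5, 3), tau = 1))
  # shrunk spectrum stays non-negative and non-ascending
  w <- c(0.2, 1, 4)
  d <- svd(weighted_svt(Y, w, tau = 0.7))$d
  expect_true(all(d >= 0))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("weighted_svt agrees with the per-singular-value brute-force oracle", {
  # the spec'd seeded 3x3 instance with inverse-magnitude weights
  Y <- seeded_matrix(3, 3, seed = 3)
  sig <- svd(Y)$d
  w <- 1 / (sig + 0.01)
  X <- weighted_svt(Y, w, tau = 0.5)
  d_star <- per_sigma_oracle(sig, sort(w), 0.5)
  sv <- svd(Y)
  X_star <- sv$u %*% (d_star * t(sv$v))
  expect_lte(wsvt_objective(X, Y, w, 0.5) - wsvt_objective(X_star, Y, w, 0.5),
             1e-6)
  expect_equal(X, X_star, tolerance = 1e-6)
})

test_that("weighted_svt rejects bad input", {
  expect_error(weighted_svt(matrix(c(1, NA, 2, 3), 2), 1, 1), "non-finite")
  expect_error(weighted_svt(matrix(numeric(0), 0, 0), 1, 1), "empty")
  expect_error(weighted_svt(diag(2), c(1, 2, 3), 1), "one entry per")
  expect_error(weighted_svt(diag(2), c(-1, 1), 1), "non-negative")
  expect_error(weighted_svt(diag(2), 1, tau = 0), "positive")
})

test_that("weighted_soft_threshold is the entrywise weighted L1 prox", {
  expect_equal(weighted_soft_threshold(matrix(5), 1, 2), matrix(3))
  expect_equal(weighted_soft_threshold(matrix(-1.5), 1, 2), matrix(0))
  # seeded 4x4 against the scalar brute-force oracle
  Y <- seeded_matrix(4, 4, seed = 21, sd = 2)
  W <- 1 / (abs(Y) + 0.1)
  X <- weighted_soft_threshold(Y, W, tau = 1)
  for (i in seq_along(Y)) {
    xs <- scalar_soft_oracle(Y[i], W[i])
    fx <- function(x) 0.5 * (x - Y[i])^2 + W[i] * abs(x)
    expect_lte(fx(X[i]) - fx(xs), 1e-8)
  }
  expect_error(weighted_soft_threshold(Y, -W, 1), "non-negative")
  expect_error(weighted_soft_threshold(Y, W[1:2, 1:2], 1), "conformable")
})

test_that("update_noise_term has the stated closed form", {
  R <- seeded_matrix(2, 2, seed = 5)
  expect_equal(update_noise_term(R, lambda2 = 0, mu = 3), R)
  expect_equal(update_noise_term(R, lambda2 = Inf, mu = 3),
               matrix(0, 2, 2))
  expect_equal(update_noise_term(matrix(1, 2, 2), lambda2 = 1, mu = 2),
               matrix(0.5, 2, 2))
  # generic mu/(mu + 2 lambda2) factor
  expect_equal(update_noise_term(R, 4, 2), (2 / 10) * R)
  expect_error(update_noise_term(R, lambda2 = 1, mu = 0), "positive")
})

test_that("update_weights implements inverse-magnitude reweighting", {
  d <- list(H = diag(c(10, 0)), S = matrix(0, 2, 2))
  w <- update_weights(d, c_weight = 1, epsilon = 0.1)
  expect_equal(w$w_H, c(1 / 10.1, 10), tolerance = 1e-12)
  expect_true(all(w$w_S == 10))
  expect_error(update_weights(d, epsilon = 0), "positive")
  # monotone: larger singular value => smaller weight
  H <- seeded_matrix(5, 5, seed = 8)
  w2 <- update_weights(list(H = H, S = H), c_weight = 3, epsilon = 0.2)
  expect_true(all(diff(w2$w_H) >= 0))   # sigma non-ascending -> w non-descending
  expect_true(all(w2$w_H > 0) && all(is.finite(w2$w_H)))
})
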