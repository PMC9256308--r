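test_that("zero input gives the zero fixed point immediately", {
  f <- solve_rlre(matrix(0, 8, 8))
  expect_true(f$converged)
  expect_lte(f$iterations, 2L)
  expect_equal(f$H, matrix(0, 8, 8))
  expect_equal(f$S, matrix(0, 8, 8))
  expect_equal(f$E, matrix(0, 8, 8))
})

test_that("strong rank-1 signal lands in H (explicit lambda config)", {
  u <- withr::with_seed(42, rnorm(50)); u <- u / sqrt(sum(u^2))
  v <- withr::with_seed(43, rnorm(50)); v <- v / sqrt(sum(v^2))
  D <- 100 * outer(u, v)
  f <- solve_rlre(D, solver_config(lambda1 = 1 / sqrt(50), lambda2 = 10))
  expect_true(f$converged)
  expect_lte(norm(f$H - D, "F") / norm(D, "F"), 0.05)
  expect_lte(norm(f$S, "F") / norm(D, "F"), 0.05)
})

test_that("unweighted RLRE with the noise term off reduces to RL", {
  D <- seeded_matrix(12, 12, seed = 7, sd = 40) + 100
  cfg <- solver_config(reweight = FALSE, lambda2 = Inf,
                       lambda1 = 1 / sqrt(12), max_iter = 1L)
  cfg_rl <- solver_config(lambda1 = 1 / sqrt(12), max_iter = 1L)
  a <- suppressWarnings(solve_rlre(D, cfg))
  b <- suppressWarnings(solve_rl(D, cfg_rl))
  expect_equal(a$H, b$H, tolerance = 1e-10)
  expect_equal(a$S, b$S, tolerance = 1e-10)
  expect_equal(a$E, b$E, tolerance = 1e-10)
  # and full runs coincide too
  a2 <- solve_rlre(D, solver_config(reweight = FALSE, lambda2 = Inf,
                                    lambda1 = 1 / sqrt(12)))
  b2 <- solve_rl(D)
  expect_equal(a2$H, b2$H, tolerance = 1e-10)
})

test_that("decomposition is feasible, deterministic, and warns on iteration cap", {
  ph <- make_phantom(phantom_spec(rows = 40, cols = 40, rank = 3,
                                  noise_sigma = 0, seed = 2))
  D <- add_gaussian_noise(ph$degraded, 10, seed = 12)
  f1 <- solve_rlre(D)
  f2 <- solve_rlre(D)
  expect_true(f1$converged)
  expect_lte(f1$residual, f1$config$tol)
  expect_identical(f1$H, f2$H)    # bit-identical rerun
  expect_identical(f1$S, f2$S)
  expect_identical(f1$E, f2$E)
  # reconstruction identity up to the feasibility gap
  gap <- norm(as_plain(D) - f1$H - f1$S - f1$E, "F") / norm(as_plain(D), "F")
  expect_lte(gap, f1$config$tol)
  # objective non-increasing across the last sweep (final-iterate weights)
  expect_lte(f1$objective_last_sweep[2],
             f1$objective_last_sweep[1] * (1 + 1e-8))
  expect_warning(f3 <- solve_rlre(D, solver_config(max_iter = 3L)),
                 "did not converge")
  expect_false(f3$converged)
})

test_that("H recovery beats the identity baseline on the synthetic family", {
  errs <- c(); base <- c()
  for (s in 1:3) {
    ph <- make_phantom(phantom_spec(rows = 50, cols = 50, rank = 3,
                                    sparse_fraction = 0.05,
                                    sparse_amplitude = 50,
                                    noise_sigma = 2, seed = s))
    D <- ph$degraded
    f <- solve_rlre(D)
    Hstar <- as_plain(ph$clean)
    errs <- c(errs, norm(f$H - Hstar, "F") / norm(Hstar, "F"))
    base <- c(base, norm(as_plain(D) - Hstar, "F") / norm(Hstar, "F"))
  }
  expect_true(all(errs < base))
  expect_lte(mean(errs), 0.10)
})

test_that("volumes are processed slice-wise", {
  ph1 <- make_phantom(phantom_spec(rows = 24, cols = 24, rank = 2, seed = 1,
                                   noise_sigma = 5))
  ph2 <- make_phantom(phantom_spec(rows = 24, cols = 24, rank = 2, seed = 2,
                                   noise_sigma = 5))
  vol <- array(c(as_plain(ph1$degraded), as_plain(ph2$degraded)),
               dim = c(24, 24, 2))
  res <- denoise_volume(vol, method = "rlre")
  expect_length(res, 2L)
  # independence: slice 1 result equals the 2-D solve of slice 1
  direct <- solve_rlre(vol[, , 1])
  expect_identical(res[[1]]$H, direct$H)
  expect_error(denoise_volume(matrix(0, 3, 3)), "3-D array")
})

test_that("solver_config validates its fields", {
  expect_error(solver_config(lambda1 = -1), "positive")
  expect_error(solver_config(rho = 1), "> 1")
  expect_error(solver_config(tol = 0), "positive")
  expect_error(solver_config(max_iter = 0), "positive integer")
  cfg <- solver_config(lambda2 = Inf)
  expect_identical(cfg$lambda2, Inf)
})
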