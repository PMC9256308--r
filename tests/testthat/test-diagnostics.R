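test_that("fixture tables reproduce every printed margin", {
  tabs <- fixture_tables()
  margins <- function(t) c(t$tp + t$fp, t$fn + t$tn,   # test-call rows
                           t$tp + t$fn, t$fp + t$tn)   # reference columns
  expect_identical(margins(tabs$plain), c(122L, 28L, 137L, 13L))
  expect_identical(margins(tabs$DWI), c(129L, 21L, 137L, 13L))
  expect_identical(margins(tabs$DCE), c(134L, 16L, 137L, 13L))
  expect_identical(vapply(tabs, function(t) t$tp + t$fp + t$fn + t$tn,
                          integer(1), USE.NAMES = FALSE), rep(150L, 3))
})

test_that("sensitivity/specificity/accuracy reproduce the printed values", {
  tabs <- fixture_tables()
  tol <- 0.005
  expect_equal(sensitivity(tabs$plain), 86.13, tolerance = tol / 86)
  expect_equal(specificity(tabs$plain), 69.23, tolerance = tol / 69)
  expect_equal(accuracy(tabs$plain), 84.67, tolerance = tol / 84)
  expect_equal(sensitivity(tabs$DWI), 91.97, tolerance = tol / 91)
  expect_equal(specificity(tabs$DWI), 76.92, tolerance = tol / 76)
  expect_equal(sensitivity(tabs$DCE), 97.08, tolerance = tol / 97)
  expect_equal(specificity(tabs$DCE), 92.31, tolerance = tol / 92)
  expect_equal(accuracy(tabs$DCE), 96.67, tolerance = tol / 96)
  # trivial edges
  expect_equal(sensitivity(contingency_table(5, 2, 0, 1)), 100)
  expect_equal(specificity(contingency_table(5, 0, 2, 3)), 100)
  expect_equal(accuracy(contingency_table(4, 0, 0, 6)), 100)
})

test_that("cohen_kappa is formula-true (and differs from the printed kappas)", {
  tabs <- fixture_tables()
  expect_equal(cohen_kappa(tabs$plain), 0.363703, tolerance = 5e-4 / 0.36)
  expect_equal(cohen_kappa(tabs$DWI), 0.538867, tolerance = 5e-4 / 0.54)
  expect_equal(cohen_kappa(tabs$DCE), 0.809354, tolerance = 5e-4 / 0.81)
  expect_equal(cohen_kappa(contingency_table(7, 0, 0, 5)), 1)
  expect_error(cohen_kappa(contingency_table(5, 0, 0, 0)), "degenerate")
  # kappa = 1 iff off-diagonals vanish
  expect_lt(cohen_kappa(contingency_table(7, 1, 0, 5)), 1)
})

test_that("kappa bands follow the stated cutoffs", {
  s <- accuracy_summary(fixture_tables()$DCE)
  expect_identical(s$kappa_band, "good")        # 0.809 >= 0.7
  expect_identical(accuracy_summary(fixture_tables()$DWI)$kappa_band,
                   "acceptable")                # 0.539 in [0.4, 0.7)
  expect_identical(accuracy_summary(fixture_tables()$plain)$kappa_band,
                   "poor")                      # 0.364 < 0.4
})

test_that("chi_square_compare matches hand computation and the stats oracle", {
  tabs <- fixture_tables()
  cc <- chi_square_compare(tabs$plain, tabs$DCE, "accuracy")
  expect_equal(cc$chi2, 12.76261, tolerance = 1e-5)   # 127/150 vs 145/150
  expect_lt(cc$p, 0.001)
  # generic Pearson oracle without continuity correction
  cs <- chi_square_compare(tabs$plain, tabs$DWI, "sensitivity")
  oracle <- stats::chisq.test(matrix(c(118, 19, 126, 11), 2, byrow = TRUE),
                              correct = FALSE)
  expect_equal(cs$chi2, unname(oracle$statistic), tolerance = 1e-8)
  expect_equal(cs$p, oracle$p.value, tolerance = 1e-8)
  # identical tables: no difference
  same <- chi_square_compare(tabs$plain, tabs$plain, "accuracy")
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # zero expected cell
  a <- contingency_table(5, 0, 0, 5)
  b <- contingency_table(4, 0, 0, 6)
  expect_error(chi_square_compare(a, b, "sensitivity"), "exact test")
})

test_that("mcnemar_compare implements the discordant-pair statistic", {
  m <- mcnemar_compare(15, 5)
  expect_equal(m$chi2, (15 - 5)^2 / 20)
  expect_equal(mcnemar_compare(15, 5, correct = TRUE)$chi2, 81 / 20)
})

test_that("accuracy_summary bundles the statistics and validates input", {
  tabs <- fixture_tables()
  s <- accuracy_summary(tabs$DWI)
  expect_equal(s$sensitivity, 91.97, tolerance = 1e-4)
  expect_equal(s$specificity, 76.92, tolerance = 1e-4)
  # the table-true DWI accuracy is 136/150, not the printed 91.33
  expect_equal(s$accuracy, 100 * 136 / 150, tolerance = 1e-10)
  expect_error(contingency_table(0, 0, 0, 0), "empty")
  expect_error(contingency_table(1.5, 0, 0, 1), "integer")
  # summary() dispatches to the same bundle
  expect_equal(summary(tabs$DWI)$kappa, s$kappa)
})

test_that("discrepancies with the printed report are surfaced, not hidden", {
  d <- diagnostic_discrepancies()
  flagged <- d[nzchar(d$note), ]
  # exactly the three kappas and the DWI accuracy are irreproducible
  expect_setequal(paste(flagged$sequence, flagged$statistic),
                  c("plain kappa", "DWI kappa", "DCE kappa", "DWI accuracy"))
  expect_true(all(grepl("not reproducible", flagged$note)))
  # everything else matches the printed values
  ok <- d[!nzchar(d$note), ]
  expect_true(all(abs(ok$computed - ok$printed) <= 0.005))
})

test_that("round_half_up rounds ties upward to 2 decimals", {
  expect_identical(rlre:::round_half_up(0.125), 0.13)
  expect_identical(rlre:::round_half_up(86.131386861, 2), 86.13)
  expect_identical(rlre:::round_half_up(-0.125), -0.13)
})
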