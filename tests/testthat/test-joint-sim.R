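test_that("coin pairing hits its exact limits and preserves marginals", {
  set.seed(11)
  tA <- sort(rexp(5000, 0.1)); tB <- sort(rweibull(5000, 1.4, 12))
  p1 <- correlate_pairs_coin(tA, tB, 1, seed = 1)
  expect_identical(p1$t_B, tB)            # nothing marked at rho = 1
  expect_equal(p1$achieved_rho, 1)
  pm1 <- correlate_pairs_coin(tA, tB, -1, seed = 2)
  expect_identical(pm1$t_B, rev(tB))      # exact flip at rho = -1
  expect_equal(pm1$achieved_rho, -1)
  p0 <- correlate_pairs_coin(tA, tB, 0, seed = 3)
  expect_lt(abs(p0$achieved_rho), 0.05)   # null within a few / sqrt(N)
  # marginal multisets invariant at every target
  for (rho in c(-0.8, -0.3, 0.25, 0.6)) {
    p <- correlate_pairs_coin(tA, tB, rho, seed = 4)
    expect_identical(sort(p$t_B), tB)
    expect_identical(p$t_A, tA)
  }
  expect_error(correlate_pairs_coin(rev(tA), tB, 0.5), "sorted")
  expect_error(correlate_pairs_coin(tA, tB[-1], 0.5), "equal length")
})

test_that("coin achieved correlation tracks the target linearly", {
  set.seed(12)
  tA <- sort(rexp(5000, 0.1)); tB <- sort(rweibull(5000, 1.4, 12))
  targets <- seq(-0.8, 0.8, by = 0.2)
  achieved <- vapply(seq_along(targets), function(i)
    correlate_pairs_coin(tA, tB, targets[i], seed = 100 + i)$achieved_rho,
    numeric(1))
  expect_gte(summary(lm(achieved ~ targets))$r.squared, 0.99)
})

test_that("window-swap pairing converges within tolerance, keeps marginals", {
  set.seed(13)
  tA <- sort(rexp(2000, 0.1)); tB <- sort(rweibull(2000, 1.4, 12))
  pw <- correlate_pairs_window(tA, tB, 1, seed = 1)
  expect_identical(pw$t_B, tB)            # immediate return at rho = 1
  p <- correlate_pairs_window(tA, tB, 0.5, tol = 0.01, seed = 2)
  expect_lte(abs(p$achieved_rho - 0.5), 0.01)
  expect_identical(sort(p$t_B), tB)
  pn <- correlate_pairs_window(tA, tB, -0.4, tol = 0.01, seed = 3)
  expect_lte(abs(pn$achieved_rho + 0.4), 0.015)  # flip preserves |rho| to tol
  # non-convergence surfaces the best-achieved value
  err <- tryCatch(
    correlate_pairs_window(tA, tB, 0.5, tol = 1e-6, seed = 4, max_iter = 2),
    error = function(e) e)
  expect_s3_class(err, "window_swap_no_convergence")
  expect_true(is.numeric(err$best_achieved))
})

test_that("simulated combination curves converge to the closed form", {
  armA <- hill_arm(10, 2, label = "A")
  armB <- hill_arm(14, 1.6, label = "B")
  SA <- armA$survival; SB <- armB$survival
  # comonotone maximum at rho = 1, Bliss form at rho = 0
  for (rho in c(1, 0, 0.5)) {
    sim <- simulate_combination_curve(armA, armB, rho, "coin",
                                      N = 1e4, seed = 21)
    expect_lt(max(abs(sim$survival - tcda_survival(SA, SB, rho))), 0.03)
  }
  # the two pairing methods agree with each other at matched rho
  sim_c <- simulate_combination_curve(armA, armB, 0.4, "coin",
                                      N = 1e4, seed = 22)
  sim_w <- simulate_combination_curve(armA, armB, 0.4, "window_swap",
                                      N = 1e4, seed = 23)
  expect_lt(max(abs(sim_c$survival - sim_w$survival)), 0.04)
})
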