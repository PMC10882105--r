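test_that("closed-form combination survival matches hand-computed values", {
  expect_equal(tcda_survival(0.8, 0.5, 0), 0.9)       # Bliss-form limit
  expect_equal(tcda_survival(0.8, 0.5, 1), 0.8)       # best single agent
  expect_equal(tcda_survival(0.8, 0.5, 0.5), 0.85)
  expect_equal(tcda_survival(0.8, 0.5, -1), 1.0)      # min(1, SA + SB)
  expect_equal(tcda_survival(0.8, 0.5, -0.5), 0.95)
  expect_error(tcda_survival(0.8, 0.5, 1.2), "\\[-1, 1\\]")
})

test_that("combination survival is monotone in rho, symmetric, above HSA", {
  set.seed(41)
  for (rep in 1:20) {
    SA <- runif(1); SB <- runif(1)
    rhos <- seq(-1, 1, by = 0.05)
    vals <- vapply(rhos, function(r) tcda_survival(SA, SB, r), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))            # non-increasing in rho
    expect_true(all(vals >= max(SA, SB) - 1e-12))    # never below best mono
    expect_equal(vals[rhos == 0], SA + SB - SA * SB)
    expect_equal(vals[rhos == 1], max(SA, SB))
    expect_equal(vals[rhos == -1], min(1, SA + SB))
    expect_equal(tcda_survival(SA, SB, 0.37), tcda_survival(SB, SA, 0.37))
  }
})

test_that("regridding interpolates linearly onto a regular grid", {
  st <- survival_table(c(0, 1), c(1, 0.5))
  rg <- regrid_survival(st, 0.5)
  expect_equal(rg$times, c(0, 0.5, 1))
  expect_equal(rg$survival, c(1, 0.75, 0.5))
  # idempotent at the same dt
  expect_equal(regrid_survival(rg, 0.5)$survival, rg$survival)
  # dt larger than the span cannot form a grid
  expect_error(regrid_survival(st, 2), "span")
  expect_error(regrid_survival(survival_table(3, 0.5), 0.5), "single-point")
})

test_that("common truncation cuts all curves at the shortest trial", {
  mk <- function(tmax) regrid_survival(
    survival_table(c(0, tmax), c(1, 0.2)), 0.5)
  cur <- common_truncate(list(mk(10), mk(12), mk(8)))
  expect_true(all(vapply(cur, function(c) max(c$times), numeric(1)) == 8))
  expect_equal(cur[[1]]$times, cur[[3]]$times)
  same <- common_truncate(list(mk(10), mk(10)))
  expect_equal(same[[1]]$survival, mk(10)$survival)
  expect_error(common_truncate(list(mk(10), regrid_survival(
    survival_table(c(0, 10), c(1, 0.2)), 0.25))), "different dt")
})

test_that("grid-search fit recovers an exactly tCDA-generated combination", {
  fit <- fit_tcda(exact_trial(0.5))
  expect_lt(abs(fit$rho_hat - 0.5), 1.5 / 199)   # nearest grid values
  expect_lt(fit$rmse, 1e-3)
  # negative correlations recovered through the other branch
  fitn <- fit_tcda(exact_trial(-0.6))
  expect_lt(abs(fitn$rho_hat + 0.6), 1.5 / 199)
  # prediction is on the observed grid and never below the best mono
  expect_equal(fit$predicted$times, fit$observed$times)
})

test_that("fit recovers the generating correlation of a simulated cohort", {
  s <- synth_spec(hill_A = hill_params(10, 2), hill_B = hill_params(14, 1.6),
                  rho_true = 0, n_units = 4000,
                  time_grid = seq(0, 60, 0.05), seed = 31)
  fit <- fit_tcda(gen_trialset(s))
  expect_lt(abs(fit$rho_hat), 0.1)
})

test_that("bootstrap CI is reproducible and covers the truth", {
  s <- synth_spec(hill_A = hill_params(10, 2), hill_B = hill_params(14, 1.6),
                  rho_true = 0.4, n_units = 400,
                  time_grid = seq(0, 60, 0.05), seed = 77)
  tr <- gen_trialset(s)
  ci1 <- bootstrap_rho_ci(tr, n_boot = 300, seed = 5)
  ci2 <- bootstrap_rho_ci(tr, n_boot = 300, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])

  tr$arm_A$n_patients <- NA_integer_
  expect_error(bootstrap_rho_ci(tr, 300, seed = 1), "n_patients")

  # coverage: the 95% interval should contain the generating correlation
  # in the vast majority of repetitions
  hits <- vapply(1:50, function(r) {
    s <- synth_spec(hill_A = hill_params(10, 2),
                    hill_B = hill_params(14, 1.6),
                    rho_true = 0.4, n_units = 400,
                    time_grid = seq(0, 60, 0.05), seed = 1000 + r)
    ci <- bootstrap_rho_ci(gen_trialset(s), n_boot = 500, seed = 2000 + r)
    ci[1] <= 0.4 && 0.4 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("KS goodness of fit separates shifted curves, not identical ones", {
  tr <- exact_trial(0.5)
  obs <- regrid_survival(tr$arm_AB, 0.05)
  expect_equal(gof_test_tcda(obs, obs, 200), 1)
  # uniform +5 month shift must be detected at n = 200
  sh <- survival_table(obs$times,
                       approx(obs$times + 5, obs$survival,
                              xout = obs$times, rule = 2)$y,
                       n_patients = 200)
  expect_lt(gof_test_tcda(obs, sh, 200), 0.01)
  expect_error(gof_test_tcda(obs, sh, 4), ">= 5")
  expect_error(gof_test_tcda(obs, regrid_survival(tr$arm_A, 0.1), 100),
               "identical time grid")
})

test_that("inverse-transform sampling reproduces the source curve", {
  arm <- hill_arm(5, 2)   # negligible censored mass beyond the grid
  x1 <- sample_survival_times(arm, 50, seed = 3)
  x2 <- sample_survival_times(arm, 50, seed = 3)
  expect_identical(x1, x2)
  big <- sample_survival_times(arm, 1e4, seed = 4)
  ks <- suppressWarnings(ks.test(big, function(t)
    1 - hill_viability(hill_params(5, 2), pmax(t, 0))))
  expect_lt(unname(ks$statistic), 0.03)
  # a curve ending at S = 0.4 parks exactly that mass at the last grid time
  short <- survival_table(seq(0, 10, 0.5),
                          c(seq(1, 0.4, length.out = 11), rep(0.4, 10)), 100)
  draws <- sample_survival_times(short, 2e4, seed = 5)
  expect_equal(mean(draws == 10), 0.4, tolerance = 0.02)
  expect_error(sample_survival_times(
    survival_table(c(0, 5), c(1, 1)), 10, seed = 1), "flat")
})

test_that("family-wise threshold is alpha over the number of tests", {
  expect_equal(corrected_threshold(0.05, 26), 0.05 / 26)
  expect_equal(round(corrected_threshold(0.05, 26), 4), 0.0019)
  expect_equal(round(corrected_threshold(0.05, 18), 3), 0.003)
  expect_equal(corrected_threshold(0.05, 1), 0.05)
  expect_error(corrected_threshold(1.2, 3), "alpha")
})
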