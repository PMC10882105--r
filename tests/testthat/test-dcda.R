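test_that("dose-space combination viability matches hand-computed values", {
  h <- hill_params(1, 1)
  expect_equal(dcda_viability(h, h, 1, 1, 0), 0.25)        # Bliss
  expect_equal(dcda_viability(h, h, 1, 1, 1), 1 / 3)       # sham V(DA + DB)
  expect_equal(dcda_viability(h, h, 1, 1, 0.5), 0.5 * 0.25 + 0.5 / 3)
  # Frechet lower bound: VA = 0.5 at D = 1, VB = 0.4 at D = 1.5
  expect_equal(dcda_viability(h, h, 1, 1.5, -1), 0)
  expect_error(dcda_viability(h, h, 1, 1, 2), "\\[-1, 1\\]")
})

test_that("model invariants: HSA envelope, dose monotonicity, sham, limits", {
  set.seed(61)
  for (rep in 1:15) {
    hA <- hill_params(runif(1, 0.5, 3), runif(1, 0.8, 3))
    hB <- hill_params(runif(1, 0.5, 3), runif(1, 0.8, 3))
    DA <- runif(1, 0, 5); DB <- runif(1, 0, 5)
    VA <- hill_viability(hA, DA); VB <- hill_viability(hB, DB)
    for (rho in c(-1, -0.4, 0, 0.3, 0.7, 1)) {
      v <- dcda_viability(hA, hB, DA, DB, rho)
      expect_lte(v, min(VA, VB) + 1e-12)          # below the HSA envelope
      expect_gte(v, -1e-12)
      # non-increasing in each dose
      expect_lte(dcda_viability(hA, hB, DA * 1.3, DB, rho), v + 1e-12)
      expect_lte(dcda_viability(hA, hB, DA, DB * 1.3, rho), v + 1e-12)
    }
    # exact limits
    expect_equal(dcda_viability(hA, hB, DA, DB, 0), VA * VB)
    expect_equal(dcda_viability(hA, hB, DA, DB, -1), max(0, VA + VB - 1))
    # continuity in rho at 0
    expect_equal(dcda_viability(hA, hB, DA, DB, 1e-9),
                 dcda_viability(hA, hB, DA, DB, -1e-9), tolerance = 1e-6)
    # sham compliance: same drug at rho = 1 adds doses
    expect_equal(dcda_viability(hA, hA, DA, DB, 1),
                 hill_viability(hA, DA + DB), tolerance = 1e-12)
  }
})

test_that("grid search recovers the correlation of an exact dCDA matrix", {
  fit <- fit_dcda(exact_matrix(0.3))
  expect_lt(abs(fit$rho_hat - 0.3), 0.02)
  expect_lt(fit$rmse, 0.005)
  fitn <- fit_dcda(exact_matrix(-0.5))
  expect_lt(abs(fitn$rho_hat + 0.5), 0.03)
})

test_that("externally studentized residuals flag single corrupted cells", {
  set.seed(62)
  pred <- runif(36, 0.1, 0.9)
  obs <- pred + rnorm(36, 0, 0.01)
  expect_length(flag_outliers(obs, pred), 0)
  obs[17] <- obs[17] + 0.1                     # 10 sigma perturbation
  expect_identical(as.integer(flag_outliers(obs, pred)), 17L)
  expect_error(flag_outliers(obs, rep(0.5, 36)), "constant")
  expect_error(flag_outliers(obs[1:4], pred[1:4]), "at least 5")
})

test_that("paired t goodness of fit behaves at its boundary cases", {
  x <- seq(0.1, 0.9, length.out = 36)
  expect_equal(gof_paired_t(x, x), 1)
  set.seed(63)
  noisy <- x + rnorm(36, 0, 0.01)
  expect_lt(gof_paired_t(x + 0.1, noisy), 1e-6)   # constant offset detected
  expect_error(gof_paired_t(x + 0.1, x), "zero-variance")
  expect_error(gof_paired_t(x[1:2], x[1:2]), "length >= 3")
})

test_that("excess over CDA is a signed elementwise difference", {
  P <- matrix(c(0.5, 0.2, 0.8, 0.4), 2)
  O <- matrix(c(0.3, 0.2, 0.9, 0.1), 2)
  expect_equal(eocda(P, O), P - O)
  expect_equal(eocda(P, O)[1, 1], 0.2)       # synergy direction
  expect_equal(eocda(P, O), -eocda(O, P))
  expect_error(eocda(P, O[, 1, drop = FALSE]), "identical shape")
})

test_that("excess over Bliss is valid only when Bliss fits globally", {
  # independent lethal doses: Bliss is the true model, noise is random
  s0 <- synth_spec(rho_true = 0, n_units = 1e5, noise_sd = 0.01, seed = 64)
  expect_gt(eob_validity(gen_combination_matrix(s0)), 0.01)
  # strong correlation: Bliss misfits systematically
  s1 <- synth_spec(rho_true = 0.8, n_units = 1e4, noise_sd = 0.02, seed = 65)
  expect_lt(eob_validity(gen_combination_matrix(s1)), 0.01)
})

test_that("pipeline refits after outlier removal and recovers contamination", {
  s <- synth_spec(rho_true = 0.3, n_units = 1e5, noise_sd = 0.01, seed = 101)
  clean <- fit_dcda_pipeline(gen_combination_matrix(s))
  expect_equal(clean$rho_hat, clean$rho_hat_initial)  # nothing to remove
  expect_equal(nrow(clean$outliers), 0L)
  expect_gt(clean$gof_p, 0.01)
  # corrupt one cell of an exact matrix: it must be flagged as an outlier
  # and the refit stay near the generating correlation
  m <- exact_matrix(0.4)
  m$viability[3, 4] <- m$viability[3, 4] + 0.25
  dirty <- fit_dcda_pipeline(m)
  expect_true(any(dirty$outliers[, 1] == 3 & dirty$outliers[, 2] == 4))
  expect_lt(abs(dirty$rho_hat - 0.4), 0.05)
})

test_that("leave-one-out local flags isolate non-dCDA dose pairs", {
  s <- synth_spec(rho_true = 0.3, n_units = 1e5, noise_sd = 0.01, seed = 101)
  m <- gen_combination_matrix(s)
  fit <- fit_dcda_pipeline(m)
  expect_false(is.null(fit$local_flags))
  expect_true(all(fit$local_flags$flag == "consistent"))
  # a bump below the outlier cutoff but beyond the local z threshold
  m2 <- gen_combination_matrix(s)
  m2$viability[2, 2] <- max(0, m2$viability[2, 2] - 0.033)
  fit2 <- fit_dcda_pipeline(m2)
  expect_false(is.null(fit2$local_flags))
  flagged <- fit2$local_flags[
    fit2$local_flags$flag %in% c("synergistic", "antagonistic"), ]
  expect_gte(nrow(flagged), 1)
  expect_true(any(flagged$i == 2 & flagged$j == 2))
  expect_true(all(flagged$flag == "synergistic"))  # observed below model
})
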