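#' Specification for synthetic CDA data
#'
#' Bundles the ground-truth parameters used by the generators: the two
#' Hill-shaped marginals (dose-response curves for cell data, survival
#' curves with time in months for trial data), the true Spearman
#' correlation of the latent variables, the number of units (cells or
#' patients), the measurement noise, and the dose or time grid.
#'
#' Defaults emulate the study conditions the models were exercised under:
#' 6-point log-spaced dose grids spanning `k/4` to `4k` (a 6 x 6 viability
#' matrix per combination), Hill marginals `(k = 1, n = 2)` and
#' `(k = 2, n = 1.5)`, Gaussian viability noise of 0.02, and 10,000 cells;
#' for trial simulation a 0.05-month time grid reaching six median
#' survival times of the slower arm.
#'
#' @param hill_A,hill_B [hill_params()] marginals.
#' @param rho_true Ground-truth Spearman correlation in `[-1, 1]`.
#' @param n_units Number of simulated cells/patients (>= 10).
#' @param noise_sd Gaussian noise added to viability fractions (>= 0).
#' @param dose_grid_A,dose_grid_B Dose grids for matrix generation.
#' @param time_grid Time grid (months) for trial generation.
#' @param seed Integer seed driving all randomness of one generation.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(hill_A = hill_params(1, 2, "synthA"),
                       hill_B = hill_params(2, 1.5, "synthB"),
                       rho_true = 0, n_units = 10000L, noise_sd = 0.02,
                       dose_grid_A = hill_A$k * 2^seq(-2, 2, length.out = 6),
                       dose_grid_B = hill_B$k * 2^seq(-2, 2, length.out = 6),
                       time_grid = seq(0, 6 * max(hill_A$k, hill_B$k),
                                       by = 0.05),
                       seed = NULL) {
  stopifnot(inherits(hill_A, "hill_params"), inherits(hill_B, "hill_params"))
  if (abs(rho_true) > 1) stop("`rho_true` must be in [-1, 1]", call. = FALSE)
  if (n_units < 10L) stop("`n_units` must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(hill_A = hill_A, hill_B = hill_B, rho_true = rho_true,
                 n_units = as.integer(n_units), noise_sd = noise_sd,
                 dose_grid_A = dose_grid_A, dose_grid_B = dose_grid_B,
                 time_grid = time_grid, seed = seed),
            class = "synth_spec")
}

# Inverse-transform draw from the lethal-dose (or survival-time)
# distribution implied by a Hill curve: solving 1 - V(d) = u gives
# d = k (u / (1 - u))^(1/n) in closed form.
hill_quantile <- function(params, u) {
  params$k * (u / (1 - u))^(1 / params$n)
}

#' Generate paired lethal doses from the mixture joint distribution
#'
#' Draws per-cell lethal doses for two drugs under the mixture that makes
#' the dose-space CDA formula exact: each cell's `delta_A` comes from the
#' Hill-implied lethal-dose distribution; with probability `|rho_true|` the
#' cell lies on the matched-quantile curve `V_A(delta_A) = V_B(delta_B)`
#' (or the anti-matched curve `V_A(delta_A) + V_B(delta_B) = 1` for
#' negative correlation), otherwise `delta_B` is drawn independently. The
#' Spearman correlation of the output approaches `rho_true` as `n_units`
#' grows.
#'
#' @param spec A [synth_spec()].
#' @return List with numeric vectors `delta_A`, `delta_B`, logical
#'   `correlated` (which cells sit on the matched curve), and
#'   `achieved_rho`.
#' @export
gen_joint_lethal_doses <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  N <- spec$n_units
  uA <- stats::runif(N)
  dA <- hill_quantile(spec$hill_A, uA)
  correlated <- stats::runif(N) < abs(spec$rho_true)
  dB <- hill_quantile(spec$hill_B, stats::runif(N))  # independent draws
  if (spec$rho_true >= 0) {
    # matched quantiles: V_B(delta_B) = V_A(delta_A), i.e. same u
    dB[correlated] <- hill_quantile(spec$hill_B, uA[correlated])
  } else {
    # anti-matched: V_B(delta_B) = 1 - V_A(delta_A)
    dB[correlated] <- hill_quantile(spec$hill_B, 1 - uA[correlated])
  }
  list(delta_A = dA, delta_B = dB, correlated = correlated,
       achieved_rho = spearman(dA, dB))
}

#' Generate a combination viability matrix with known correlation
#'
#' Cell-counting simulation of a dose-combination screen. Lethal doses are
#' drawn by [gen_joint_lethal_doses()]; at each dose pair `(D_A, D_B)` a
#' cell survives when both its lethal doses exceed the applied doses --
#' for positive correlation, cells on the matched-quantile (correlated)
#' component face fully enhanced doses `D_A + g(D_B)` and `D_B + f(D_A)`;
#' for negative correlation no enhancement applies. Under this convention
#' the counting estimate converges to the closed-form [dcda_viability()]. Gaussian noise of `noise_sd` is added per cell of
#' the matrix and to the monotherapy vectors, and values are clipped to
#' `[0, 1.5]`.
#'
#' @param spec A [synth_spec()].
#' @return A [dose_matrix()] with explicit monotherapy vectors.
#' @export
gen_combination_matrix <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  draws <- gen_joint_lethal_doses(spec)   # seeds the generator via spec$seed
  dA <- draws$delta_A; dB <- draws$delta_B; corr <- draws$correlated
  gA <- spec$dose_grid_A; gB <- spec$dose_grid_B
  N <- spec$n_units
  # dose enhancement acts only on the matched-quantile component and only
  # for positive correlation (no enhancement at rho <= 0)
  if (spec$rho_true >= 0) {
    enh_A <- outer(gA, equivalent_dose(spec$hill_B, spec$hill_A, gB), `+`)
    enh_B <- outer(equivalent_dose(spec$hill_A, spec$hill_B, gA), gB, `+`)
  } else {
    enh_A <- outer(gA, rep(0, length(gB)), `+`)
    enh_B <- outer(rep(0, length(gA)), gB, `+`)
  }
  viab <- matrix(0, length(gA), length(gB))
  for (i in seq_along(gA)) {
    for (j in seq_along(gB)) {
      alive_ind <- !corr & dA > gA[i] & dB > gB[j]
      alive_cor <- corr & dA > enh_A[i, j] & dB > enh_B[i, j]
      viab[i, j] <- (sum(alive_ind) + sum(alive_cor)) / N
    }
  }
  mono_A <- vapply(gA, function(D) mean(dA > D), numeric(1L))
  mono_B <- vapply(gB, function(D) mean(dB > D), numeric(1L))
  if (spec$noise_sd > 0) {
    viab <- viab + stats::rnorm(length(viab), sd = spec$noise_sd)
    mono_A <- mono_A + stats::rnorm(length(mono_A), sd = spec$noise_sd)
    mono_B <- mono_B + stats::rnorm(length(mono_B), sd = spec$noise_sd)
  }
  clip <- function(x) pmin(pmax(x, 0), 1.5)
  dose_matrix(gA, gB, clip(viab),
              mono_A = clip(mono_A), mono_B = clip(mono_B),
              combination_id = paste0("synthetic rho=", spec$rho_true))
}

#' Generate a synthetic combination trial with known correlation
#'
#' Builds the three arms of a trial: the monotherapy survival curves are
#' the Hill-shaped forms (time playing the role of dose) evaluated on the
#' time grid, and the combination arm is simulated by sampling `n_units`
#' patient survival times per monotherapy from the closed-form inverse,
#' pairing them at `rho_true` with the chosen method, and taking each
#' patient's maximum.
#'
#' @param spec A [synth_spec()].
#' @param method Pairing method, `"coin"` (default) or `"window_swap"`.
#' @return A [trial_set()] with `n_patients = n_units` on every arm.
#' @export
gen_trialset <- function(spec, method = c("coin", "window_swap")) {
  stopifnot(inherits(spec, "synth_spec"))
  method <- match.arg(method)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  grid <- spec$time_grid
  if (grid[1L] != 0) stop("`time_grid` must start at 0", call. = FALSE)
  N <- spec$n_units
  SA <- hill_viability(spec$hill_A, grid)
  SB <- hill_viability(spec$hill_B, grid)
  tA <- sort(hill_quantile(spec$hill_A, stats::runif(N)))
  tB <- sort(hill_quantile(spec$hill_B, stats::runif(N)))
  pair <- if (method == "coin") correlate_pairs_coin(tA, tB, spec$rho_true)
          else correlate_pairs_window(tA, tB, spec$rho_true)
  SAB <- empirical_survival(grid, pmax(pair$t_A, pair$t_B))
  trial_set(
    survival_table(grid, SA, n_patients = N, label = "synthetic arm A"),
    survival_table(grid, SB, n_patients = N, label = "synthetic arm B"),
    survival_table(grid, SAB, n_patients = N, label = "synthetic arm AB"),
    combination_id = paste0("synthetic rho=", spec$rho_true))
}
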