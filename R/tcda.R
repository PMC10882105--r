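#' Combination survival under the temporal correlated drug action model
#'
#' Closed-form survival of a two-drug combination given the monotherapy
#' survival fractions at the same time and the Spearman correlation `rho`
#' of the latent per-patient survival times. Writing
#' `Smax = max(SA, SB)`, `Smin = min(SA, SB)` and `a = |rho|`:
#' \deqn{S_{AB} = S_{max} + S_{min}(1 - S_{max})(1 - a)}{SAB = Smax + Smin (1-Smax) (1-a)}
#' for `rho >= 0`, and
#' \deqn{S_{AB} = (S_A + S_B - S_A S_B)(1 - a) + \min(1, S_A + S_B)\,a}{SAB = (SA+SB-SA*SB)(1-a) + min(1, SA+SB) a}
#' for `rho < 0`. At `rho = 0` this is the Bliss-form independence limit,
#' at `rho = 1` the better monotherapy (`Smax`), and at `rho = -1` the
#' anti-correlated bound `min(1, SA + SB)`. All arguments are vectorized
#' over a shared time grid.
#'
#' @param SA,SB Monotherapy survival fractions in `[0, 1]`.
#' @param rho Spearman correlation in `[-1, 1]` (scalar).
#' @return Combination survival fraction(s), always `>= pmax(SA, SB)`.
#' @examples
#' tcda_survival(0.8, 0.5, 0)     # 0.9, Bliss-form limit
#' tcda_survival(0.8, 0.5, 1)     # 0.8, best single agent
#' tcda_survival(0.8, 0.5, -1)    # 1.0, anti-correlated bound
#' @export
tcda_survival <- function(SA, SB, rho) {
  if (length(rho) != 1L || is.na(rho) || rho < -1 || rho > 1)
    stop("`rho` must be a single value in [-1, 1]", call. = FALSE)
  if (any(SA < 0 | SA > 1, na.rm = TRUE) || any(SB < 0 | SB > 1, na.rm = TRUE))
    stop("survival fractions must lie in [0, 1]", call. = FALSE)
  a <- abs(rho)
  if (rho >= 0) {
    smax <- pmax(SA, SB); smin <- pmin(SA, SB)
    smax + smin * (1 - smax) * (1 - a)
  } else {
    (SA + SB - SA * SB) * (1 - a) + pmin(1, SA + SB) * a
  }
}

#' Interpolate a survival curve onto a regular time grid
#'
#' Linear interpolation onto the grid `0, dt, 2 dt, ...` up to the curve's
#' maximum observed time. Times before the first observed point carry the
#' first observed survival value.
#'
#' @param curve A [survival_table()].
#' @param dt Grid spacing in months (default 0.05).
#' @return A [survival_table()] on the regular grid.
#' @export
regrid_survival <- function(curve, dt = 0.05) {
  stopifnot(inherits(curve, "survival_table"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (length(curve$times) < 2L)
    stop("cannot interpolate a single-point curve", call. = FALSE)
  tmax <- max(curve$times)
  grid <- seq(0, tmax, by = dt)
  if (length(grid) < 2L)
    stop("`dt` (", dt, ") exceeds the curve's time span (", tmax, ")",
         call. = FALSE)
  s <- stats::approx(curve$times, curve$survival, xout = grid,
                     method = "linear", rule = 2)$y
  survival_table(grid, s, n_patients = curve$n_patients, label = curve$label)
}

#' Truncate gridded survival curves to their common time span
#'
#' Finds the minimum over curves of the maximum observed time and drops all
#' grid points beyond it, so that every returned curve lives on the same
#' grid. Curves must already be on regular grids with the same spacing.
#'
#' @param curves List of gridded [survival_table()]s (>= 2).
#' @return List of truncated curves on identical grids.
#' @export
common_truncate <- function(curves) {
  if (!is.list(curves) || length(curves) < 2L)
    stop("need at least two curves", call. = FALSE)
  for (c in curves) stopifnot(inherits(c, "survival_table"))
  dts <- vapply(curves, function(c) {
    d <- diff(c$times)
    if (length(d) == 0L || max(abs(d - d[1L])) > 1e-8 * d[1L])
      stop("curves must be on regular grids (use regrid_survival)",
           call. = FALSE)
    d[1L]
  }, numeric(1L))
  if (max(dts) - min(dts) > 1e-8 * min(dts))
    stop("curves are gridded at different dt", call. = FALSE)
  tstar <- min(vapply(curves, function(c) max(c$times), numeric(1L)))
  if (tstar <= 0) stop("a curve has zero time span", call. = FALSE)
  lapply(curves, function(c) {
    keep <- c$times <= tstar + 1e-9
    if (sum(keep) < 2L) stop("degenerate truncation", call. = FALSE)
    survival_table(c$times[keep], c$survival[keep],
                   n_patients = c$n_patients, label = c$label)
  })
}

# RMSE of the tCDA prediction against the observed combination for every
# candidate rho at once. For fixed arms the prediction is affine in
# a = |rho| within each sign branch, so rmse^2(a) is a quadratic whose three
# coefficients are single dot products -- this makes the 200-point grid
# search (and the bootstrap that repeats it thousands of times) cheap.
tcda_rmse_profile <- function(SA, SB, SAB_obs, rho_grid) {
  bliss <- SA + SB - SA * SB
  smax <- pmax(SA, SB)
  mneg <- pmin(1, SA + SB)
  d <- bliss - SAB_obs
  epos <- smax - bliss
  eneg <- mneg - bliss
  n <- length(SA)
  a <- abs(rho_grid)
  mse <- ifelse(rho_grid >= 0,
    sum(d * d) / n + 2 * a * sum(d * epos) / n + a * a * sum(epos * epos) / n,
    sum(d * d) / n + 2 * a * sum(d * eneg) / n + a * a * sum(eneg * eneg) / n)
  sqrt(pmax(mse, 0))
}

# Argmin over the rho grid with ties broken toward the smallest |rho|
# (prefer the less-structured explanation); remaining ties toward +rho.
pick_rho <- function(rho_grid, rmse, tol = 1e-12) {
  cand <- which(rmse <= min(rmse) + tol)
  cand <- cand[order(abs(rho_grid[cand]), -rho_grid[cand])]
  rho_grid[cand[1L]]
}

#' Fit the temporal CDA model to a combination trial
#'
#' Regrids the three arms to a common `dt` grid, truncates them to their
#' shared time span, and grid-searches the Spearman correlation `rho` over
#' `grid_size` equally spaced candidates in `[-1, 1]`, choosing the value
#' minimizing the RMSE between the [tcda_survival()] prediction and the
#' observed combination curve. RMSE ties are broken toward the smallest
#' `|rho|`.
#'
#' @param trial A [trial_set()].
#' @param grid_size Number of candidate correlations (default 200).
#' @param dt Time grid spacing in months (default 0.05).
#' @return An object of class `tcda_fit` with elements `rho_hat`,
#'   `alpha_of_rho` (`= |rho_hat|`), `rmse`, `predicted` (a
#'   [survival_table()] on the common grid), `observed`, `gof_p`
#'   (Kolmogorov-Smirnov, when the combination cohort size is known), `ci`
#'   (`NA` until [bootstrap_rho_ci()] is run), `rho_grid`, `rmse_profile`,
#'   `time_grid_dt`.
#' @export
fit_tcda <- function(trial, grid_size = 200L, dt = 0.05) {
  stopifnot(inherits(trial, "trial_set"))
  if (grid_size < 3L) stop("`grid_size` must be >= 3", call. = FALSE)
  arms <- common_truncate(list(
    regrid_survival(trial$arm_A, dt),
    regrid_survival(trial$arm_B, dt),
    regrid_survival(trial$arm_AB, dt)))
  SA <- arms[[1L]]$survival; SB <- arms[[2L]]$survival
  obs <- arms[[3L]]
  if (length(SA) < 3L) stop("degenerate truncation: < 3 grid points",
                            call. = FALSE)
  rho_grid <- seq(-1, 1, length.out = grid_size)
  rmse <- tcda_rmse_profile(SA, SB, obs$survival, rho_grid)
  rho_hat <- pick_rho(rho_grid, rmse)
  pred <- survival_table(obs$times, tcda_survival(SA, SB, rho_hat),
                         n_patients = obs$n_patients,
                         label = paste0("tCDA prediction (rho=",
                                        signif(rho_hat, 3), ")"))
  gof_p <- if (!is.na(obs$n_patients) && obs$n_patients >= 5)
    gof_test_tcda(pred, obs, obs$n_patients) else NA_real_
  structure(
    list(rho_hat = rho_hat, alpha_of_rho = abs(rho_hat),
         rmse = rmse[which(rho_grid == rho_hat)][1L],
         predicted = pred, observed = obs,
         ci = c(NA_real_, NA_real_), gof_p = gof_p,
         rho_grid = rho_grid, rmse_profile = rmse,
         time_grid_dt = dt, grid_size = as.integer(grid_size),
         combination_id = trial$combination_id,
         arms = arms),
    class = "tcda_fit")
}

# Inverse-transform sample of survival times from a gridded curve:
# u ~ U(0,1) maps to the smallest grid time t with 1 - S(t) >= u; u beyond
# the total observed event fraction maps to the last grid time (the curve
# is treated as right-censored at truncation).
step_inverse_times <- function(curve, u) {
  FF <- 1 - curve$survival
  idx <- findInterval(u, FF, left.open = TRUE) + 1L
  idx[idx > length(FF)] <- length(FF)
  curve$times[idx]
}

# Empirical survival of sampled times on a grid. Samples sitting exactly at
# the last grid time are censored mass (the step inverse parks them there),
# so they count as surviving through it; otherwise S(t) = mean(times > t).
empirical_survival <- function(grid, times) {
  times <- sort(times)
  s <- 1 - findInterval(grid, times) / length(times)
  G <- length(grid)
  s[G] <- mean(times >= grid[G])
  s
}

#' Sample survival times from an empirical survival curve
#'
#' Inverse-transform sampling through the step-inverse of the cumulative
#' distribution `1 - S(t)`: each uniform draw maps to the smallest grid
#' time whose cumulative event fraction reaches it; draws beyond the total
#' observed event fraction map to the last grid time (right-censoring at
#' truncation).
#'
#' @param curve A gridded [survival_table()].
#' @param N Number of draws (>= 2).
#' @param seed Optional integer seed.
#' @return Numeric vector of `N` survival times (months).
#' @export
sample_survival_times <- function(curve, N, seed = NULL) {
  stopifnot(inherits(curve, "survival_table"))
  if (N < 2L) stop("`N` must be >= 2", call. = FALSE)
  if (all(curve$survival >= 1))
    stop("curve is flat at 1: no events to sample", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  step_inverse_times(curve, stats::runif(N))
}

#' Bootstrap confidence interval for the tCDA correlation
#'
#' For each replicate, survival times are resampled by inverse transform
#' from each arm's fitted-grid curve with that arm's cohort size, empirical
#' survival curves are rebuilt on the same grid, and `rho` is refitted by
#' the same grid search. Returns the 2.5% and 97.5% quantiles of the
#' replicate estimates.
#'
#' @param trial A [trial_set()]; every arm must carry `n_patients`.
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Integer seed.
#' @param grid_size,dt Passed to the refits (defaults as in [fit_tcda()]).
#' @return Numeric `c(low, high)` 95% interval, with attribute `"rho_boot"`
#'   holding the replicate estimates.
#' @export
bootstrap_rho_ci <- function(trial, n_boot = 5000L, seed = NULL,
                             grid_size = 200L, dt = 0.05) {
  stopifnot(inherits(trial, "trial_set"))
  if (n_boot < 100L) stop("`n_boot` must be >= 100", call. = FALSE)
  ns <- c(trial$arm_A$n_patients, trial$arm_B$n_patients,
          trial$arm_AB$n_patients)
  if (anyNA(ns))
    stop("all arms need `n_patients` for the bootstrap", call. = FALSE)
  arms <- common_truncate(list(
    regrid_survival(trial$arm_A, dt),
    regrid_survival(trial$arm_B, dt),
    regrid_survival(trial$arm_AB, dt)))
  grid <- arms[[1L]]$times
  rho_grid <- seq(-1, 1, length.out = grid_size)
  if (!is.null(seed)) set.seed(seed)
  rho_boot <- vapply(seq_len(n_boot), function(b) {
    S <- lapply(1:3, function(k)
      empirical_survival(grid, step_inverse_times(arms[[k]],
                                                  stats::runif(ns[k]))))
    rmse <- tcda_rmse_profile(S[[1L]], S[[2L]], S[[3L]], rho_grid)
    pick_rho(rho_grid, rmse)
  }, numeric(1L))
  ci <- unname(stats::quantile(rho_boot, c(0.025, 0.975), type = 7))
  attr(ci, "rho_boot") <- rho_boot
  ci
}

#' Goodness of fit of a tCDA prediction (Kolmogorov-Smirnov)
#'
#' Compares the implied event-time distributions of the predicted and
#' observed combination curves with a two-sample Kolmogorov-Smirnov test.
#' Each curve is represented by `n_AB` deterministic quantile samples
#' (`u = (i - 0.5) / n_AB` through the step-inverse), making the p-value a
#' deterministic function of the inputs.
#'
#' @param predicted,observed Gridded [survival_table()]s on the same grid.
#' @param n_AB Combination-arm cohort size (>= 5).
#' @return Two-sided KS p-value.
#' @export
gof_test_tcda <- function(predicted, observed, n_AB) {
  stopifnot(inherits(predicted, "survival_table"),
            inherits(observed, "survival_table"))
  if (n_AB < 5L) stop("`n_AB` must be >= 5", call. = FALSE)
  if (length(predicted$times) != length(observed$times) ||
      max(abs(predicted$times - observed$times)) > 1e-9)
    stop("curves must share an identical time grid", call. = FALSE)
  u <- (seq_len(n_AB) - 0.5) / n_AB
  tp <- step_inverse_times(predicted, u)
  to <- step_inverse_times(observed, u)
  if (identical(tp, to)) return(1)
  suppressWarnings(stats::ks.test(tp, to)$p.value)
}

#' Family-wise corrected significance threshold
#'
#' Single corrected threshold `alpha / m` applied when `m` combinations are
#' tested in one screen.
#'
#' @param alpha Per-test significance level in `(0, 1)`.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' corrected_threshold(0.05, 26)   # 0.00192...
#' @export
corrected_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (m < 1 || m != round(m)) stop("`m` must be a positive integer",
                                   call. = FALSE)
  alpha / m
}

#' @export
print.tcda_fit <- function(x, ...) {
  cat("tCDA fit", if (nzchar(x$combination_id)) x$combination_id, "\n")
  cat("  rho_hat =", signif(x$rho_hat, 4),
      " (alpha = |rho| =", signif(x$alpha_of_rho, 4), ")\n")
  cat("  RMSE =", signif(x$rmse, 4),
      " over", length(x$predicted$times), "grid points (dt =",
      x$time_grid_dt, "months)\n")
  if (!anyNA(x$ci))
    cat("  95% bootstrap CI: [", signif(x$ci[1L], 3), ",",
        signif(x$ci[2L], 3), "]\n")
  if (!is.na(x$gof_p))
    cat("  KS goodness-of-fit p =", signif(x$gof_p, 3), "\n")
  invisible(x)
}
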