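#' Combination viability under the dose-space correlated drug action model
#'
#' Closed-form combination viability given the two monotherapy Hill curves,
#' the doses, and the Spearman correlation `rho` of the latent per-cell
#' lethal doses. With `a = |rho|`, equivalent-dose functions
#' `f(DA) = kB (DA/kA)^(nA/nB)` and `g(DB) = kA (DB/kB)^(nB/nA)`:
#' \deqn{V_{AB} = (1-a) V_A(D_A) V_B(D_B) + a \min\{V_A(D_A + g(D_B)), V_B(D_B + f(D_A))\}}
#' for `rho >= 0` (the sham-compliant highest-single-agent limit at
#' `rho = 1`, evaluated at enhanced doses), and
#' \deqn{V_{AB} = (1-a) V_A V_B + a \max(0, V_A + V_B - 1)}
#' for `rho < 0` (the Frechet lower bound at `rho = -1`). `rho = 0` is
#' exactly Bliss independence `V_A V_B`.
#'
#' @param hill_A,hill_B [hill_params()] of the two monotherapies.
#' @param DA,DB Doses (vectorized; recycled together).
#' @param rho Spearman correlation in `[-1, 1]` (scalar).
#' @return Combination viability fraction(s) in `[0, 1]`.
#' @examples
#' h <- hill_params(1, 1)
#' dcda_viability(h, h, 1, 1, 0)    # 0.25, Bliss
#' dcda_viability(h, h, 1, 1, 1)    # 1/3, sham: V(D_A + D_B)
#' @export
dcda_viability <- function(hill_A, hill_B, DA, DB, rho) {
  if (length(rho) != 1L || is.na(rho) || rho < -1 || rho > 1)
    stop("`rho` must be a single value in [-1, 1]", call. = FALSE)
  a <- abs(rho)
  VA <- hill_viability(hill_A, DA)
  VB <- hill_viability(hill_B, DB)
  if (rho >= 0) {
    enhA <- hill_viability(hill_A, DA + equivalent_dose(hill_B, hill_A, DB))
    enhB <- hill_viability(hill_B, DB + equivalent_dose(hill_A, hill_B, DA))
    (1 - a) * VA * VB + a * pmin(enhA, enhB)
  } else {
    (1 - a) * VA * VB + a * pmax(0, VA + VB - 1)
  }
}

# Predicted combination matrix over the full dose grid for one rho, using
# branch matrices precomputed by dcda_components (the prediction is affine
# in |rho| within each sign branch).
dcda_components <- function(hill_A, hill_B, doses_A, doses_B) {
  VA <- hill_viability(hill_A, doses_A)
  VB <- hill_viability(hill_B, doses_B)
  bliss <- outer(VA, VB)
  enhA <- outer(doses_A, equivalent_dose(hill_B, hill_A, doses_B), `+`)
  enhB <- outer(equivalent_dose(hill_A, hill_B, doses_A), doses_B, `+`)
  hsa <- pmin(hill_viability(hill_A, enhA), hill_viability(hill_B, enhB))
  frechet <- pmax(0, outer(VA, VB, `+`) - 1)
  list(bliss = bliss, hsa = hsa, frechet = frechet)
}

dcda_predict <- function(comp, rho) {
  a <- abs(rho)
  if (rho >= 0) (1 - a) * comp$bliss + a * comp$hsa
  else          (1 - a) * comp$bliss + a * comp$frechet
}

#' Grid-search fit of the dose-space CDA correlation
#'
#' Fits Hill curves to the two monotherapy vectors of a [dose_matrix()]
#' (unless pre-fitted parameters are supplied), then evaluates the
#' [dcda_viability()] prediction over `grid_size` equally spaced candidate
#' correlations in `[-1, 1]` and returns the candidate minimizing the RMSE
#' against the observed combination matrix over all non-excluded cells.
#' RMSE ties are broken toward the smallest `|rho|`.
#'
#' @param matrix A [dose_matrix()].
#' @param grid_size Number of candidate correlations (default 200).
#' @param exclude Integer matrix or data frame of `(i, j)` cell indices to
#'   leave out (e.g. flagged outliers); may be empty.
#' @param hill_A,hill_B Optional pre-fitted [hill_params()]; fitted from
#'   the monotherapy vectors when `NULL`.
#' @return List with `rho_hat`, `rmse`, `predicted` (full matrix at
#'   `rho_hat`), `hill_A`, `hill_B`, `rho_grid`, `rmse_profile`.
#' @export
fit_dcda <- function(matrix, grid_size = 200L, exclude = NULL,
                     hill_A = NULL, hill_B = NULL) {
  stopifnot(inherits(matrix, "dose_matrix"))
  if (grid_size < 3L) stop("`grid_size` must be >= 3", call. = FALSE)
  if (is.null(hill_A))
    hill_A <- fit_hill(matrix$doses_A, matrix$mono_A, drug_label = "A")
  if (is.null(hill_B))
    hill_B <- fit_hill(matrix$doses_B, matrix$mono_B, drug_label = "B")
  comp <- dcda_components(hill_A, hill_B, matrix$doses_A, matrix$doses_B)
  obs <- matrix$viability
  keep <- !exclusion_mask(exclude, dim(obs))
  rho_grid <- seq(-1, 1, length.out = grid_size)
  rmse <- vapply(rho_grid, function(r) {
    pred <- dcda_predict(comp, r)
    sqrt(mean((pred[keep] - obs[keep])^2))
  }, numeric(1L))
  rho_hat <- pick_rho(rho_grid, rmse)
  list(rho_hat = rho_hat,
       rmse = rmse[which(rho_grid == rho_hat)][1L],
       predicted = dcda_predict(comp, rho_hat),
       hill_A = hill_A, hill_B = hill_B,
       rho_grid = rho_grid, rmse_profile = rmse)
}

exclusion_mask <- function(exclude, dims) {
  mask <- array(FALSE, dim = dims)
  if (!is.null(exclude) && NROW(exclude) > 0L) {
    ex <- as.matrix(exclude)[, 1:2, drop = FALSE]
    storage.mode(ex) <- "integer"
    mask[ex] <- TRUE
  }
  mask
}

#' Flag outlier cells by externally studentized residuals
#'
#' Regresses observed on predicted viabilities (one covariate plus
#' intercept) and computes externally studentized residuals, which under
#' the model follow a t-distribution with `n - 3` degrees of freedom. A
#' cell is flagged when its absolute residual exceeds the two-sided
#' Bonferroni outlier cutoff `qt(1 - 0.05 / (2 n), df = n - 3)`.
#'
#' @param observed,predicted Paired numeric vectors (length >= 5).
#' @return Integer vector of flagged positions (possibly empty), with
#'   attribute `"cutoff"`.
#' @export
flag_outliers <- function(observed, predicted) {
  n <- length(observed)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)
  if (length(predicted) != n)
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  if (stats::sd(predicted) == 0)
    stop("predictor is constant; studentized residuals undefined",
         call. = FALSE)
  fit <- stats::lm(observed ~ predicted)
  rs <- stats::rstudent(fit)
  cutoff <- stats::qt(1 - 0.05 / (2 * n), df = n - 3)
  idx <- which(is.finite(rs) & abs(rs) > cutoff)
  attr(idx, "cutoff") <- cutoff
  idx
}

#' Paired t-test goodness of fit
#'
#' Two-sided paired t-test on the differences `predicted - observed`; the
#' p-value quantifies evidence against the hypothesis that the model
#' estimate describes the observed combination.
#'
#' @param predicted,observed Paired numeric vectors (length >= 3).
#' @return Two-sided p-value; exactly 1 when all differences are zero.
#' @export
gof_paired_t <- function(predicted, observed) {
  n <- length(predicted)
  if (n < 3L || length(observed) != n)
    stop("need paired vectors of length >= 3", call. = FALSE)
  d <- predicted - observed
  if (stats::sd(d) <= 1e-12 * (1 + abs(mean(d)))) {
    if (all(abs(d) <= 1e-12)) return(1)
    stop("zero-variance non-zero differences: t statistic undefined",
         call. = FALSE)
  }
  stats::t.test(d)$p.value
}

#' Validity of the Excess-over-Bliss baseline
#'
#' Tests whether Bliss independence (the dose-space CDA model at
#' `rho = 0`, i.e. `V_A V_B` from the fitted Hill curves) is an adequate
#' null for the observed combination matrix, via a paired t-test. A
#' p-value above 0.01 supports using Excess over Bliss as a synergy
#' measure for this combination.
#'
#' @param matrix A [dose_matrix()].
#' @param hill_A,hill_B Optional pre-fitted [hill_params()].
#' @return Paired-t p-value.
#' @export
eob_validity <- function(matrix, hill_A = NULL, hill_B = NULL) {
  stopifnot(inherits(matrix, "dose_matrix"))
  if (is.null(hill_A))
    hill_A <- fit_hill(matrix$doses_A, matrix$mono_A, drug_label = "A")
  if (is.null(hill_B))
    hill_B <- fit_hill(matrix$doses_B, matrix$mono_B, drug_label = "B")
  bliss <- outer(hill_viability(hill_A, matrix$doses_A),
                 hill_viability(hill_B, matrix$doses_B))
  gof_paired_t(as.vector(bliss), as.vector(matrix$viability))
}

#' Excess over CDA
#'
#' Elementwise difference `predicted - observed` between the model
#' combination viability and the observed one. Positive values point
#' toward synergy (cells died more than correlated independent action
#' predicts), negative values toward antagonism.
#'
#' @param predicted,observed Matrices of identical shape.
#' @return Matrix of the same shape.
#' @export
eocda <- function(predicted, observed) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (!identical(dim(predicted), dim(observed)))
    stop("matrices must have identical shape", call. = FALSE)
  predicted - observed
}

#' Full dose-space CDA fitting pipeline
#'
#' Initial grid-search fit, outlier flagging on its predictions
#' ([flag_outliers()]), refit excluding flagged cells, and computation of
#' all summary statistics: paired-t goodness of fit and Excess-over-Bliss
#' validity (both on non-outlier cells), the Excess-over-CDA matrix, and
#' (when the global fit is acceptable at `local_alpha`) leave-one-out local
#' synergy/antagonism flags.
#'
#' @param matrix A [dose_matrix()].
#' @param grid_size Number of candidate correlations (default 200).
#' @param local_alpha Significance level gating and testing the local
#'   flags (default 0.01).
#' @return An object of class `dcda_fit` with elements `rho_hat`,
#'   `rho_hat_initial`, `rmse`, `predicted`, `outliers` (two-column matrix
#'   of cell indices), `gof_p`, `eob_p`, `eocda`, `local_flags`, `hill_A`,
#'   `hill_B`, `doses_A`, `doses_B`, `observed`.
#' @export
fit_dcda_pipeline <- function(matrix, grid_size = 200L, local_alpha = 0.01) {
  stopifnot(inherits(matrix, "dose_matrix"))
  init <- fit_dcda(matrix, grid_size)
  out_idx <- flag_outliers(as.vector(matrix$viability),
                           as.vector(init$predicted))
  dims <- dim(matrix$viability)
  outliers <- cbind(i = ((out_idx - 1L) %% dims[1L]) + 1L,
                    j = ((out_idx - 1L) %/% dims[1L]) + 1L)
  final <- fit_dcda(matrix, grid_size, exclude = outliers,
                    hill_A = init$hill_A, hill_B = init$hill_B)
  keep <- !exclusion_mask(outliers, dims)
  gof_p <- gof_paired_t(final$predicted[keep], matrix$viability[keep])
  eob_p <- eob_validity(matrix, init$hill_A, init$hill_B)
  fit <- structure(
    list(rho_hat = final$rho_hat, rho_hat_initial = init$rho_hat,
         rmse = final$rmse, predicted = final$predicted,
         outliers = outliers, gof_p = gof_p, eob_p = eob_p,
         eocda = eocda(final$predicted, matrix$viability),
         local_flags = NULL,
         hill_A = init$hill_A, hill_B = init$hill_B,
         doses_A = matrix$doses_A, doses_B = matrix$doses_B,
         observed = matrix$viability,
         grid_size = as.integer(grid_size),
         combination_id = matrix$combination_id),
    class = "dcda_fit")
  if (is.finite(gof_p) && gof_p > local_alpha)
    fit$local_flags <- local_dcda_flags(matrix, fit, alpha = local_alpha)
  fit
}

#' Locally synergistic or antagonistic dose pairs
#'
#' For a combination globally consistent with the dose-space CDA model,
#' identifies individual dose pairs that the model fails to describe.
#' Residuals (`estimate - observed`) over all non-outlier cells give a
#' normal MLE mean and standard deviation. Each cell in turn is held out,
#' the correlation is refitted without it, the held-out cell is predicted
#' under the refit, and its residual `r_i` is converted to the z-score
#' `(mu - r_i) / sigma` and a two-sided standard-normal p-value. Cells
#' with `p <= alpha` are labeled `"synergistic"` or `"antagonistic"` by the
#' sign of their Excess-over-CDA; others are `"consistent"`. Cells flagged
#' as outliers during fitting are labeled `"outlier"` and not tested.
#'
#' @param matrix A [dose_matrix()].
#' @param fit A `dcda_fit` from [fit_dcda_pipeline()].
#' @param alpha Flagging significance level (default 0.01).
#' @return Data frame with one row per cell: `i`, `j`, `dose_A`, `dose_B`,
#'   `residual`, `z`, `p`, `flag`.
#' @export
local_dcda_flags <- function(matrix, fit, alpha = 0.01) {
  stopifnot(inherits(matrix, "dose_matrix"), inherits(fit, "dcda_fit"))
  dims <- dim(matrix$viability)
  outlier_mask <- exclusion_mask(fit$outliers, dims)
  keep <- which(!outlier_mask)
  res_all <- fit$predicted - matrix$viability
  mu <- mean(res_all[keep])
  sigma <- sqrt(mean((res_all[keep] - mu)^2))  # normal MLE (1/n) variance
  grid <- expand.grid(i = seq_len(dims[1L]), j = seq_len(dims[2L]))
  out <- data.frame(grid,
                    dose_A = matrix$doses_A[grid$i],
                    dose_B = matrix$doses_B[grid$j],
                    residual = NA_real_, z = NA_real_, p = NA_real_,
                    flag = "outlier", stringsAsFactors = FALSE)
  if (sigma == 0) {   # perfect fit: every tested cell is consistent
    out$flag[keep] <- "consistent"
    out$residual[keep] <- res_all[keep]
    return(out)
  }
  comp <- dcda_components(fit$hill_A, fit$hill_B,
                          matrix$doses_A, matrix$doses_B)
  rho_grid <- seq(-1, 1, length.out = fit$grid_size)
  obs <- matrix$viability
  for (cell in keep) {
    drop_mask <- outlier_mask
    drop_mask[cell] <- TRUE
    rmse <- vapply(rho_grid, function(r) {
      pred <- dcda_predict(comp, r)
      sqrt(mean((pred[!drop_mask] - obs[!drop_mask])^2))
    }, numeric(1L))
    rho_loo <- pick_rho(rho_grid, rmse)
    r_i <- dcda_predict(comp, rho_loo)[cell] - obs[cell]
    z <- (mu - r_i) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    out$residual[cell] <- r_i
    out$z[cell] <- z
    out$p[cell] <- p
    out$flag[cell] <-
      if (p > alpha) "consistent"
      else if (fit$eocda[cell] > 0) "synergistic"
      else "antagonistic"
  }
  out
}

#' @export
print.dcda_fit <- function(x, ...) {
  cat("dCDA fit", if (nzchar(x$combination_id)) x$combination_id, "\n")
  cat("  rho_hat =", signif(x$rho_hat, 4),
      "(initial", signif(x$rho_hat_initial, 4), ");",
      "RMSE =", signif(x$rmse, 4), "\n")
  cat("  Hill A: k =", signif(x$hill_A$k, 4), "n =", signif(x$hill_A$n, 3),
      "| Hill B: k =", signif(x$hill_B$k, 4), "n =", signif(x$hill_B$n, 3),
      "\n")
  cat("  outliers removed:", nrow(x$outliers),
      "| GoF paired-t p =", signif(x$gof_p, 3),
      "| EOB validity p =", signif(x$eob_p, 3), "\n")
  if (!is.null(x$local_flags)) {
    nf <- sum(x$local_flags$flag %in% c("synergistic", "antagonistic"))
    cat("  local non-dCDA cells:", nf, "\n")
  }
  invisible(x)
}
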