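#' Hill dose-response parameters
#'
#' Container for the two-parameter Hill curve
#' `V(D) = 1 / (1 + (D / k)^n)`, where `k` is the dose at 50% viability
#' (EC50) and `n` the steepness.
#'
#' @param k EC50, in drug units; must be positive.
#' @param n Hill steepness; must be positive.
#' @param drug_label Free-text drug name.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(k, n, drug_label = "") {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("`k` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("`n` must be a single positive number", call. = FALSE)
  structure(list(k = k, n = n, drug_label = as.character(drug_label)[1L]),
            class = "hill_params")
}

#' Hill curve viability at a dose
#'
#' @param params A [hill_params()].
#' @param D Dose(s), `>= 0`.
#' @return Viability fraction(s) `1 / (1 + (D/k)^n)` in `(0, 1]`.
#' @examples
#' hill_viability(hill_params(k = 1, n = 1), 3)  # 0.25
#' @export
hill_viability <- function(params, D) {
  stopifnot(inherits(params, "hill_params"))
  if (any(D < 0)) stop("doses must be non-negative", call. = FALSE)
  1 / (1 + (D / params$k)^params$n)
}

#' Inverse Hill curve: dose at a given viability
#'
#' @param params A [hill_params()].
#' @param v Viability fraction(s) in `(0, 1]`.
#' @return Dose(s) `D` with `hill_viability(params, D) = v`.
#' @export
hill_inverse <- function(params, v) {
  stopifnot(inherits(params, "hill_params"))
  if (any(v <= 0 | v > 1)) stop("viability must be in (0, 1]", call. = FALSE)
  params$k * ((1 - v) / v)^(1 / params$n)
}

#' Equivalent dose of one drug for a given dose of another
#'
#' The dose of the target drug producing the same viability as dose `D` of
#' the source drug, via matched Hill quantiles:
#' `to_k * (D / from_k)^(from_n / to_n)`. This is the dose-equivalence
#' function `f` (A to B) or `g` (B to A) of the dose-space CDA model.
#'
#' @param from_params Source drug [hill_params()].
#' @param to_params Target drug [hill_params()].
#' @param D Dose(s) of the source drug, `>= 0`.
#' @return Equivalent dose(s) of the target drug.
#' @export
equivalent_dose <- function(from_params, to_params, D) {
  stopifnot(inherits(from_params, "hill_params"),
            inherits(to_params, "hill_params"))
  if (any(D < 0)) stop("doses must be non-negative", call. = FALSE)
  to_params$k * (D / from_params$k)^(from_params$n / to_params$n)
}

#' Fit a Hill curve to monotherapy dose-response data
#'
#' Two-stage initialization followed by an optional local refinement.
#' Stage one: viabilities are linearly interpolated onto a dense grid over
#' the experimental dose range and rescaled to 0-100; an ordinary
#' least-squares line of viability on dose, restricted to the
#' `window` (default 40-60%) viability band around the midpoint (full
#' range when the band holds fewer than two points), gives slope `s` and
#' intercept `i`, from which the EC50 is `k = (50 - i) / s`. Stage two:
#' the steepness `n` is chosen by scanning `n_grid` (default 0.05 to 10 in
#' steps of 0.01) for the lowest RMSE between the Hill curve and the
#' observed viabilities at the experimental doses. With `refine = TRUE`
#' (the default) both parameters are then polished by the same RMSE
#' criterion over a local grid of `k` around the linear-stage estimate --
#' a single least-squares line through a sigmoid carries a steepness-
#' dependent EC50 bias of several percent, which the dose-space model
#' fit is sensitive to. `refine = FALSE` returns the bare two-stage
#' estimate.
#'
#' @param doses Dose vector (>= 3 points, strictly increasing).
#' @param viabilities Observed viability fractions (0-1 or 0-100 scale,
#'   auto-detected) at `doses`; must be broadly decreasing.
#' @param drug_label Drug name carried into the result.
#' @param dense_points Size of the interpolation grid for the linear stage
#'   (default 200).
#' @param n_grid Candidate steepness values for the RMSE scan.
#' @param window Viability band (percent) for the linear stage.
#' @param refine Jointly polish `(k, n)` by RMSE (default `TRUE`).
#' @return A [hill_params()] with attributes `"rmse"` (fit RMSE on the 0-1
#'   scale) and `"k_linear"` (the linear-stage EC50).
#' @export
fit_hill <- function(doses, viabilities, drug_label = "",
                     dense_points = 200L,
                     n_grid = seq(0.05, 10, by = 0.01),
                     window = c(40, 60), refine = TRUE) {
  if (length(doses) < 3L) stop("need at least 3 dose points", call. = FALSE)
  if (length(doses) != length(viabilities))
    stop("`doses` and `viabilities` must have equal length", call. = FALSE)
  if (any(diff(doses) <= 0))
    stop("`doses` must be strictly increasing", call. = FALSE)
  v <- viabilities
  if (max(v) > 1.5) v <- v / 100
  v100 <- v * 100

  dense_d <- seq(min(doses), max(doses), length.out = dense_points)
  dense_v <- stats::approx(doses, v100, xout = dense_d)$y
  sel <- dense_v >= window[1L] & dense_v <= window[2L]
  if (sum(sel) < 2L) sel <- rep(TRUE, length(dense_d))
  fit <- stats::lm.fit(cbind(1, dense_d[sel]), dense_v[sel])
  i0 <- fit$coefficients[1L]; s <- fit$coefficients[2L]
  if (!is.finite(s) || s >= 0)
    stop("viability is not decreasing in dose; cannot fit a Hill curve",
         call. = FALSE)
  k0 <- unname((50 - i0) / s)
  if (k0 <= 0)
    stop("linear stage produced a non-positive EC50 (k = ", signif(k0, 3),
         ")", call. = FALSE)

  # RMSE over the steepness grid for a fixed k, vectorized over n_grid
  scan_n <- function(k) {
    pred <- 1 / (1 + exp(outer(log(doses / k), n_grid)))  # doses x n_grid
    err <- sqrt(colMeans((pred - v)^2))
    i <- which.min(err)
    c(rmse = err[i], n = n_grid[i])
  }
  # log(0/k) = -Inf gives pred = 1 at dose 0, consistent with the curve
  best <- scan_n(k0)
  k_hat <- k0; n_hat <- best[["n"]]; rmse <- best[["rmse"]]
  if (isTRUE(refine)) {
    for (k in k0 * seq(0.6, 1.6, by = 0.005)) {
      cand <- scan_n(k)
      if (cand[["rmse"]] < rmse) {
        rmse <- cand[["rmse"]]; k_hat <- k; n_hat <- cand[["n"]]
      }
    }
  }
  out <- hill_params(k_hat, n_hat, drug_label)
  attr(out, "rmse") <- rmse
  attr(out, "k_linear") <- k0
  out
}

#' @export
print.hill_params <- function(x, ...) {
  cat("Hill curve", if (nzchar(x$drug_label)) paste0("'", x$drug_label, "'"),
      ": k (EC50) =", signif(x$k, 4), ", n =", signif(x$n, 4), "\n")
  invisible(x)
}
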