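#' Pair survival times at a target Spearman correlation (coin method)
#'
#' Realizes the mixture joint distribution behind the temporal CDA model:
#' starting from the rank-matched (`rho = 1`) configuration of two sorted
#' time vectors, each index independently remains rank-matched with
#' probability `|rho|`; the complementary marked indices have their `t_B`
#' values uniformly permuted among themselves. For negative targets the
#' paired `t_B` vector is then reversed. Marginals are preserved exactly
#' and the expected Spearman correlation of the output equals `rho`.
#'
#' @param t_A,t_B Sorted (ascending) time vectors of equal length.
#' @param rho Target Spearman correlation in `[-1, 1]`.
#' @param seed Optional integer seed.
#' @return An object of class `paired_times`: list with `t_A`, `t_B`
#'   (re-paired), `achieved_rho`, `target_rho`, `method`.
#' @export
correlate_pairs_coin <- function(t_A, t_B, rho, seed = NULL) {
  check_pairing_input(t_A, t_B, rho)
  if (!is.null(seed)) set.seed(seed)
  N <- length(t_A)
  a <- abs(rho)
  out <- t_B
  marked <- stats::runif(N) >= a    # 1 - |rho| chance of leaving the rho=1 line
  k <- sum(marked)
  if (k > 1L) out[marked] <- out[sample(which(marked))]
  if (rho < 0) out <- rev(out)
  new_paired_times(t_A, out, rho, "coin")
}

#' Pair survival times at a target Spearman correlation (window swap)
#'
#' Starting from the rank-matched configuration, repeatedly sweeps the
#' to-be-shuffled vector: at each index `i` a partner `j` is drawn uniformly
#' from the window `[i - w, i + w]` (clamped to `[1, N]`) and the values are
#' swapped. After each sweep the achieved Spearman correlation is compared
#' with `|rho|`: if still too high the window grows and the sweep continues
#' from the current state; if the sweep overshot below the target the state
#' is restored and the window shrinks. Stops when the achieved correlation
#' is within `tol` of the target. For negative targets the converged vector
#' is reversed.
#'
#' @param t_A,t_B Sorted (ascending) time vectors of equal length.
#' @param rho Target Spearman correlation in `[-1, 1]`.
#' @param tol Convergence tolerance on the achieved correlation
#'   (default 0.01).
#' @param seed Optional integer seed.
#' @param max_iter Maximum number of sweeps before giving up (default 200).
#' @param adapt Window adaptation: `"double"` (double/halve, default) or
#'   `"step"` (grow/shrink by 1).
#' @return A `paired_times` object (see [correlate_pairs_coin()]).
#' @export
correlate_pairs_window <- function(t_A, t_B, rho, tol = 0.01, seed = NULL,
                                   max_iter = 200L,
                                   adapt = c("double", "step")) {
  check_pairing_input(t_A, t_B, rho)
  adapt <- match.arg(adapt)
  if (!is.null(seed)) set.seed(seed)
  N <- length(t_A)
  target <- abs(rho)
  cur <- t_B
  if (spearman(t_A, cur) <= target + tol) {
    # already within tolerance of the target (e.g. rho = +-1): no swaps
    if (rho < 0) cur <- rev(cur)
    return(new_paired_times(t_A, cur, rho, "window_swap"))
  }
  w <- max(1L, N %/% 10L)
  grow <- function(w) if (adapt == "double") min(N, w * 2L) else min(N, w + 1L)
  shrink <- function(w) if (adapt == "double") max(1L, w %/% 2L) else max(1L, w - 1L)
  best <- spearman(t_A, cur)
  for (iter in seq_len(max_iter)) {
    prev <- cur
    idx <- seq_len(N)
    lo <- pmax(1L, idx - w); hi <- pmin(N, idx + w)
    js <- lo + as.integer(floor(stats::runif(N) * (hi - lo + 1L)))
    for (i in idx) {
      j <- js[i]
      tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
    }
    ach <- spearman(t_A, cur)
    if (abs(ach - target) <= tol) {
      if (rho < 0) cur <- rev(cur)
      return(new_paired_times(t_A, cur, rho, "window_swap"))
    }
    if (ach > target) {
      best <- ach
      w <- grow(w)           # still too organized: disorganize harder
    } else {
      cur <- prev            # overshot below target: restore and retry finer
      w <- shrink(w)
    }
  }
  stop(structure(
    class = c("window_swap_no_convergence", "error", "condition"),
    list(message = paste0("window swap did not converge in ", max_iter,
                          " sweeps (best achieved ", signif(best, 4),
                          " for target ", signif(target, 4), ")"),
         call = NULL, best_achieved = best)))
}

#' Simulate a combination survival curve from two monotherapy arms
#'
#' Samples `N` survival times from each monotherapy curve by inverse
#' transform, pairs them at the target correlation with the coin or
#' window-swap method, assigns each simulated patient the maximum of their
#' two monotherapy times, and returns the empirical survival curve of those
#' maxima on the arms' common grid.
#'
#' @param arm_A,arm_B Monotherapy [survival_table()]s.
#' @param rho Target Spearman correlation in `[-1, 1]`.
#' @param method `"coin"` (default) or `"window_swap"`.
#' @param N Number of simulated patients; default 4x the grid length.
#' @param seed Optional integer seed.
#' @param dt Grid spacing used to regrid the arms (default 0.05 months).
#' @return A [survival_table()] of the simulated combination arm with
#'   `n_patients = N`.
#' @export
simulate_combination_curve <- function(arm_A, arm_B, rho,
                                       method = c("coin", "window_swap"),
                                       N = NULL, seed = NULL, dt = 0.05) {
  method <- match.arg(method)
  arms <- common_truncate(list(regrid_survival(arm_A, dt),
                               regrid_survival(arm_B, dt)))
  grid <- arms[[1L]]$times
  if (is.null(N)) N <- 4L * length(grid)
  if (!is.null(seed)) set.seed(seed)
  tA <- sort(step_inverse_times(arms[[1L]], stats::runif(N)))
  tB <- sort(step_inverse_times(arms[[2L]], stats::runif(N)))
  pair <- if (method == "coin") correlate_pairs_coin(tA, tB, rho)
          else correlate_pairs_window(tA, tB, rho)
  surv <- empirical_survival(grid, pmax(pair$t_A, pair$t_B))
  survival_table(grid, surv, n_patients = N,
                 label = paste0("simulated combination (", method,
                                ", rho=", signif(rho, 3), ")"))
}

# Spearman rank correlation; ranks of grid-sampled times carry heavy ties,
# which cor(method = "spearman") handles via midranks.
spearman <- function(x, y) stats::cor(x, y, method = "spearman")

check_pairing_input <- function(t_A, t_B, rho) {
  if (length(t_A) != length(t_B))
    stop("`t_A` and `t_B` must have equal length", call. = FALSE)
  if (length(t_A) < 2L) stop("need at least two pairs", call. = FALSE)
  if (is.unsorted(t_A) || is.unsorted(t_B))
    stop("inputs must be sorted ascending (the rho = 1 configuration)",
         call. = FALSE)
  if (length(rho) != 1L || is.na(rho) || abs(rho) > 1)
    stop("`rho` must be a single value in [-1, 1]", call. = FALSE)
  invisible(TRUE)
}

new_paired_times <- function(t_A, t_B, target_rho, method) {
  structure(list(t_A = t_A, t_B = t_B,
                 achieved_rho = spearman(t_A, t_B),
                 target_rho = target_rho, method = method),
            class = "paired_times")
}

#' @export
print.paired_times <- function(x, ...) {
  cat("Paired times (", x$method, " method): N = ", length(x$t_A), "\n",
      sep = "")
  cat("  target rho =", signif(x$target_rho, 4),
      ", achieved rho =", signif(x$achieved_rho, 4), "\n")
  invisible(x)
}
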