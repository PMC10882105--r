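#' Batch run configuration
#'
#' Collects the tunable parameters shared across a batch of fits.
#'
#' @param grid_size Correlation grid size (default 200).
#' @param dt Survival time grid spacing in months (default 0.05).
#' @param n_boot Bootstrap replicates for tCDA confidence intervals
#'   (default 5000; set to 0 to skip the bootstrap).
#' @param alpha_family Family-wise significance level divided by the batch
#'   size to form the goodness-of-fit threshold (default 0.05).
#' @param local_alpha Significance level for Excess-over-Bliss validity and
#'   local flags (default 0.01).
#' @param seed Integer seed for the batch.
#' @param method Simulation method where one is needed (`"coin"` or
#'   `"window_swap"`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(grid_size = 200L, dt = 0.05, n_boot = 5000L,
                       alpha_family = 0.05, local_alpha = 0.01,
                       seed = 1L, method = c("coin", "window_swap")) {
  method <- match.arg(method)
  stopifnot(grid_size >= 3, dt > 0, n_boot >= 0,
            alpha_family > 0, alpha_family < 1,
            local_alpha > 0, local_alpha < 1)
  structure(list(grid_size = as.integer(grid_size), dt = dt,
                 n_boot = as.integer(n_boot),
                 alpha_family = alpha_family, local_alpha = local_alpha,
                 seed = as.integer(seed), method = method),
            class = "run_config")
}

#' Fit a batch of combinations and summarize screen-wide results
#'
#' Reads a manifest CSV describing one combination per row and fits the
#' matching model. Temporal rows (`kind = "tcda"`) need `path_a`,
#' `path_b`, `path_ab` survival CSVs and `n_a`, `n_b`, `n_ab` cohort
#' sizes; dose-space rows (`kind = "dcda"`) need `path_matrix`. The
#' goodness-of-fit decision for each combination uses the single corrected
#' threshold `alpha_family / m`, where `m` is the number of combinations
#' of that kind in the batch. Per-combination JSON reports are written to
#' `out_dir` when given. Malformed rows are skipped with a logged error;
#' the run fails only if every row fails.
#'
#' @param manifest Path to the manifest CSV (columns `combination_id`,
#'   `kind`, then the kind-specific path/cohort columns).
#' @param config A [run_config()].
#' @param out_dir Optional directory for per-combination JSON reports.
#' @param quiet Suppress per-combination progress messages on stderr.
#' @return Data frame with one row per fitted combination: `combination_id`,
#'   `kind`, `rho_hat`, `ci_low`, `ci_high`, `rmse`, `gof_p`,
#'   `gof_threshold`, `describable` (fail-to-reject at the corrected
#'   threshold), `eob_p`, `eob_valid`, `n_outliers`, `n_local_flags`.
#' @export
run_batch <- function(manifest, config = run_config(), out_dir = NULL,
                      quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                   call. = FALSE)
  rows <- utils::read.csv(manifest, comment.char = "#", strip.white = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) stop("empty manifest", call. = FALSE)
  if (!all(c("combination_id", "kind") %in% names(rows)))
    stop("manifest needs `combination_id` and `kind` columns", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  m_by_kind <- table(rows$kind)

  res <- vector("list", nrow(rows))
  for (r in seq_len(nrow(rows))) {
    row <- rows[r, ]
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch({
      set.seed(config$seed + r)
      m <- as.integer(m_by_kind[[row$kind]])
      thr <- corrected_threshold(config$alpha_family, m)
      if (row$kind == "tcda") {
        trial <- trial_set(
          read_survival_table(resolve(row$path_a), row$n_a, "arm A"),
          read_survival_table(resolve(row$path_b), row$n_b, "arm B"),
          read_survival_table(resolve(row$path_ab), row$n_ab, "arm AB"),
          combination_id = row$combination_id)
        fit <- fit_tcda(trial, config$grid_size, config$dt)
        if (config$n_boot > 0)
          fit$ci <- bootstrap_rho_ci(trial, config$n_boot,
                                     seed = config$seed + r,
                                     grid_size = config$grid_size,
                                     dt = config$dt)
        if (!is.null(out_dir))
          write_fit_report(fit, file.path(out_dir,
                                          paste0(row$combination_id, ".json")))
        data.frame(combination_id = row$combination_id, kind = "tcda",
                   rho_hat = fit$rho_hat, ci_low = fit$ci[1L],
                   ci_high = fit$ci[2L], rmse = fit$rmse,
                   gof_p = fit$gof_p, gof_threshold = thr,
                   describable = is.na(fit$gof_p) || fit$gof_p > thr,
                   eob_p = NA_real_, eob_valid = NA,
                   n_outliers = NA_integer_, n_local_flags = NA_integer_)
      } else if (row$kind == "dcda") {
        mat <- read_dose_matrix(resolve(row$path_matrix),
                                combination_id = row$combination_id)
        fit <- fit_dcda_pipeline(mat, config$grid_size, config$local_alpha)
        if (!is.null(out_dir))
          write_fit_report(fit, file.path(out_dir,
                                          paste0(row$combination_id, ".json")))
        nflag <- if (is.null(fit$local_flags)) NA_integer_ else
          sum(fit$local_flags$flag %in% c("synergistic", "antagonistic"))
        data.frame(combination_id = row$combination_id, kind = "dcda",
                   rho_hat = fit$rho_hat, ci_low = NA_real_,
                   ci_high = NA_real_, rmse = fit$rmse,
                   gof_p = fit$gof_p, gof_threshold = thr,
                   describable = fit$gof_p > thr,
                   eob_p = fit$eob_p,
                   eob_valid = fit$eob_p > config$local_alpha,
                   n_outliers = nrow(fit$outliers),
                   n_local_flags = nflag)
      } else {
        stop("unknown kind: ", row$kind)
      }
    }, error = function(e) {
      if (!quiet)
        message("[cdaction] skipping ", row$combination_id, ": ",
                conditionMessage(e))
      NULL
    })
    if (!quiet && !is.null(out))
      message(sprintf("[cdaction] %s fitted in %.2fs", row$combination_id,
                      proc.time()[["elapsed"]] - t0))
    res[[r]] <- out
  }
  ok <- !vapply(res, is.null, logical(1L))
  if (!any(ok)) stop("all manifest rows failed", call. = FALSE)
  out <- do.call(rbind, res[ok])
  rownames(out) <- NULL
  out
}
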