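#' Write a fit report to JSON
#'
#' Serializes a [fit_tcda()] or [fit_dcda_pipeline()] result to a JSON
#' report. Matrices are written row-major with their dose grids alongside;
#' undefined statistics (`NA`/`NaN`) are serialized as `null` (with a
#' warning). Numeric fields round-trip losslessly through
#' [read_fit_report()].
#'
#' @param fit A `tcda_fit` or `dcda_fit` object.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  rep <- if (inherits(fit, "tcda_fit")) {
    list(model = "tcda",
         combination_id = fit$combination_id,
         rho_hat = fit$rho_hat,
         alpha_of_rho = fit$alpha_of_rho,
         rmse = fit$rmse,
         ci = fit$ci,
         gof_p = fit$gof_p,
         time_grid_dt = fit$time_grid_dt,
         grid_size = fit$grid_size,
         times = fit$predicted$times,
         predicted_survival = fit$predicted$survival,
         observed_survival = fit$observed$survival,
         outliers = list())
  } else if (inherits(fit, "dcda_fit")) {
    list(model = "dcda",
         combination_id = fit$combination_id,
         rho_hat = fit$rho_hat,
         rho_hat_initial = fit$rho_hat_initial,
         rmse = fit$rmse,
         gof_p = fit$gof_p,
         eob_p = fit$eob_p,
         grid_size = fit$grid_size,
         hill_A = list(k = fit$hill_A$k, n = fit$hill_A$n),
         hill_B = list(k = fit$hill_B$k, n = fit$hill_B$n),
         doses_A = fit$doses_A,
         doses_B = fit$doses_B,
         predicted = matrix_rows(fit$predicted),
         observed = matrix_rows(fit$observed),
         eocda = matrix_rows(fit$eocda),
         outliers = outlier_rows(fit$outliers),
         local_flags = if (is.null(fit$local_flags)) NULL else
           fit$local_flags)
  } else {
    stop("`fit` must be a tcda_fit or dcda_fit object", call. = FALSE)
  }
  undef <- names(which(vapply(
    rep, function(x) is.numeric(x) && length(x) == 1L && !is.finite(x),
    logical(1L))))
  if (length(undef))
    warning("undefined statistics serialized as null: ",
            paste(undef, collapse = ", "), call. = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

matrix_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

outlier_rows <- function(outliers) {
  if (is.null(outliers) || nrow(outliers) == 0L) return(list())
  lapply(seq_len(nrow(outliers)), function(r) unname(outliers[r, ]))
}

#' Read a fit report written by [write_fit_report()]
#'
#' @param path Path to the JSON report.
#' @return Named list mirroring the report structure; matrices are
#'   reassembled from their row-major serialization.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("predicted", "observed", "eocda"))
    if (!is.null(rep[[f]]) && is.list(rep[[f]]))
      rep[[f]] <- do.call(rbind, rep[[f]])
  if (!is.null(rep$outliers) && length(rep$outliers))
    rep$outliers <- if (is.list(rep$outliers))
      do.call(rbind, rep$outliers) else rep$outliers
  rep
}
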