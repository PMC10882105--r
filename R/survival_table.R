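#' Construct a survival table
#'
#' A `survival_table` holds one trial arm's survival curve: a strictly
#' increasing time grid (months) and the surviving fraction at each time,
#' together with the cohort size used for resampling and goodness-of-fit.
#'
#' Digitized curves are noisy: raw survival values may locally increase by a
#' small amount. Values are monotonized by a running minimum from `t = 0`;
#' input is rejected only if a raw point exceeds the running minimum by more
#' than `tol` (default 0.02, a digitizer-noise allowance).
#'
#' @param times Numeric vector of times in months, `>= 0`. Rows are sorted
#'   and duplicate times collapsed to their minimum survival.
#' @param survival Numeric vector of surviving fractions. A 0-100 scale is
#'   auto-detected (`max > 1.5`) and divided by 100.
#' @param n_patients Positive integer cohort size, or `NA` if unknown.
#' @param label Free-text arm label.
#' @param tol Maximum allowed local increase in raw survival before
#'   monotonization fails.
#' @return An object of class `survival_table` with fields `times`,
#'   `survival`, `n_patients`, `label`.
#' @examples
#' survival_table(c(0, 6, 12), c(100, 50, 25), n_patients = 100)
#' @export
survival_table <- function(times, survival, n_patients = NA_integer_,
                           label = "", tol = 0.02) {
  if (!is.numeric(times) || !is.numeric(survival))
    stop("`times` and `survival` must be numeric", call. = FALSE)
  if (length(times) != length(survival))
    stop("`times` and `survival` must have equal length", call. = FALSE)
  if (length(times) < 1L) stop("empty survival table", call. = FALSE)
  if (anyNA(times) || anyNA(survival))
    stop("missing values in survival table", call. = FALSE)
  if (any(times < 0)) stop("negative times in survival table", call. = FALSE)

  scale <- if (max(survival) > 1.5) 100 else 1
  if (any(survival < -0.02 * scale) || any(survival > 1.02 * scale))
    stop("survival values outside [", -0.02 * scale, ", ", 1.02 * scale, "]",
         call. = FALSE)
  survival <- survival / scale

  ord <- order(times, survival)   # duplicate times: keep minimum survival
  times <- times[ord]; survival <- survival[ord]
  keep <- !duplicated(times)      # first occurrence = minimum at that time
  times <- times[keep]; survival <- survival[keep]

  runmin <- cummin(survival)
  if (any(survival - runmin > tol))
    stop("survival increases by more than ", tol,
         " over the running minimum; not a monotonizable curve", call. = FALSE)
  survival <- pmin(pmax(runmin, 0), 1)

  if (!is.na(n_patients)) {
    if (!is.numeric(n_patients) || length(n_patients) != 1L ||
        n_patients < 1 || n_patients != round(n_patients))
      stop("`n_patients` must be a positive integer", call. = FALSE)
    n_patients <- as.integer(n_patients)
  }

  structure(
    list(times = as.numeric(times), survival = as.numeric(survival),
         n_patients = n_patients, label = as.character(label)[1L]),
    class = "survival_table")
}

#' Read a survival curve from CSV
#'
#' Expects two numeric columns, time (months) and survival. Survival on a
#' 0-100 scale is auto-detected (maximum above 1.5) and rescaled to 0-1.
#' Comma separated, `.` decimal, `#` comment lines allowed.
#'
#' @param path Path to the CSV file.
#' @param n_patients Cohort size of the arm (used for bootstrap resampling
#'   and goodness-of-fit).
#' @param label Arm label; defaults to the file name.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path, n_patients = NA_integer_,
                                label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (ncol(df) < 2L)
    stop("survival CSV must have two columns (time, survival): ", path,
         call. = FALSE)
  df <- df[, 1:2]
  if (!all(vapply(df, is.numeric, logical(1L))))
    stop("non-numeric values in survival CSV: ", path, call. = FALSE)
  survival_table(df[[1L]], df[[2L]], n_patients = n_patients, label = label)
}

#' Write a survival table to CSV
#'
#' Writes columns `time_months,survival`, the format [read_survival_table()]
#' reads back.
#'
#' @param x A `survival_table`.
#' @param path Output path.
#' @export
write_survival_table <- function(x, path) {
  stopifnot(inherits(x, "survival_table"))
  utils::write.csv(
    data.frame(time_months = x$times, survival = x$survival),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle the three arms of one combination trial
#'
#' @param arm_A,arm_B Monotherapy [survival_table()]s.
#' @param arm_AB Combination-arm [survival_table()].
#' @param combination_id Identifier for the combination.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(arm_A, arm_B, arm_AB, combination_id = "") {
  for (a in list(arm_A, arm_B, arm_AB))
    if (!inherits(a, "survival_table"))
      stop("all arms must be survival_table objects", call. = FALSE)
  labs <- c(arm_A$label, arm_B$label, arm_AB$label)
  if (anyDuplicated(labs))
    stop("arm labels must be distinct", call. = FALSE)
  structure(list(arm_A = arm_A, arm_B = arm_B, arm_AB = arm_AB,
                 combination_id = as.character(combination_id)[1L]),
            class = "trial_set")
}

#' @export
print.survival_table <- function(x, ...) {
  cat("Survival curve", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  ", length(x$times), " time points over [",
      min(x$times), ", ", max(x$times), "] months; final S = ",
      signif(x$survival[length(x$survival)], 3), "\n", sep = "")
  cat("  cohort n =", x$n_patients, "\n")
  invisible(x)
}

#' @export
print.trial_set <- function(x, ...) {
  cat("Trial set", if (nzchar(x$combination_id)) x$combination_id, "\n")
  for (nm in c("arm_A", "arm_B", "arm_AB")) {
    a <- x[[nm]]
    cat("  ", nm, ": ", length(a$times), " points, max t = ",
        max(a$times), " mo, n = ", a$n_patients, "\n", sep = "")
  }
  invisible(x)
}
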