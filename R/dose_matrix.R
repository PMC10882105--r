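#' Construct a dose-response combination matrix
#'
#' Holds the dose grids of two drugs, the observed combination viability
#' matrix (rows = drug A doses, columns = drug B doses, fractions relative
#' to untreated control), and the monotherapy viability vectors. Viability
#' may exceed 1 slightly because luminescence is normalized to untreated
#' wells; values up to 1.5 are accepted.
#'
#' @param doses_A,doses_B Strictly increasing non-negative dose grids.
#' @param viability `length(doses_A) x length(doses_B)` matrix of fractions.
#' @param mono_A Viability of drug A alone at `doses_A`; if `NULL`,
#'   approximated by the viability column at the lowest B dose (and
#'   `approx_mono` is set).
#' @param mono_B Same for drug B (row at the lowest A dose).
#' @param treatment_time_h Assay treatment time in hours.
#' @param combination_id Identifier.
#' @return An object of class `dose_matrix` with an `approx_mono` flag
#'   recording whether monotherapies were approximated from the matrix edge.
#' @export
dose_matrix <- function(doses_A, doses_B, viability,
                        mono_A = NULL, mono_B = NULL,
                        treatment_time_h = NA_real_, combination_id = "") {
  viability <- as.matrix(viability)
  if (!is.numeric(doses_A) || !is.numeric(doses_B))
    stop("dose grids must be numeric", call. = FALSE)
  for (d in list(A = doses_A, B = doses_B)) {
    if (any(d < 0) || any(diff(d) <= 0))
      stop("dose grids must be non-negative and strictly increasing",
           call. = FALSE)
  }
  if (nrow(viability) != length(doses_A) ||
      ncol(viability) != length(doses_B))
    stop("viability matrix must be length(doses_A) x length(doses_B)",
         call. = FALSE)
  if (anyNA(viability))
    stop("missing cells in viability matrix", call. = FALSE)
  if (any(viability < 0) || any(viability > 1.5))
    stop("viability values must lie in [0, 1.5]", call. = FALSE)

  approx_mono <- is.null(mono_A) || is.null(mono_B)
  if (is.null(mono_A)) mono_A <- viability[, 1L]
  if (is.null(mono_B)) mono_B <- viability[1L, ]
  if (length(mono_A) != length(doses_A) || length(mono_B) != length(doses_B))
    stop("monotherapy vectors must match their dose grids", call. = FALSE)

  structure(
    list(doses_A = as.numeric(doses_A), doses_B = as.numeric(doses_B),
         viability = unname(viability),
         mono_A = as.numeric(mono_A), mono_B = as.numeric(mono_B),
         approx_mono = approx_mono,
         treatment_time_h = as.numeric(treatment_time_h),
         combination_id = as.character(combination_id)[1L]),
    class = "dose_matrix")
}

#' Read a combination dose matrix from CSV
#'
#' Layout: header row `dose_A\dose_B,<b1>,<b2>,...` giving the drug-B dose
#' grid, first column the drug-A dose grid, body the observed combination
#' viabilities. If both grids include dose 0, the zero row/column are taken
#' as the explicit monotherapy responses and stripped from the combination
#' matrix. Otherwise the monotherapies are approximated by the matrix edge
#' at the lowest dose of the partner drug, and the `approx_mono` flag is set
#' (the convention used for screens measured without drug-free wells).
#'
#' @param path Path to the CSV file.
#' @param treatment_time_h Assay treatment time in hours (metadata).
#' @param combination_id Identifier; defaults to the file name.
#' @return A [dose_matrix()].
#' @export
read_dose_matrix <- function(path, treatment_time_h = NA_real_,
                             combination_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", header = TRUE,
                         check.names = FALSE, strip.white = TRUE,
                         colClasses = "character")
  if (ncol(raw) < 3L)
    stop("dose-matrix CSV needs a dose-A column and >= 2 dose-B columns: ",
         path, call. = FALSE)
  doses_B <- suppressWarnings(as.numeric(names(raw)[-1L]))
  if (anyNA(doses_B))
    stop("header must contain numeric drug-B doses: ", path, call. = FALSE)
  doses_A <- suppressWarnings(as.numeric(raw[[1L]]))
  if (anyNA(doses_A))
    stop("first column must contain numeric drug-A doses: ", path,
         call. = FALSE)

  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or blank cell at row %d (dose_A=%g), column %d (dose_B=%g) in %s",
                 bad[1L], doses_A[bad[1L]], bad[2L], doses_B[bad[2L]], path),
         call. = FALSE)
  }

  has_zero <- min(doses_A) == 0 && min(doses_B) == 0
  if (has_zero) {
    ia <- doses_A > 0; ib <- doses_B > 0
    mono_A <- num[ia, !ib]
    mono_B <- num[!ia, ib]
    dose_matrix(doses_A[ia], doses_B[ib], num[ia, ib, drop = FALSE],
                mono_A = mono_A, mono_B = mono_B,
                treatment_time_h = treatment_time_h,
                combination_id = combination_id)
  } else {
    dose_matrix(doses_A, doses_B, num,
                treatment_time_h = treatment_time_h,
                combination_id = combination_id)
  }
}

#' Write a dose matrix to CSV
#'
#' Writes the combination matrix in the layout [read_dose_matrix()] reads.
#' When explicit monotherapy vectors are present (not edge-approximated)
#' they are emitted as a dose-0 row and column.
#'
#' @param x A `dose_matrix`.
#' @param path Output path.
#' @export
write_dose_matrix <- function(x, path) {
  stopifnot(inherits(x, "dose_matrix"))
  if (x$approx_mono) {
    m <- x$viability
    da <- x$doses_A; db <- x$doses_B
  } else {
    m <- rbind(c(NA, x$mono_B), cbind(x$mono_A, x$viability))
    m[1L, 1L] <- 1      # untreated control
    da <- c(0, x$doses_A); db <- c(0, x$doses_B)
  }
  num <- function(x) sprintf("%.17g", x)   # full double precision
  header <- paste(c("dose_A\\dose_B", num(db)), collapse = ",")
  rows <- vapply(seq_along(da), function(i)
    paste(c(num(da[i]), num(m[i, ])), collapse = ","), character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat("Dose matrix", if (nzchar(x$combination_id)) x$combination_id, "\n")
  cat("  ", length(x$doses_A), " x ", length(x$doses_B), " doses; ",
      "viability range [", signif(min(x$viability), 3), ", ",
      signif(max(x$viability), 3), "]\n", sep = "")
  if (x$approx_mono)
    cat("  monotherapies approximated at the lowest partner dose\n")
  invisible(x)
}
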