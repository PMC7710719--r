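#' Contact matrix container
#'
#' A symmetric, nonnegative, binned contact matrix together with its bin
#' table and a per-bin validity mask.  Entries on masked rows/columns are
#' stored as `NA` and treated as missing by every operation.
#'
#' @param bins bin table from [make_bin_table()].
#' @param values square numeric matrix, symmetric to relative tolerance 1e-9.
#' @param valid logical per-bin mask; defaults to bins whose row is not
#'   entirely `NA`.
#' @param balanced logical flag: has iterative correction been applied?
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, values, valid = NULL, balanced = FALSE) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("values must be a square matrix")
  if (nrow(values) != nrow(bins))
    stop("bin table has ", nrow(bins), " bins but matrix is ",
         nrow(values), "x", ncol(values))
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  scale <- max(abs(values), 1, na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-9 * scale)
    stop("matrix is asymmetric beyond tolerance (max |A - t(A)| = ", asym, ")")
  if (any(values < 0, na.rm = TRUE))
    stop("contact matrices must be nonnegative")
  if (is.null(valid)) valid <- rowSums(!is.na(values)) > 0
  stopifnot(is.logical(valid), length(valid) == nrow(bins))
  values[!valid, ] <- NA_real_
  values[, !valid] <- NA_real_
  structure(list(bins = bins, values = values, valid = valid,
                 resolution = bin_resolution(bins),
                 assembly = attr(bins, "assembly") %||% "unknown",
                 balanced = isTRUE(balanced), bias = NULL),
            class = "contact_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$bins), "bins @", format(x$resolution, big.mark = ","),
      "bp (", length(unique(x$bins$chrom)), "chromosome(s) )\n")
  cat("  valid bins:", sum(x$valid), "/", length(x$valid),
      " balanced:", x$balanced, "\n")
  cat("  total contacts:", format(matrix_total(x)), "\n")
  invisible(x)
}

#' @export
summary.contact_matrix <- function(object, ...) {
  v <- object$values[object$valid, object$valid, drop = FALSE]
  out <- list(n_bins = nrow(object$bins), n_valid = sum(object$valid),
              resolution = object$resolution, balanced = object$balanced,
              total = matrix_total(object),
              quantiles = stats::quantile(v, c(0, .25, .5, .75, 1), na.rm = TRUE))
  class(out) <- "summary.contact_matrix"
  out
}

#' @export
print.summary.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$n_valid, "valid /", x$n_bins, "bins @",
      x$resolution, "bp; total", format(x$total), "\n")
  print(x$quantiles)
  invisible(x)
}

#' Sum of all (valid) matrix entries
#' @param m a `contact_matrix`.
#' @export
matrix_total <- function(m) {
  sum(m$values[m$valid, m$valid], na.rm = TRUE)
}

# valid-submatrix accessor used by most stages
valid_block <- function(m, rows) {
  m$values[rows, rows, drop = FALSE]
}

stop_if_bins_differ <- function(a, b) {
  if (!bins_equal(a$bins, b$bins))
    stop("bin tables differ between the two matrices")
  invisible(TRUE)
}
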