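#' Log-scale correlation map of a contact matrix
#'
#' After log-transforming the corrected counts (zero entries are replaced
#' by the matrix's smallest positive entry so they stay finite), entry (i, j) is the
#' Pearson correlation between the full row i and the full row j (equal to
#' column j by symmetry) over mutually valid bins.  This emphasizes
#' interaction patterns over the average distance decay.
#'
#' @param m a balanced, scaled `contact_matrix` (genome-wide, coarse bins).
#' @param min_pairs pairs with fewer mutually valid bins are masked.
#' @return a symmetric correlation matrix with unit diagonal on valid bins.
#' @export
log_correlation_matrix <- function(m, min_pairs = 3) {
  V <- m$values
  pos <- V[V > 0]
  eps <- if (length(pos)) min(pos, na.rm = TRUE) else 1
  V[!is.na(V) & V == 0] <- eps
  L <- log(V)
  L[!m$valid, ] <- NA_real_
  L[, !m$valid] <- NA_real_
  C <- suppressWarnings(stats::cor(L, use = "pairwise.complete.obs"))
  # mask pairs with too few complete observations
  obs <- crossprod(!is.na(L))
  C[obs < min_pairs] <- NA_real_
  diag(C)[m$valid] <- 1
  C
}

#' Reproducibility score between two datasets
#'
#' Each matrix is turned into its genome-wide log correlation map, the maps
#' are flattened column-wise, and the score is the Spearman rank correlation
#' between the two vectors over mutually finite entries (average ranks for
#' ties).
#'
#' @param a,b `contact_matrix` objects on identical bin tables.
#' @param include_diagonal keep the unit diagonal of the correlation maps in
#'   the flattened vectors (default TRUE; constant entries barely affect the
#'   rank correlation).
#' @return a scalar in [-1, 1].
#' @export
reproducibility_score <- function(a, b, include_diagonal = TRUE) {
  stop_if_bins_differ(a, b)
  Ca <- log_correlation_matrix(a)
  Cb <- log_correlation_matrix(b)
  if (!include_diagonal) {
    diag(Ca) <- NA_real_
    diag(Cb) <- NA_real_
  }
  va <- as.vector(Ca)
  vb <- as.vector(Cb)
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3) stop("too few mutually valid correlation entries")
  stats::cor(va[ok], vb[ok], method = "spearman")
}

#' Pairwise reproducibility report
#'
#' @param matrices named list of `contact_matrix` objects on one bin table.
#' @param ... passed to [reproducibility_score()].
#' @return a `reproducibility_report`: symmetric score matrix with unit
#'   diagonal.
#' @export
reproducibility_report <- function(matrices, ...) {
  k <- length(matrices)
  labels <- names(matrices) %||% paste0("dataset", seq_len(k))
  S <- diag(1, k)
  dimnames(S) <- list(labels, labels)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      S[i, j] <- S[j, i] <- reproducibility_score(matrices[[i]], matrices[[j]], ...)
    }
  }
  structure(list(scores = S, labels = labels,
                 resolution = matrices[[1]]$resolution),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat("reproducibility report @", format(x$resolution, scientific = FALSE), "bp\n")
  print(round(x$scores, 4))
  invisible(x)
}
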