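#' Aggregate contact map around TAD boundaries
#'
#' Element-wise mean over boundary-centered sub-matrices of half-width
#' `window_bp`; the boundary bin is the central row/column.  Cells closer to
#' the matrix diagonal than `diag_exclusion_bp` are masked, boundaries whose
#' window exits their chromosome are skipped (and counted), and only
#' boundaries with strength >= `min_strength` (or `NA` strength, as in truth
#' sets) enter the average.
#'
#' @param m a balanced, scaled `contact_matrix` (typically 40 kb bins).
#' @param boundaries a `boundary_set`.
#' @param min_strength default 1, the paper-style cut for pileups.
#' @param window_bp half-window, default 500 kb.
#' @param diag_exclusion_bp default 30 kb (masks the diagonal at 40 kb bins).
#' @return a `pileup_map`.
#' @export
boundary_pileup <- function(m, boundaries, min_strength = 1,
                            window_bp = 500000, diag_exclusion_bp = 30000) {
  keep <- is.na(boundaries$strength) | boundaries$strength >= min_strength
  bs <- boundaries[keep, , drop = FALSE]
  W <- round(window_bp / m$resolution)
  pile <- aggregate_windows(m, bs$bin, bs$bin, W)
  if (pile$n == 0) stop("no eligible boundaries for the pileup")
  ex <- outer(seq_len(2 * W + 1), seq_len(2 * W + 1),
              function(r, c) abs(r - c) * m$resolution < diag_exclusion_bp)
  vals <- pile$mean
  vals[ex] <- NA_real_
  structure(list(values = vals, center_kind = "boundary",
                 window_bp = W * m$resolution, resolution = m$resolution,
                 n_aggregated = pile$n, n_skipped = pile$skipped,
                 excluded_diag_bp = diag_exclusion_bp),
            class = "pileup_map")
}

#' Aggregate contact map around loop anchors
#'
#' Mean of sub-matrices centered at each (anchor1, anchor2) bin pair; loops
#' whose window exits the chromosome are skipped and counted.
#'
#' @param m a balanced, scaled `contact_matrix`.
#' @param loops a BEDPE-style data.frame (`chrom1,start1,end1,chrom2,
#'   start2,end2`) or a data.frame with genome-wide `bin1`, `bin2` columns.
#' @param window_bins half-window in bins, default 10.
#' @return a `pileup_map`.
#' @export
loop_pileup <- function(m, loops, window_bins = 10) {
  if (!NROW(loops)) stop("empty loop list")
  if (!is.null(loops$bin1)) {
    b1 <- loops$bin1; b2 <- loops$bin2
  } else {
    b1 <- locate_bins(m$bins, loops$chrom1, (loops$start1 + loops$end1) / 2)
    b2 <- locate_bins(m$bins, loops$chrom2, (loops$start2 + loops$end2) / 2)
  }
  ok <- !is.na(b1) & !is.na(b2)
  pile <- aggregate_windows(m, b1[ok], b2[ok], window_bins)
  if (pile$n == 0) stop("no loop window fits inside its chromosome")
  structure(list(values = pile$mean, center_kind = "loop",
                 window_bp = window_bins * m$resolution,
                 resolution = m$resolution,
                 n_aggregated = pile$n,
                 n_skipped = pile$skipped + sum(!ok),
                 excluded_diag_bp = 0),
            class = "pileup_map")
}

# genome-wide bin index of (chrom, bp); NA if outside
locate_bins <- function(bins, chrom, bp) {
  idx <- chrom_bin_index(bins)
  res <- bin_resolution(bins)
  mapply(function(ch, p) {
    ii <- idx[[ch]]
    if (is.null(ii)) return(NA_integer_)
    k <- floor(p / res) + 1
    if (k < 1 || k > length(ii)) return(NA_integer_)
    ii[k]
  }, as.character(chrom), bp)
}

# shared window-averaging core: centers (ci, cj) must stay inside one
# chromosome each; per-cell mean over finite entries
aggregate_windows <- function(m, ci, cj, W) {
  side <- 2 * W + 1
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  n <- 0L; skipped <- 0L
  idx <- chrom_bin_index(m$bins)
  lo <- vapply(idx, min, integer(1))
  hi <- vapply(idx, max, integer(1))
  chrom_of <- m$bins$chrom
  for (t in seq_along(ci)) {
    i <- ci[t]; j <- cj[t]
    chi <- chrom_of[i]; chj <- chrom_of[j]
    if (i - W < lo[[chi]] || i + W > hi[[chi]] ||
        j - W < lo[[chj]] || j + W > hi[[chj]]) {
      skipped <- skipped + 1L
      next
    }
    sub <- m$values[(i - W):(i + W), (j - W):(j + W)]
    fin <- is.finite(sub)
    sub[!fin] <- 0
    acc <- acc + sub
    cnt <- cnt + fin
    n <- n + 1L
  }
  mu <- acc / cnt
  mu[cnt == 0] <- NA_real_
  list(mean = mu, n = n, skipped = skipped)
}

#' @export
print.pileup_map <- function(x, ...) {
  cat("pileup_map (", x$center_kind, "): +/-",
      format(x$window_bp, scientific = FALSE), "bp @",
      format(x$resolution, scientific = FALSE), "bp bins\n", sep = " ")
  cat("  aggregated:", x$n_aggregated, " skipped at edges:", x$n_skipped, "\n")
  invisible(x)
}

#' @export
plot.pileup_map <- function(x, ...) {
  W <- x$window_bp / x$resolution
  off <- (-W:W) * x$resolution
  graphics::image(off, off, log2(x$values), xlab = "offset (bp)",
                  ylab = "offset (bp)", ...)
  invisible(x)
}

#' Composite maps of two pileups
#'
#' `pileup_log2_ratio` is the entrywise `log2((A + eps) / (B + eps))` (eps =
#' smallest positive entry across both maps unless given);
#' `pileup_subtract` is `A - B`.  Masks propagate.
#'
#' @param a,b `pileup_map`s on identical grids.
#' @param pseudocount eps for the ratio.
#' @return a matrix on the pileup offset grid.
#' @export
pileup_log2_ratio <- function(a, b, pseudocount = NULL) {
  check_pileup_grids(a, b)
  if (is.null(pseudocount)) {
    pos <- c(a$values[a$values > 0], b$values[b$values > 0])
    pseudocount <- if (length(pos)) min(pos, na.rm = TRUE) else 1e-9
  }
  log2((a$values + pseudocount) / (b$values + pseudocount))
}

#' @rdname pileup_log2_ratio
#' @export
pileup_subtract <- function(a, b) {
  check_pileup_grids(a, b)
  a$values - b$values
}

check_pileup_grids <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      a$resolution != b$resolution ||
      a$excluded_diag_bp != b$excluded_diag_bp)
    stop("pileup grids do not match")
  invisible(TRUE)
}

#' Planted-parameter readouts from pileups
#'
#' `pileup_permeability` estimates the boundary permeability from a boundary
#' pileup: for each genomic distance present both in the cross-boundary
#' quadrant and in the within-TAD quadrants, the cross/within mean ratio is
#' formed, and the estimate is the geometric mean over distances (matching
#' distances removes the decay from the comparison).
#'
#' @param p a boundary `pileup_map`.
#' @return scalar permeability estimate.
#' @export
pileup_permeability <- function(p) {
  V <- p$values
  side <- nrow(V)
  Wc <- (side + 1) / 2
  r <- row(V); c <- col(V)
  s <- c - r
  within <- (r < Wc & c < Wc & s > 0) | (r > Wc & c > Wc & s > 0)
  cross <- r < Wc & c > Wc
  ratios <- c()
  for (d in sort(unique(s[s > 0]))) {
    wv <- V[within & s == d]
    cv <- V[cross & s == d]
    wv <- wv[is.finite(wv)]; cv <- cv[is.finite(cv)]
    if (length(wv) && length(cv) && mean(wv) > 0)
      ratios <- c(ratios, mean(cv) / mean(wv))
  }
  if (!length(ratios)) stop("no shared distances between quadrants")
  exp(mean(log(ratios)))
}

#' @rdname pileup_permeability
#' @param exclude_bins half-width of the central region excluded from the
#'   background (default: the loop footprint radius + 1).
#' @return `pileup_loop_enrichment`: center value over the mean of
#'   same-distance (diagonal-offset) background cells.
#' @export
pileup_loop_enrichment <- function(p, exclude_bins = 2) {
  V <- p$values
  side <- nrow(V)
  Wc <- (side + 1) / 2
  center <- V[Wc, Wc]
  k <- seq_len(side)
  bg_idx <- k[abs(k - Wc) > exclude_bins]
  bg <- mean(V[cbind(bg_idx, bg_idx)], na.rm = TRUE)
  center / bg
}
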