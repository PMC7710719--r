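#' Observed/expected normalization
#'
#' Each cis entry is divided by the mean of its distance stratum on that
#' chromosome (mean over valid bins); strata with zero mean are masked.
#' Trans entries are masked: O/E is a cis-chromosome normalization here.
#'
#' @param m a balanced `contact_matrix`.
#' @return a `contact_matrix` of O/E values.
#' @export
observed_expected <- function(m) {
  idx <- chrom_bin_index(m$bins)
  n <- nrow(m$bins)
  OE <- matrix(NA_real_, n, n)
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    W <- m$values[ii, ii, drop = FALSE]
    k <- length(ii)
    B <- matrix(NA_real_, k, k)
    for (d in 0:(k - 1)) {
      r <- seq_len(k - d)
      cells <- cbind(r, r + d)
      mu <- mean(W[cells], na.rm = TRUE)
      if (is.finite(mu) && mu > 0) {
        B[cells] <- W[cells] / mu
        B[cells[, 2:1, drop = FALSE]] <- B[cells]
      }
    }
    OE[ii, ii] <- B
  }
  out <- m
  out$values <- OE
  out
}

#' A/B compartment eigenvector
#'
#' Per chromosome: O/E is computed, its bin-bin Pearson correlation matrix
#' is formed, and the leading eigenvectors of that correlation matrix are
#' extracted.  Among the first `n_components` the one with the largest
#' absolute correlation to the orientation anchor is selected (first
#' otherwise), and its sign is set so it correlates positively with the
#' anchor.  Positive values are labeled A, negative B.
#'
#' @param m a balanced `contact_matrix` (typically at coarse resolution).
#' @param anchor per-bin numeric reference track used to pick and orient the
#'   component (for simulations, the planted compartment vector; for real
#'   data, e.g. gene density).  `NULL` leaves the eigen sign as computed and
#'   records the track as unoriented.
#' @param n_components leading components examined when an anchor is given.
#' @param min_bins chromosomes with fewer valid bins are masked with a
#'   warning.
#' @return a `compartment_track`: data.frame `chrom`, `start`, `end`, `pc1`,
#'   `label` (A/B/NA).
#' @export
compartment_eigenvector <- function(m, anchor = NULL, n_components = 2,
                                    min_bins = 10) {
  idx <- chrom_bin_index(m$bins)
  n <- nrow(m$bins)
  oe <- observed_expected(m)
  pc1 <- rep(NA_real_, n)
  chosen <- character(0)
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    vv <- ii[m$valid[ii]]
    if (length(vv) < min_bins) {
      warning("chromosome ", ch, " has fewer than ", min_bins,
              " valid bins; compartment track masked")
      next
    }
    OE <- oe$values[vv, vv, drop = FALSE]
    C <- suppressWarnings(stats::cor(OE, use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    eg <- eigen(C, symmetric = TRUE)
    k <- min(n_components, ncol(eg$vectors))
    comp <- 1L
    if (!is.null(anchor)) {
      cors <- vapply(seq_len(k), function(j)
        abs(suppressWarnings(stats::cor(eg$vectors[, j], anchor[vv]))),
        numeric(1))
      cors[!is.finite(cors)] <- 0
      comp <- which.max(cors)
    }
    v <- eg$vectors[, comp] * sqrt(max(eg$values[comp], 0))
    if (!is.null(anchor)) {
      s <- suppressWarnings(stats::cor(v, anchor[vv]))
      if (is.finite(s) && s < 0) v <- -v
    }
    pc1[vv] <- v
    chosen[ch] <- paste0("PC", comp)
  }
  label <- ifelse(is.na(pc1), NA_character_, ifelse(pc1 >= 0, "A", "B"))
  structure(data.frame(chrom = m$bins$chrom, start = m$bins$start,
                       end = m$bins$end, pc1 = pc1, label = label,
                       stringsAsFactors = FALSE),
            orientation_reference = if (is.null(anchor)) "unoriented" else "anchor track",
            component = chosen,
            class = c("compartment_track", "data.frame"))
}

#' Fraction of bins whose A/B label differs between two tracks
#' @param a,b `compartment_track` objects on the same bins.
#' @export
switch_fraction <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(a$chrom, b$chrom))
    stop("tracks are on different bin tables")
  ok <- !is.na(a$label) & !is.na(b$label)
  if (!any(ok)) stop("no mutually valid bins")
  mean(a$label[ok] != b$label[ok])
}

#' Saddle plot and compartment strength
#'
#' Valid bins are ranked by their compartment eigenvector value and split
#' into `Q` equal-count quantile groups; saddle entry (q, r) is the mean
#' cis O/E between groups q and r (diagonal excluded), pooled across
#' chromosomes.  Compartment strength is
#' `log2(mean(AA corner) * mean(BB corner) / mean(AB corner)^2)` using the
#' extreme `corner_frac` of quantiles on each side.
#'
#' @param m a balanced `contact_matrix`.
#' @param track a `compartment_track` on the same bins.
#' @param Q number of quantile groups (>= 3, default 10).
#' @param corner_frac fraction of extreme quantiles in each corner
#'   (default 0.2).
#' @return a `saddle_matrix` with fields `values` (Q x Q), `counts`,
#'   `strength`, and corner means `AA`, `BB`, `AB`.
#' @export
saddle <- function(m, track, Q = 10, corner_frac = 0.2) {
  stopifnot(Q >= 3)
  if (nrow(track) != nrow(m$bins)) stop("track/matrix bin mismatch")
  oe <- observed_expected(m)
  usable <- m$valid & is.finite(track$pc1)
  rk <- rep(NA_integer_, nrow(m$bins))
  rk[usable] <- rank(track$pc1[usable], ties.method = "first")
  grp <- rep(NA_integer_, nrow(m$bins))
  grp[usable] <- ceiling(rk[usable] * Q / sum(usable))
  grp[usable] <- pmax(1L, pmin(Q, grp[usable]))

  sums <- matrix(0, Q, Q)
  cnts <- matrix(0, Q, Q)
  idx <- chrom_bin_index(m$bins)
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    g <- grp[ii]
    keep <- !is.na(g)
    ii <- ii[keep]; g <- g[keep]
    if (length(ii) < 2) next
    W <- oe$values[ii, ii, drop = FALSE]
    ut <- upper.tri(W)
    ok <- ut & is.finite(W)
    gi <- matrix(g, length(g), length(g))
    gj <- t(gi)
    key <- (pmin(gi[ok], gj[ok]) - 1) * Q + pmax(gi[ok], gj[ok])
    s <- rowsum(W[ok], key)
    c0 <- rowsum(rep(1, sum(ok)), key)
    kk <- as.integer(rownames(s))
    qi <- (kk - 1) %/% Q + 1
    qj <- (kk - 1) %% Q + 1
    for (t in seq_along(kk)) {
      sums[qi[t], qj[t]] <- sums[qi[t], qj[t]] + s[t]
      cnts[qi[t], qj[t]] <- cnts[qi[t], qj[t]] + c0[t]
      if (qi[t] != qj[t]) {
        sums[qj[t], qi[t]] <- sums[qj[t], qi[t]] + s[t]
        cnts[qj[t], qi[t]] <- cnts[qj[t], qi[t]] + c0[t]
      }
    }
  }
  S <- sums / cnts
  S[cnts == 0] <- NA_real_
  k <- max(1L, round(corner_frac * Q))
  lo <- seq_len(k)          # most negative pc1 -> B
  hi <- Q - k + seq_len(k)  # most positive pc1 -> A
  corner_mean <- function(rows, cols)
    sum(sums[rows, cols]) / sum(cnts[rows, cols])
  AA <- corner_mean(hi, hi)
  BB <- corner_mean(lo, lo)
  AB <- corner_mean(lo, hi)
  strength <- log2(AA * BB / AB^2)
  structure(list(values = S, counts = cnts, Q = Q, corner_frac = corner_frac,
                 AA = AA, BB = BB, AB = AB, strength = strength),
            class = "saddle_matrix")
}

#' @rdname saddle
#' @param sd a `saddle_matrix`.
#' @export
compartment_strength <- function(sd) sd$strength

#' @export
print.saddle_matrix <- function(x, ...) {
  cat("saddle matrix, Q =", x$Q, "\n")
  cat("  corner means  AA:", signif(x$AA, 4), " BB:", signif(x$BB, 4),
      " AB:", signif(x$AB, 4), "\n")
  cat("  compartment strength (log2):", signif(x$strength, 4), "\n")
  invisible(x)
}
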