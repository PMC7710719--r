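#' Boundary set container
#'
#' @param df data.frame with columns `chrom`, `bin` (genome-wide 1-based bin
#'   index), `pos` (bp) and `strength`.
#' @param method one of `"insulation"`, `"hicratio"`, `"truth"`.
#' @export
boundary_set <- function(df, method = c("insulation", "hicratio", "truth")) {
  method <- match.arg(method)
  df <- df[order(df$chrom, df$bin), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, method = method, class = c("boundary_set", "data.frame"))
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("boundary_set (", attr(x, "method"), "): ", nrow(x), " boundaries\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Insulation score track
#'
#' Raw insulation `I_i` is the mean of the `w x w` block of contacts between
#' bins (i-w .. i-1) and (i+1 .. i+w), where `w = floor(square_bp /
#' resolution)` (500 kb at 40 kb bins gives w = 12, 480 kb effective).  The
#' reported score is `log2(I_i / geometric mean of valid I)` per chromosome,
#' so valid scores average ~0.  Bins within `w` of a chromosome end, bins
#' with empty squares, and masked bins carry `NA`.
#'
#' @param m a balanced, scaled cis `contact_matrix` (typically 40 kb bins).
#' @param square_bp insulation square size in bp (default 500,000).
#' @param min_valid_frac minimum fraction of unmasked cells in the square.
#' @return an `insulation_track`: data.frame `chrom`, `start`, `end`,
#'   `score`, `raw`, with attribute `square_bins`.
#' @export
insulation_track <- function(m, square_bp = 500000, min_valid_frac = 0.5) {
  w <- floor(square_bp / m$resolution)
  if (w < 1) stop("square smaller than one bin")
  idx <- chrom_bin_index(m$bins)
  n <- nrow(m$bins)
  raw <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    k <- length(ii)
    if (k < 2 * w + 1) next  # fully masked: chromosome shorter than the square reach
    W <- m$values[ii, ii, drop = FALSE]
    I <- rep(NA_real_, k)
    for (i in (w + 1):(k - w)) {
      if (!m$valid[ii[i]]) next
      blk <- W[(i - w):(i - 1), (i + 1):(i + w)]
      nv <- sum(!is.na(blk))
      if (nv < min_valid_frac * w * w) next
      I[i] <- mean(blk, na.rm = TRUE)
    }
    pos <- is.finite(I) & I > 0
    if (!any(pos)) next
    gm <- exp(mean(log(I[pos])))
    sc <- rep(NA_real_, k)
    sc[pos] <- log2(I[pos] / gm)
    raw[ii] <- I
    score[ii] <- sc
  }
  structure(data.frame(chrom = m$bins$chrom, start = m$bins$start,
                       end = m$bins$end, score = score, raw = raw,
                       stringsAsFactors = FALSE),
            square_bins = w, resolution = m$resolution,
            class = c("insulation_track", "data.frame"))
}

# delta vector: mean score over the right span minus mean over the left span;
# crosses zero from negative to positive at insulation minima
insulation_delta <- function(score, span) {
  n <- length(score)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    l <- score[max(1, i - span):(i - 1)]
    r <- score[(i + 1):min(n, i + span)]
    if (i == 1 || i == n) next
    l <- l[is.finite(l)]; r <- r[is.finite(r)]
    if (!length(l) || !length(r)) next
    delta[i] <- mean(r) - mean(l)
  }
  delta
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries sit where the delta vector (mean score over the downstream
#' span minus the upstream span) crosses zero from negative to positive,
#' centered on the local score minimum; strength is the local maximum of
#' delta right of the crossing minus the local minimum left of it
#' (nonnegative).  Plateaus resolve to the leftmost bin.
#'
#' @param track an [insulation_track()].
#' @param delta_span_bp averaging span each side, default 120 kb (3 bins at
#'   40 kb).
#' @param min_strength noise floor below which crossings are discarded
#'   (default 0.1; the paper-style "strength > 1" cut is applied later, at
#'   the pileup/statistics stage).
#' @return a `boundary_set` with method `"insulation"`.
#' @export
call_boundaries_insulation <- function(track, delta_span_bp = 120000,
                                       min_strength = 0.1) {
  res <- attr(track, "resolution")
  span <- max(1L, round(delta_span_bp / res))
  idx <- chrom_bin_index(track)
  rows <- list()
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    sc <- track$score[ii]
    sc[!is.finite(sc)] <- NA_real_
    delta <- insulation_delta(sc, span)
    k <- length(sc)
    for (i in seq_len(k - 1)) {
      if (!is.finite(delta[i]) || !is.finite(delta[i + 1])) next
      if (!(delta[i] <= 0 && delta[i + 1] > 0)) next
      # boundary bin: local score minimum around the crossing (leftmost tie)
      win <- max(1, i - 1):min(k, i + 2)
      win <- win[is.finite(sc[win])]
      if (!length(win)) next
      b <- win[which.min(sc[win])]
      # strength from delta extrema flanking the crossing
      jl <- i
      while (jl > 1 && is.finite(delta[jl - 1]) && delta[jl - 1] <= delta[jl]) jl <- jl - 1
      jr <- i + 1
      while (jr < k && is.finite(delta[jr + 1]) && delta[jr + 1] >= delta[jr]) jr <- jr + 1
      strength <- delta[jr] - delta[jl]
      if (!is.finite(strength) || strength < min_strength) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, bin = ii[b], pos = track$end[ii[b]],
        strength = strength, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), bin = integer(), pos = numeric(),
               strength = numeric())
  df <- df[!duplicated(df[c("chrom", "bin")]), , drop = FALSE]
  boundary_set(df, "insulation")
}

#' Hicratio track and boundary calls
#'
#' With flanking windows of `D = floor(d_bp / resolution)` bins either side
#' of bin i, within-window contacts (pairs inside the upstream window plus
#' pairs inside the downstream window) are compared with cross-window
#' contacts (pairs between the two windows) *at matched genomic distances*:
#' for each separation s present in both groups, the ratio of the
#' within-group mean to the cross-group mean is formed, and `ratio_i` is the
#' mean of those per-distance ratios.  Distance matching removes the
#' distance decay from the comparison, so the track is exactly 1 on a
#' translation-invariant matrix and approximately `tau / p` at a boundary
#' of permeability p with within-TAD enrichment tau -- which is what makes
#' the (1, 12] strength filter meaningful.
#'
#' @param m a balanced cis `contact_matrix` (typically 40 kb bins).
#' @param d_bp window size in bp, default 400,000 (D = 10 at 40 kb).
#' @return a `hicratio_track`: data.frame `chrom`, `start`, `end`, `ratio`.
#' @export
hicratio_track <- function(m, d_bp = 400000) {
  D <- floor(d_bp / m$resolution)
  if (D < 3) stop("window smaller than three bins")
  idx <- chrom_bin_index(m$bins)
  n <- nrow(m$bins)
  ratio <- rep(NA_real_, n)
  # offset templates within the (2D+1)-wide neighbourhood of i
  U <- 1:D              # rows/cols 1..D are the upstream window, D+1 is i
  Dn <- (D + 2):(2 * D + 1)
  within_cells <- rbind(
    do.call(rbind, lapply(U, function(r) if (r < D) cbind(r, (r + 1):D)else NULL)),
    do.call(rbind, lapply(Dn, function(r) if (r < 2 * D + 1) cbind(r, (r + 1):(2 * D + 1)) else NULL)))
  cross_cells <- as.matrix(expand.grid(U, Dn))
  within_s <- within_cells[, 2] - within_cells[, 1]
  cross_s <- cross_cells[, 2] - cross_cells[, 1]
  shared <- intersect(unique(within_s), unique(cross_s))
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    k <- length(ii)
    if (k < 2 * D + 1) next
    W <- m$values[ii, ii, drop = FALSE]
    for (i in (D + 1):(k - D)) {
      if (!m$valid[ii[i]]) next
      sub <- W[(i - D):(i + D), (i - D):(i + D)]
      wv <- sub[within_cells]
      cv <- sub[cross_cells]
      rs <- vapply(shared, function(s) {
        a <- mean(wv[within_s == s], na.rm = TRUE)
        x <- mean(cv[cross_s == s], na.rm = TRUE)
        if (!is.finite(a) || !is.finite(x) || x <= 0) return(NA_real_)
        a / x
      }, numeric(1))
      rs <- rs[is.finite(rs)]
      if (length(rs)) ratio[ii[i]] <- mean(rs)
    }
  }
  structure(data.frame(chrom = m$bins$chrom, start = m$bins$start,
                       end = m$bins$end, ratio = ratio,
                       stringsAsFactors = FALSE),
            window_bins = D, resolution = m$resolution,
            class = c("hicratio_track", "data.frame"))
}

#' @rdname hicratio_track
#' @param track a `hicratio_track`.
#' @param threshold minimum ratio for a called boundary (default 1).
#' @param max_window local-maximum window half-width in bins; defaults to D.
#' @return `call_boundaries_hicratio`: a `boundary_set` with method
#'   `"hicratio"` and strength = the ratio at the called bin.
#' @export
call_boundaries_hicratio <- function(track, threshold = 1, max_window = NULL) {
  D <- attr(track, "window_bins")
  if (is.null(max_window)) max_window <- D
  idx <- chrom_bin_index(track)
  rows <- list()
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    r <- track$ratio[ii]
    k <- length(r)
    for (i in seq_len(k)) {
      if (!is.finite(r[i]) || r[i] <= threshold) next
      win <- max(1, i - max_window):min(k, i + max_window)
      wv <- r[win]
      mx <- max(wv, na.rm = TRUE)
      if (r[i] < mx) next
      if (win[which.max(wv)] != i) next  # leftmost bin of a plateau
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, bin = ii[i], pos = track$end[ii[i]],
        strength = r[i], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), bin = integer(), pos = numeric(),
               strength = numeric())
  boundary_set(df, "hicratio")
}

#' Outlier filter for Hicratio boundary statistics
#'
#' Statistics/boxplot views drop boundaries with Hicratio score greater
#' than twelve or not above one, leaving strengths in (1, 12].
#'
#' @param bs a `boundary_set`.
#' @param lo,hi filter bounds (keep `lo < strength <= hi`).
#' @export
filter_boundary_strengths <- function(bs, lo = 1, hi = 12) {
  keep <- is.finite(bs$strength) & bs$strength > lo & bs$strength <= hi
  boundary_set(as.data.frame(bs)[keep, , drop = FALSE], attr(bs, "method"))
}

#' Recall/precision of called boundaries against a truth set
#' @param called,truth `boundary_set` objects.
#' @param tol_bins match tolerance in bins (default 1).
#' @return list with `recall`, `precision`, `n_called`, `n_true`.
#' @export
boundary_recovery <- function(called, truth, tol_bins = 1) {
  hit_true <- vapply(seq_len(nrow(truth)), function(i) {
    any(called$chrom == truth$chrom[i] &
          abs(called$bin - truth$bin[i]) <= tol_bins)
  }, logical(1))
  hit_called <- vapply(seq_len(nrow(called)), function(i) {
    any(truth$chrom == called$chrom[i] &
          abs(truth$bin - called$bin[i]) <= tol_bins)
  }, logical(1))
  list(recall = if (nrow(truth)) mean(hit_true) else NA_real_,
       precision = if (nrow(called)) mean(hit_called) else NA_real_,
       n_called = nrow(called), n_true = nrow(truth))
}
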