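#' Match boundaries between two conditions
#'
#' Greedy nearest matching within `max_offset_bins` on each chromosome;
#' candidate pairs are processed by increasing offset (then position), and
#' each boundary is used at most once.  Unmatched counts are reported in
#' attributes.
#'
#' @param control,treated `boundary_set` objects called with the same method
#'   on the same bin table.
#' @param max_offset_bins matching tolerance, default 1 bin.
#' @return a `boundary_pairs` data.frame: `chrom`, `bin_control`,
#'   `bin_treated`, `strength_control`, `strength_treated`.
#' @export
match_boundaries <- function(control, treated, max_offset_bins = 1) {
  rows <- list()
  used_b <- rep(FALSE, nrow(treated))
  used_a <- rep(FALSE, nrow(control))
  cand <- list()
  for (i in seq_len(nrow(control))) {
    js <- which(treated$chrom == control$chrom[i] &
                  abs(treated$bin - control$bin[i]) <= max_offset_bins)
    for (j in js)
      cand[[length(cand) + 1]] <- c(i, j, abs(treated$bin[j] - control$bin[i]))
  }
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, 3], control$bin[cm[, 1]]), , drop = FALSE]
    for (t in seq_len(nrow(cm))) {
      i <- cm[t, 1]; j <- cm[t, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        chrom = control$chrom[i], bin_control = control$bin[i],
        bin_treated = treated$bin[j],
        strength_control = control$strength[i],
        strength_treated = treated$strength[j], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), bin_control = integer(),
               bin_treated = integer(), strength_control = numeric(),
               strength_treated = numeric())
  structure(df, unmatched_control = sum(!used_a),
            unmatched_treated = sum(!used_b),
            class = c("boundary_pairs", "data.frame"))
}

#' One-sided signed-rank test on matched boundary strengths
#'
#' Wilcoxon signed-rank test with continuity correction on the per-boundary
#' strength differences (treated minus control): exact distribution for
#' fewer than 20 nonzero differences, normal approximation with continuity
#' correction otherwise.  Zero differences are dropped (standard signed-rank
#' convention).
#'
#' @param pairs a `boundary_pairs` data.frame (>= 6 matched pairs).
#' @param direction `"treated_greater"` or `"treated_less"`.
#' @return a `comparison_result`: statistic, one-sided p, n_matched,
#'   n_zero_dropped, direction, method label.
#' @export
boundary_strength_test <- function(pairs,
                                   direction = c("treated_greater", "treated_less")) {
  direction <- match.arg(direction)
  if (nrow(pairs) < 6) stop("need at least 6 matched pairs")
  d <- pairs$strength_treated - pairs$strength_control
  nz <- d != 0
  n <- sum(nz)
  if (n == 0) {
    warning("all strength differences are zero; p = 1")
    return(structure(list(statistic = NA_real_, p_value = 1,
                          n_matched = nrow(pairs), n_zero_dropped = nrow(pairs),
                          direction = direction, method = "wilcoxon signed-rank"),
                     class = "comparison_result"))
  }
  alt <- if (direction == "treated_greater") "greater" else "less"
  wt <- suppressWarnings(stats::wilcox.test(
    pairs$strength_treated, pairs$strength_control, paired = TRUE,
    alternative = alt, exact = n < 20, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_matched = nrow(pairs), n_zero_dropped = sum(!nz),
                 direction = direction, method = "wilcoxon signed-rank"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("boundary strength comparison (", x$method, ")\n", sep = "")
  cat("  n matched:", x$n_matched, " zero differences dropped:",
      x$n_zero_dropped, "\n")
  cat("  V =", signif(x$statistic, 6), " one-sided p (", x$direction, ") =",
      format.pval(x$p_value), "\n")
  invisible(x)
}

#' Distribution summary of matched strength changes
#'
#' Per-pair `treated - control` strength changes with quartiles and box
#' whiskers: the upper whisker extends 1.5 x IQR beyond the upper quartile,
#' the lower whisker 1.5 x IQR below the lower quartile or to the end of
#' the data.
#'
#' @param pairs a `boundary_pairs` data.frame.
#' @return a `strength_summary` list.
#' @export
strength_change_summary <- function(pairs) {
  d <- pairs$strength_treated - pairs$strength_control
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  structure(list(delta = d, n = length(d),
                 q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
                 whisker_low = max(min(d), q[1] - 1.5 * iqr),
                 whisker_high = q[3] + 1.5 * iqr),
            class = "strength_summary")
}

#' @export
print.strength_summary <- function(x, ...) {
  cat("strength changes (treated - control), n =", x$n, "\n")
  cat("  median", signif(x$median, 4), " IQR [", signif(x$q1, 4), ",",
      signif(x$q3, 4), "]  whiskers [", signif(x$whisker_low, 4), ",",
      signif(x$whisker_high, 4), "]\n")
  invisible(x)
}
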