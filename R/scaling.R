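#' Contact frequency versus genomic distance
#'
#' Extracts all cis upper-triangle entries at distance >= 1 bin (the
#' zero-distance diagonal is excluded), with distance in bp.  Masked bins
#' are omitted.
#'
#' @param m a balanced, scaled `contact_matrix`.
#' @param chrom one chromosome name, or NULL for all.
#' @return data.frame with columns `chrom`, `distance` (bp), `value`.
#' @export
contacts_by_distance <- function(m, chrom = NULL) {
  idx <- chrom_bin_index(m$bins)
  if (!is.null(chrom)) {
    if (!chrom %in% names(idx)) stop("unknown chromosome: ", chrom)
    idx <- idx[chrom]
  }
  res <- m$resolution
  out <- lapply(names(idx), function(ch) {
    ii <- idx[[ch]][m$valid[idx[[ch]]]]
    if (length(ii) < 2) return(NULL)
    W <- m$values[ii, ii, drop = FALSE]
    d <- abs(outer(seq_along(ii), seq_along(ii), "-"))
    ut <- upper.tri(W)
    keep <- ut & !is.na(W)
    data.frame(chrom = ch, distance = d[keep] * res, value = W[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||% data.frame(chrom = character(), distance = numeric(),
                                      value = numeric())
}

# per-distance mean contact frequency for one chromosome (positive means only)
distance_profile <- function(m, ch) {
  df <- contacts_by_distance(m, ch)
  if (!nrow(df)) return(NULL)
  agg <- stats::aggregate(value ~ distance, df, mean)
  agg$n <- stats::aggregate(value ~ distance, df, length)$value
  agg[agg$value > 0, , drop = FALSE]
}

#' Loess-smoothed distance-decay (P(s)) curve
#'
#' Per chromosome, the per-distance mean contact frequency is fitted with
#' loess in log10-log10 space (span in log10 distance); the fits are
#' evaluated on a shared log-spaced grid, averaged across chromosomes on the
#' linear scale, and the curve is normalized so its value at the minimum
#' grid distance is exactly 1.
#'
#' @param m a balanced, scaled `contact_matrix`.
#' @param span loess span, default 0.3.
#' @param n_grid grid size, default 50 log-spaced points from one bin to the
#'   longest chromosome's span.
#' @param min_points chromosomes with fewer distance points are skipped with
#'   a warning.
#' @param average `"linear"` (default) or `"log"`: scale on which
#'   per-chromosome fits are averaged.
#' @return a `scaling_curve`: data.frame `distance`, `value`, with the
#'   per-chromosome fit matrix in attribute `per_chromosome`.
#' @export
loess_scaling_curve <- function(m, span = 0.3, n_grid = 50, min_points = 10,
                                average = c("linear", "log")) {
  average <- match.arg(average)
  idx <- chrom_bin_index(m$bins)
  res <- m$resolution
  max_d <- max(vapply(idx, length, integer(1)) - 1) * res
  if (max_d < res) stop("no chromosome has 2 bins")
  grid <- 10^seq(log10(res), log10(max_d), length.out = n_grid)
  fits <- matrix(NA_real_, n_grid, length(idx),
                 dimnames = list(NULL, names(idx)))
  for (ch in names(idx)) {
    prof <- distance_profile(m, ch)
    if (is.null(prof) || nrow(prof) < min_points) {
      if (!is.null(prof)) warning("skipping ", ch, ": too few distance points")
      next
    }
    fit <- try(stats::loess(log10(value) ~ log10(distance), data = prof,
                            weights = prof$n, span = span, degree = 2,
                            control = stats::loess.control(surface = "direct")),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("loess failed on ", ch, "; chromosome skipped")
      next
    }
    in_range <- grid >= min(prof$distance) * (1 - 1e-9) &
      grid <= max(prof$distance) * (1 + 1e-9)
    fits[in_range, ch] <- 10^stats::predict(fit,
                                            data.frame(distance = grid[in_range]))
  }
  if (!any(is.finite(fits))) stop("no chromosome could be fitted")
  avg <- if (average == "linear") {
    rowMeans(fits, na.rm = TRUE)
  } else {
    10^rowMeans(log10(fits), na.rm = TRUE)
  }
  avg[is.nan(avg)] <- NA_real_
  anchor <- avg[which(is.finite(avg))[1]]
  value <- avg / anchor
  structure(data.frame(distance = grid, value = value),
            per_chromosome = fits / anchor, anchor = anchor, span = span,
            class = c("scaling_curve", "data.frame"))
}

#' Log-log slope of a scaling curve
#'
#' Ordinary least-squares slope of log10(value) on log10(distance) over a
#' distance window; the default window is the central decade of the grid
#' (half a decade either side of the grid's geometric midpoint).
#'
#' @param curve a `scaling_curve`.
#' @param from,to distance window in bp.
#' @export
scaling_slope <- function(curve, from = NULL, to = NULL) {
  lo <- log10(min(curve$distance))
  hi <- log10(max(curve$distance))
  mid <- (lo + hi) / 2
  if (is.null(from)) from <- 10^(mid - 0.5)
  if (is.null(to)) to <- 10^(mid + 0.5)
  sel <- curve$distance >= from & curve$distance <= to & is.finite(curve$value) &
    curve$value > 0
  if (sum(sel) < 3) stop("too few finite points in the slope window")
  stats::coef(stats::lm(log10(value) ~ log10(distance), data = curve[sel, ]))[[2]]
}

#' Pointwise ratio of two scaling curves
#' @param a,b `scaling_curve` objects on the same distance grid.
#' @export
scaling_ratio <- function(a, b) {
  if (!isTRUE(all.equal(a$distance, b$distance)))
    stop("scaling curves are on different distance grids")
  structure(data.frame(distance = a$distance, value = a$value / b$value),
            class = c("scaling_curve", "data.frame"))
}

#' @export
plot.scaling_curve <- function(x, ..., log = "xy") {
  graphics::plot(x$distance, x$value, type = "l", log = log,
                 xlab = "genomic distance (bp)",
                 ylab = "normalized contact frequency", ...)
  invisible(x)
}
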