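#' Build a genome bin table
#'
#' Tiles each chromosome with fixed-width bins (the last bin of a chromosome
#' may be shorter).  Coordinates are 0-based, half-open; chromosomes keep the
#' order in which they are supplied (no karyotype sorting).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param resolution bin width in bp.
#' @param assembly free-text assembly label.
#' @return a data.frame with columns `chrom`, `start`, `end` and attributes
#'   `resolution` and `assembly`.
#' @export
make_bin_table <- function(chrom_lengths, resolution, assembly = "synthetic") {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  nm <- names(chrom_lengths)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("chrom_lengths must be a named vector with unique names")
  if (any(chrom_lengths < resolution))
    stop("every chromosome must span at least one bin")
  rows <- lapply(nm, function(ch) {
    len <- as.numeric(chrom_lengths[[ch]])
    n <- as.integer(ceiling(len / resolution))
    start <- (seq_len(n) - 1) * resolution
    data.frame(chrom = ch, start = start, end = pmin(start + resolution, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL
  attr(bins, "resolution") <- as.numeric(resolution)
  attr(bins, "assembly") <- assembly
  bins
}

bin_resolution <- function(bins) {
  r <- attr(bins, "resolution")
  if (is.null(r)) r <- stats::median(bins$end - bins$start)
  as.numeric(r)
}

#' @keywords internal
bins_equal <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(as.character(a$chrom), as.character(b$chrom)) &&
    isTRUE(all.equal(a$start, b$start, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$end, b$end, tolerance = 1e-9))
}

# per-chromosome row indices, in bin-table order
chrom_bin_index <- function(bins) {
  f <- factor(bins$chrom, levels = unique(bins$chrom))
  split(seq_len(nrow(bins)), f)
}

chrom_lengths_from_bins <- function(bins) {
  idx <- chrom_bin_index(bins)
  vapply(idx, function(ii) max(bins$end[ii]), numeric(1))
}
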