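#' Ground-truth generative parameters for a synthetic contact map
#'
#' A `genome_spec` fixes every parameter of the generative model: power-law
#' distance decay `P(s) ~ s^-alpha` plus a long-range/trans floor, a two-state
#' compartment plaid, TAD blocks separated by boundaries of controllable
#' permeability, point loops, per-bin multiplicative biases and optional
#' balanced translocations.  It is the ground truth against which every
#' downstream stage is validated.
#'
#' @param chrom_lengths named numeric vector, bp per chromosome.
#' @param resolution bin width in bp.
#' @param decay_exponent alpha > 0 of the cis contact decay.
#' @param decay_floor trans / long-range background level (>= 0).
#' @param tad_boundaries named list (per chromosome) of bp positions strictly
#'   inside the chromosome, sorted.
#' @param boundary_permeability named list matching `tad_boundaries`; each
#'   value p in (0, 1] multiplies contacts for every boundary crossed.
#'   A scalar is recycled.  Default 0.4.
#' @param within_tad_enrichment tau >= 1 applied to same-TAD pairs.
#' @param compartment_vector per-bin values in \{-1, +1\} (B/A) across the
#'   whole genome; default all +1.
#' @param compartment_amplitude c in [0, 1): plaid modulation `1 + c*v_i*v_j`.
#' @param loops data.frame with columns `bin1`, `bin2` (genome-wide 1-based
#'   bin indices, bin1 < bin2), `enrichment` (>= 1) and `footprint` (odd bin
#'   count, default 3).
#' @param translocations list of lists with fields `chromA`, `bpA`, `chromB`,
#'   `bpB` (reciprocal, clonal by default).
#' @param translocation_fraction mixing fraction of the translocated clone
#'   in (0, 1]; default 1 (fully clonal).
#' @param bin_bias per-bin multiplicative bias > 0 (exercises balancing);
#'   default 1.
#' @param seed integer seed recorded with the spec (sampling functions take
#'   their own explicit seed).
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, resolution,
                        decay_exponent = 1, decay_floor = 1e-4,
                        tad_boundaries = NULL, boundary_permeability = 0.4,
                        within_tad_enrichment = 1,
                        compartment_vector = NULL, compartment_amplitude = 0,
                        loops = NULL, translocations = list(),
                        translocation_fraction = 1,
                        bin_bias = NULL, seed = 1L) {
  bins <- make_bin_table(chrom_lengths, resolution)
  n <- nrow(bins)
  if (is.null(tad_boundaries)) tad_boundaries <- list()
  if (!is.list(boundary_permeability)) {
    boundary_permeability <- lapply(tad_boundaries, function(b)
      rep_len(boundary_permeability, length(b)))
  }
  if (is.null(compartment_vector)) compartment_vector <- rep(1, n)
  if (is.null(bin_bias)) bin_bias <- rep(1, n)
  if (!is.null(loops)) {
    loops <- as.data.frame(loops)
    if (is.null(loops$footprint)) loops$footprint <- 3L
  }
  spec <- structure(list(
    chrom_lengths = chrom_lengths, resolution = as.numeric(resolution),
    decay_exponent = decay_exponent, decay_floor = decay_floor,
    tad_boundaries = tad_boundaries,
    boundary_permeability = boundary_permeability,
    within_tad_enrichment = within_tad_enrichment,
    compartment_vector = compartment_vector,
    compartment_amplitude = compartment_amplitude,
    loops = loops, translocations = translocations,
    translocation_fraction = translocation_fraction,
    bin_bias = bin_bias, seed = as.integer(seed)), class = "genome_spec")
  validate_genome_spec(spec)
  spec
}

#' @export
print.genome_spec <- function(x, ...) {
  nb <- sum(lengths(x$tad_boundaries))
  cat("genome_spec:", length(x$chrom_lengths), "chromosome(s),",
      nrow(spec_bins(x)), "bins @", format(x$resolution, scientific = FALSE), "bp\n")
  cat("  decay alpha =", x$decay_exponent, " floor =", x$decay_floor,
      " tau =", x$within_tad_enrichment, "\n")
  cat("  ", nb, "TAD boundaries;  compartment amplitude =",
      x$compartment_amplitude, ";  ", NROW(x$loops), "loops;  ",
      length(x$translocations), "translocation(s)\n")
  invisible(x)
}

#' @rdname genome_spec
#' @param spec a `genome_spec`.
#' @export
validate_genome_spec <- function(spec) {
  with(spec, {
    stopifnot(decay_exponent > 0, decay_floor >= 0,
              within_tad_enrichment >= 1,
              compartment_amplitude >= 0, compartment_amplitude < 1,
              translocation_fraction > 0, translocation_fraction <= 1)
    n <- nrow(spec_bins(spec))
    stopifnot(length(compartment_vector) == n,
              all(compartment_vector %in% c(-1, 1)),
              length(bin_bias) == n, all(is.finite(bin_bias)),
              all(bin_bias > 0))
    for (ch in names(tad_boundaries)) {
      b <- tad_boundaries[[ch]]
      if (!ch %in% names(chrom_lengths)) stop("unknown chromosome: ", ch)
      if (is.unsorted(b, strictly = TRUE)) stop("boundaries must be strictly sorted")
      if (any(b <= 0 | b >= chrom_lengths[[ch]]))
        stop("boundaries must lie strictly inside ", ch)
      p <- boundary_permeability[[ch]]
      if (length(p) != length(b)) stop("permeability/boundary length mismatch on ", ch)
      if (any(p <= 0 | p > 1)) stop("permeabilities must be in (0, 1]")
    }
    if (!is.null(loops) && nrow(loops)) {
      stopifnot(all(loops$bin1 >= 1), all(loops$bin2 <= n),
                all(loops$enrichment >= 1), all(loops$footprint %% 2 == 1))
      if (any(abs(loops$bin2 - loops$bin1) <= loops$footprint))
        stop("loop anchors must be separated by more than their footprint")
    }
    for (tr in translocations) {
      if (!all(c(tr$chromA, tr$chromB) %in% names(chrom_lengths)))
        stop("translocation references unknown chromosome")
      if (tr$chromA == tr$chromB) stop("translocations must join two chromosomes")
      if (tr$bpA <= 0 || tr$bpA >= chrom_lengths[[tr$chromA]] ||
          tr$bpB <= 0 || tr$bpB >= chrom_lengths[[tr$chromB]])
        stop("translocation breakpoints must lie inside their chromosomes")
    }
  })
  invisible(spec)
}

#' Bin table implied by a genome_spec
#' @param spec a `genome_spec`.
#' @export
spec_bins <- function(spec) {
  make_bin_table(spec$chrom_lengths, spec$resolution)
}

#' Strengthen every planted boundary by a common factor
#'
#' Multiplying permeabilities by a factor in (0, 1] lowers cross-boundary
#' contacts, i.e. strengthens boundaries -- the direction of the effect of
#' ionizing radiation the simulator is built to emulate.
#'
#' @param spec a `genome_spec`.
#' @param factor multiplier in (0, 1].
#' @export
perturb_boundaries <- function(spec, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0, factor <= 1)
  spec$boundary_permeability <- lapply(spec$boundary_permeability,
                                       function(p) pmin(p * factor, 1))
  validate_genome_spec(spec)
  spec
}

#' Append a reciprocal, clonal translocation to a spec
#' @param spec a `genome_spec`.
#' @param chromA,bpA,chromB,bpB fusion breakpoints.
#' @export
insert_translocation <- function(spec, chromA, bpA, chromB, bpB) {
  rec <- list(chromA = chromA, bpA = bpA, chromB = chromB, bpB = bpB)
  for (tr in spec$translocations) {
    same <- (identical(tr, rec)) ||
      (tr$chromA == chromB && tr$bpA == bpB &&
       tr$chromB == chromA && tr$bpB == bpA)
    if (same) stop("duplicate translocation record")
  }
  spec$translocations <- c(spec$translocations, list(rec))
  validate_genome_spec(spec)
  spec
}

#' Ground-truth boundary set of a spec
#'
#' Boundary bin = the last bin of the upstream TAD (genome-wide index);
#' position = the bp breakpoint.  Strengths are `NA` (truth has no measured
#' strength).
#' @param spec a `genome_spec`.
#' @export
true_boundaries <- function(spec) {
  bins <- spec_bins(spec)
  idx <- chrom_bin_index(bins)
  res <- spec$resolution
  rows <- lapply(names(spec$tad_boundaries), function(ch) {
    b <- spec$tad_boundaries[[ch]]
    if (!length(b)) return(NULL)
    local_bin <- floor(b / res)            # last bin before the breakpoint
    data.frame(chrom = ch, bin = idx[[ch]][1] - 1L + local_bin,
               pos = b, strength = NA_real_, stringsAsFactors = FALSE)
  })
  bs <- do.call(rbind, rows)
  boundary_set(bs, method = "truth")
}
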