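#' Noise-free expected contact intensities for a genome_spec
#'
#' For cis pairs at distance `s = max(1, |i - j|)` bins,
#' `E_ij = bias_i * bias_j * (s^-alpha + floor) * (1 + c * v_i * v_j) *
#'  tau^[same TAD] * prod(p_b over boundaries crossed) * loopfactor(i, j)`.
#' Trans pairs get `floor * (1 + c * v_i * v_j)`; a planted translocation
#' adds a cis-like decay term over the fused distance to its trans block.
#'
#' @param spec a [genome_spec()].
#' @return a `contact_matrix` of expected intensities (class also carries
#'   `expected_matrix`).
#' @export
expected_matrix <- function(spec) {
  validate_genome_spec(spec)
  bins <- spec_bins(spec)
  n <- nrow(bins)
  res <- spec$resolution
  alpha <- spec$decay_exponent
  fl <- spec$decay_floor
  idx <- chrom_bin_index(bins)

  E <- matrix(fl, n, n)
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    loc <- seq_along(ii)
    s <- abs(outer(loc, loc, "-"))
    s[s < 1] <- 1
    B <- s^(-alpha) + fl
    bnd <- spec$tad_boundaries[[ch]]
    if (length(bnd)) {
      bb <- floor(bnd / res)                       # boundary sits after bin bb
      perm <- spec$boundary_permeability[[ch]]
      tid <- findInterval(loc - 0.5, bb)           # TAD id per bin
      S <- c(0, cumsum(-log(perm)))[tid + 1]       # cumulative -log p left of bin
      B <- B * exp(-abs(outer(S, S, "-")))
      same <- outer(tid, tid, "==")
      B[same] <- B[same] * spec$within_tad_enrichment
    } else {
      B <- B * spec$within_tad_enrichment          # whole chromosome one TAD
    }
    E[ii, ii] <- B
  }

  # translocations: splice the decay over the fused distance into the trans block
  for (tr in spec$translocations) {
    ii <- idx[[tr$chromA]]; jj <- idx[[tr$chromB]]
    da <- abs(seq_along(ii) - 0.5 - tr$bpA / res)  # bin-center distance to breakpoint
    db <- abs(seq_along(jj) - 0.5 - tr$bpB / res)
    sf <- outer(da, db, "+")
    sf[sf < 1] <- 1
    add <- spec$translocation_fraction * sf^(-alpha)
    E[ii, jj] <- E[ii, jj] + add
    E[jj, ii] <- E[jj, ii] + t(add)
  }

  v <- spec$compartment_vector
  if (spec$compartment_amplitude > 0)
    E <- E * (1 + spec$compartment_amplitude * outer(v, v))

  if (!is.null(spec$loops) && nrow(spec$loops)) {
    for (k in seq_len(nrow(spec$loops))) {
      lp <- spec$loops[k, ]
      r <- (lp$footprint - 1) / 2
      w1 <- max(1, lp$bin1 - r):min(n, lp$bin1 + r)
      w2 <- max(1, lp$bin2 - r):min(n, lp$bin2 + r)
      E[w1, w2] <- E[w1, w2] * lp$enrichment
      E[w2, w1] <- E[w2, w1] * lp$enrichment
    }
  }

  E <- E * outer(spec$bin_bias, spec$bin_bias)
  if (!all(is.finite(E)))
    stop("expected matrix has non-finite entries (overlapping loops?)")
  m <- contact_matrix(bins, E)
  class(m) <- c("expected_matrix", class(m))
  m
}

#' Poisson-sample a count matrix from expected intensities
#'
#' Each upper-triangle entry (diagonal included) is drawn independently as
#' Poisson with mean `depth * E_ij / sum(E upper triangle)`, then mirrored to
#' symmetry.  Fully reproducible for a fixed seed.
#'
#' @param expected an [expected_matrix()] result.
#' @param depth total expected read pairs (> 0).
#' @param seed integer seed.
#' @return an integer-valued `contact_matrix`.
#' @export
sample_counts <- function(expected, depth, seed) {
  stopifnot(inherits(expected, "contact_matrix"))
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("depth must be a positive number")
  V <- expected$values
  if (!all(is.finite(V))) stop("expected matrix has non-finite values")
  n <- nrow(V)
  ut <- upper.tri(V, diag = TRUE)
  lam <- depth * V[ut] / sum(V[ut])
  set.seed(as.integer(seed))
  cnt <- stats::rpois(length(lam), lam)
  M <- matrix(0, n, n)
  M[ut] <- cnt
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  contact_matrix(expected$bins, M)
}
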