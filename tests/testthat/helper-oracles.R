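# Independent brute-force implementations used as oracles.  These are kept
# deliberately naive (element-wise loops, direct formulas) and share no code
# with the package internals they check.

oracle_expected <- function(spec) {
  bins <- spec_bins(spec)
  n <- nrow(bins)
  res <- spec$resolution
  chrom <- as.character(bins$chrom)
  loc <- unlist(lapply(split(seq_len(n), factor(chrom, levels = unique(chrom))),
                       seq_along), use.names = FALSE)
  E <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    compf <- 1 + spec$compartment_amplitude *
      spec$compartment_vector[i] * spec$compartment_vector[j]
    if (chrom[i] == chrom[j]) {
      s <- max(1, abs(loc[i] - loc[j]))
      val <- (s^(-spec$decay_exponent) + spec$decay_floor) * compf
      bnd <- spec$tad_boundaries[[chrom[i]]]
      crossed <- integer(0)
      if (length(bnd)) {
        bb <- floor(bnd / res)
        lo <- min(loc[i], loc[j]); hi <- max(loc[i], loc[j])
        crossed <- which(bb >= lo & bb < hi)
      }
      if (length(crossed)) {
        val <- val * prod(spec$boundary_permeability[[chrom[i]]][crossed])
      } else {
        val <- val * spec$within_tad_enrichment
      }
    } else {
      val <- spec$decay_floor * compf
      for (tr in spec$translocations) {
        fwd <- chrom[i] == tr$chromA && chrom[j] == tr$chromB
        rev_ <- chrom[i] == tr$chromB && chrom[j] == tr$chromA
        if (fwd || rev_) {
          a <- if (fwd) tr$bpA else tr$bpB
          b <- if (fwd) tr$bpB else tr$bpA
          sf <- max(1, abs(loc[i] - 0.5 - a / res) + abs(loc[j] - 0.5 - b / res))
          val <- val + spec$translocation_fraction *
            sf^(-spec$decay_exponent) * compf
        }
      }
    }
    if (!is.null(spec$loops) && nrow(spec$loops)) {
      for (k in seq_len(nrow(spec$loops))) {
        lp <- spec$loops[k, ]
        r <- (lp$footprint - 1) / 2
        if ((abs(i - lp$bin1) <= r && abs(j - lp$bin2) <= r) ||
            (abs(i - lp$bin2) <= r && abs(j - lp$bin1) <= r))
          val <- val * lp$enrichment
      }
    }
    E[i, j] <- val * spec$bin_bias[i] * spec$bin_bias[j]
  }
  E
}

oracle_insulation <- function(V, w) {
  n <- nrow(V)
  I <- rep(NA_real_, n)
  for (i in (w + 1):(n - w))
    I[i] <- mean(V[(i - w):(i - 1), (i + 1):(i + w)])
  gm <- exp(mean(log(I[is.finite(I) & I > 0])))
  log2(I / gm)
}

oracle_hicratio <- function(V, D) {
  n <- nrow(V)
  out <- rep(NA_real_, n)
  for (i in (D + 1):(n - D)) {
    U <- (i - D):(i - 1); Dn <- (i + 1):(i + D)
    wv <- c(); ws <- c(); cv <- c(); cs <- c()
    for (a in U) for (b in U) if (b > a) { wv <- c(wv, V[a, b]); ws <- c(ws, b - a) }
    for (a in Dn) for (b in Dn) if (b > a) { wv <- c(wv, V[a, b]); ws <- c(ws, b - a) }
    for (a in U) for (b in Dn) { cv <- c(cv, V[a, b]); cs <- c(cs, b - a) }
    shared <- intersect(unique(ws), unique(cs))
    rs <- vapply(shared, function(s) mean(wv[ws == s]) / mean(cv[cs == s]),
                 numeric(1))
    out[i] <- mean(rs)
  }
  out
}

oracle_oe <- function(V) {
  n <- nrow(V)
  OE <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    vals <- vapply(1:(n - d), function(i) V[i, i + d], numeric(1))
    mu <- mean(vals)
    if (mu > 0) for (i in 1:(n - d)) {
      OE[i, i + d] <- V[i, i + d] / mu
      OE[i + d, i] <- OE[i, i + d]
    }
  }
  OE
}

oracle_logcor <- function(V) {
  eps <- min(V[V > 0])
  V[V == 0] <- eps
  L <- log(V)
  n <- nrow(L)
  C <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) C[i, j] <- stats::cor(L[i, ], L[, j])
  C
}

# type-7 order-statistic quantile, written out by hand
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exact signed-rank p by full enumeration over sign assignments (no ties)
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  stats <- vapply(0:(2^n - 1), function(mask) {
    sgn <- as.integer(intToBits(mask))[1:n]
    sum(r[sgn == 1])
  }, numeric(1))
  if (alternative == "greater") mean(stats >= W) else mean(stats <= W)
}

# shared tiny fixtures -------------------------------------------------------

# a pure-decay contact matrix (translation-invariant within one chromosome)
decay_matrix <- function(n, res = 40000, alpha = 1, chrom = "chr1") {
  bins <- make_bin_table(stats::setNames(n * res, chrom), res)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  d[d < 1] <- 1
  contact_matrix(bins, d^(-alpha))
}

# one-chromosome spec with equally spaced TAD boundaries
tad_spec <- function(n_tads, tad_bins, p, res = 40000, ...) {
  len <- n_tads * tad_bins * res
  bnd <- seq(tad_bins, (n_tads - 1) * tad_bins, by = tad_bins) * res
  genome_spec(c(chr1 = len), res, tad_boundaries = list(chr1 = bnd),
              boundary_permeability = p, ...)
}

rand_sym_counts <- function(n, seed, res = 40000) {
  set.seed(seed)
  M <- matrix(stats::rpois(n * n, 20), n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  contact_matrix(make_bin_table(c(chr1 = n * res), res), M)
}
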