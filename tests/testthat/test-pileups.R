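test_that("boundary pileups average windows with masking and edge accounting", {
  flat <- decay_matrix(60)
  bs <- boundary_set(data.frame(chrom = "chr1", bin = c(20, 30, 40),
                                pos = c(20, 30, 40) * 40000,
                                strength = c(2, 3, 4)), "insulation")
  p <- boundary_pileup(flat, bs, min_strength = 1, window_bp = 200000,
                       diag_exclusion_bp = 30000)
  expect_equal(p$n_aggregated, 3)
  side <- nrow(p$values)
  expect_equal(side, 11)
  # translation-invariant input: constant along each off-diagonal
  for (k in 1:(side - 1)) {
    vals <- p$values[cbind(1:(side - k), (1 + k):side)]
    expect_lt(max(vals) - min(vals), 1e-12)
  }
  # 30 kb exclusion at 40 kb bins masks exactly the diagonal
  expect_true(all(is.na(diag(p$values))))
  expect_true(all(is.finite(p$values[upper.tri(p$values)])))

  # n = 1 equals the raw sub-matrix; strength filter and edges skip
  one <- boundary_set(data.frame(chrom = "chr1", bin = 25, pos = 25 * 40000,
                                 strength = 5), "insulation")
  p1 <- boundary_pileup(flat, one, window_bp = 200000)
  sub <- flat$values[20:30, 20:30]
  expect_equal(p1$values[!is.na(p1$values)], sub[!is.na(p1$values)])
  edge <- boundary_set(data.frame(chrom = "chr1", bin = c(2, 25),
                                  pos = c(2, 25) * 40000,
                                  strength = c(5, 5)), "insulation")
  pe <- boundary_pileup(flat, edge, window_bp = 200000)
  expect_equal(pe$n_aggregated, 1)
  expect_equal(pe$n_skipped, 1)
  weak <- boundary_set(data.frame(chrom = "chr1", bin = 25, pos = 25 * 40000,
                                  strength = 0.5), "insulation")
  expect_error(boundary_pileup(flat, weak, min_strength = 1), "eligible")
})

test_that("pileup composites are exact log-ratios and antisymmetric differences", {
  flat <- decay_matrix(60)
  bs <- boundary_set(data.frame(chrom = "chr1", bin = c(20, 40),
                                pos = c(20, 40) * 40000,
                                strength = c(2, 2)), "insulation")
  a <- boundary_pileup(flat, bs, window_bp = 200000)
  expect_equal(pileup_log2_ratio(a, a)[!is.na(a$values)],
               rep(0, sum(!is.na(a$values))))
  double <- flat; double$values <- flat$values * 2
  b <- boundary_pileup(double, bs, window_bp = 200000)
  d1 <- pileup_subtract(a, b)
  d2 <- pileup_subtract(b, a)
  expect_equal(d1, -d2)
  small <- boundary_pileup(flat, bs, window_bp = 120000)
  expect_error(pileup_log2_ratio(a, small), "match")
})

test_that("pileup is linear over disjoint boundary sets and order-invariant", {
  m <- rand_sym_counts(80, seed = 61)
  s1 <- boundary_set(data.frame(chrom = "chr1", bin = c(20, 30),
                                pos = c(20, 30) * 40000,
                                strength = c(2, 2)), "insulation")
  s2 <- boundary_set(data.frame(chrom = "chr1", bin = c(50, 60, 70),
                                pos = c(50, 60, 70) * 40000,
                                strength = c(2, 2, 2)), "insulation")
  both <- boundary_set(rbind(as.data.frame(s1), as.data.frame(s2)), "insulation")
  pb <- boundary_pileup(m, both, window_bp = 200000)
  p1 <- boundary_pileup(m, s1, window_bp = 200000)
  p2 <- boundary_pileup(m, s2, window_bp = 200000)
  expect_equal(pb$values, (2 * p1$values + 3 * p2$values) / 5, tolerance = 1e-12)
  shuffled <- boundary_set(as.data.frame(both)[c(4, 1, 5, 2, 3), ], "insulation")
  expect_equal(boundary_pileup(m, shuffled, window_bp = 200000)$values, pb$values)
})

test_that("boundary pileups read out planted permeability", {
  spec <- tad_spec(21, 30, p = 0.3)
  m <- scale_to_total(sample_counts(expected_matrix(spec), 1e7, 62))
  p <- boundary_pileup(m, true_boundaries(spec), min_strength = 0)
  expect_equal(p$n_aggregated, 20)
  est <- pileup_permeability(p)
  expect_lt(abs(est / 0.3 - 1), 0.1)

  # treated-vs-control ratio concentrates negative signal across the boundary
  trt <- perturb_boundaries(spec, 0.5)
  mt <- scale_to_total(sample_counts(expected_matrix(trt), 1e7, 63))
  pt <- boundary_pileup(mt, true_boundaries(trt), min_strength = 0)
  rat <- pileup_log2_ratio(pt, p)
  side <- nrow(rat)
  Wc <- (side + 1) / 2
  cross <- row(rat) < Wc & col(rat) > Wc
  within <- (row(rat) < Wc & col(rat) < Wc) | (row(rat) > Wc & col(rat) > Wc)
  expect_lt(mean(rat[cross], na.rm = TRUE), -0.5)
  expect_lt(abs(mean(rat[within & row(rat) != col(rat)], na.rm = TRUE)), 0.1)
})

test_that("loop pileups recover planted enrichment with a flat shifted null", {
  res <- 40000
  n <- 400
  loops <- data.frame(bin1 = seq(30, 330, by = 30), bin2 = seq(60, 360, by = 30),
                      enrichment = 3, footprint = 3)
  sp <- genome_spec(c(chr1 = n * res), res, decay_floor = 1e-4, loops = loops)
  m <- scale_to_total(sample_counts(expected_matrix(sp), 1e7, 64))
  lp <- loop_pileup(m, loops)
  expect_equal(lp$n_aggregated, nrow(loops))
  expect_lt(abs(pileup_loop_enrichment(lp) / 3 - 1), 0.15)
  # single loop: pileup equals its sub-matrix
  l1 <- loop_pileup(m, loops[3, ])
  expect_equal(l1$values, m$values[(loops$bin1[3] - 10):(loops$bin1[3] + 10),
                                   (loops$bin2[3] - 10):(loops$bin2[3] + 10)])
  # anchors shifted off the planted loops: no enrichment
  sh <- loops
  sh$bin1 <- sh$bin1 + 15
  sh$bin2 <- sh$bin2 + 15
  expect_lt(abs(pileup_loop_enrichment(loop_pileup(m, sh)) - 1), 0.15)
  expect_error(loop_pileup(m, loops[0, ]), "empty")
  # BEDPE-style input addresses the same bins
  bins <- sp |> spec_bins()
  bed <- data.frame(chrom1 = "chr1", start1 = bins$start[loops$bin1],
                    end1 = bins$end[loops$bin1], chrom2 = "chr1",
                    start2 = bins$start[loops$bin2], end2 = bins$end[loops$bin2])
  expect_equal(loop_pileup(m, bed)$values, lp$values)
})
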