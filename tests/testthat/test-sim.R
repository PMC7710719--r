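test_that("expected matrix reduces to pure decay when structure is off", {
  spec <- genome_spec(c(chr1 = 30 * 40000), 40000, decay_exponent = 1.3,
                      decay_floor = 1e-3, within_tad_enrichment = 1)
  E <- expected_matrix(spec)$values
  # translation-invariant: depends only on |i - j|
  for (d in 0:29) {
    diag_vals <- E[cbind(1:(30 - d), (1 + d):30)]
    expect_equal(max(diag_vals) - min(diag_vals), 0)
  }
  # cis decay is monotone decreasing off the diagonal
  expect_true(all(diff(E[1, 2:30]) < 0))
})

test_that("a single boundary attenuates cross-TAD contacts by exactly p", {
  spec <- genome_spec(c(chr1 = 40 * 40000), 40000,
                      tad_boundaries = list(chr1 = 20 * 40000),
                      boundary_permeability = list(chr1 = 0.5),
                      within_tad_enrichment = 1)
  E <- expected_matrix(spec)$values
  # compare same-distance pairs: within TAD 1 vs across the boundary
  for (d in 1:10) {
    within <- E[5, 5 + d]
    cross <- E[20 - d + 1, 21]   # spans bins 20|21, distance d
    expect_equal(cross / within, 0.5, tolerance = 1e-12)
  }
})

test_that("expected matrix matches the element-wise brute-force oracle", {
  loops <- data.frame(bin1 = c(5, 22), bin2 = c(12, 33),
                      enrichment = c(2, 4), footprint = 3)
  set.seed(11)
  v <- sample(c(-1, 1), 40, replace = TRUE)
  bias <- exp(stats::rnorm(40, 0, 0.3))
  spec <- genome_spec(c(chr1 = 40 * 40000), 40000, decay_exponent = 1,
                      decay_floor = 1e-3,
                      tad_boundaries = list(chr1 = c(13, 27) * 40000),
                      boundary_permeability = list(chr1 = c(0.3, 0.7)),
                      within_tad_enrichment = 2,
                      compartment_vector = v, compartment_amplitude = 0.3,
                      loops = loops, bin_bias = bias)
  E <- expected_matrix(spec)$values
  O <- oracle_expected(spec)
  expect_equal(E, O, tolerance = 1e-12)
})

test_that("oracle equivalence holds on a multi-chromosome spec with a translocation", {
  spec <- genome_spec(c(chrA = 15 * 40000, chrB = 12 * 40000), 40000,
                      decay_exponent = 1.1, decay_floor = 0.01,
                      tad_boundaries = list(chrA = 7 * 40000),
                      boundary_permeability = list(chrA = 0.4))
  spec <- insert_translocation(spec, "chrA", 10 * 40000, "chrB", 4 * 40000)
  expect_equal(expected_matrix(spec)$values, oracle_expected(spec),
               tolerance = 1e-12)
})

test_that("expected matrices are symmetric and positive for randomized specs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:40, 1)
    spec <- genome_spec(c(chr1 = n * 40000), 40000,
                        decay_exponent = stats::runif(1, 0.6, 1.8),
                        decay_floor = stats::runif(1, 1e-4, 1e-2),
                        tad_boundaries = list(chr1 = sort(sample(2:(n - 2), 3)) * 40000),
                        boundary_permeability = list(chr1 = stats::runif(3, 0.2, 1)),
                        within_tad_enrichment = stats::runif(1, 1, 2),
                        compartment_vector = sample(c(-1, 1), n, replace = TRUE),
                        compartment_amplitude = stats::runif(1, 0, 0.5),
                        bin_bias = exp(stats::rnorm(n, 0, 0.3)))
    E <- expected_matrix(spec)$values
    expect_equal(E, t(E))
    expect_true(all(E > 0))
  }
})

test_that("poisson sampling honors depth, determinism and the mean contract", {
  spec <- genome_spec(c(chr1 = 20 * 40000), 40000, decay_floor = 0.01)
  E <- expected_matrix(spec)
  expect_error(sample_counts(E, 0, seed = 1), "positive")
  m1 <- sample_counts(E, 1e6, seed = 3)
  # total sampled read pairs (each pair counted once: upper triangle)
  pairs_total <- sum(m1$values[upper.tri(m1$values, diag = TRUE)])
  expect_lt(abs(pairs_total - 1e6), 4 * sqrt(1e6))
  expect_true(all(m1$values == round(m1$values)))
  m2 <- sample_counts(E, 1e6, seed = 3)
  expect_identical(m1$values, m2$values)
  expect_false(identical(m1$values, sample_counts(E, 1e6, seed = 4)$values))
  # Monte-Carlo mean of one entry over 200 seeds
  ut_sum <- sum(E$values[upper.tri(E$values, diag = TRUE)])
  lam <- 1e5 * E$values[3, 9] / ut_sum
  draws <- vapply(1:200, function(s) sample_counts(E, 1e5, seed = s)$values[3, 9],
                  numeric(1))
  se <- sqrt(lam / 200)
  expect_lt(abs(mean(draws) - lam), 3 * se)
})

test_that("perturb_boundaries rescales permeabilities and strengthens boundaries", {
  spec <- tad_spec(4, 10, p = 0.4, within_tad_enrichment = 1)
  expect_identical(perturb_boundaries(spec, 1), spec)
  expect_equal(perturb_boundaries(spec, 0.5)$boundary_permeability$chr1,
               rep(0.2, 3))
  expect_error(perturb_boundaries(spec, 0))
  E0 <- expected_matrix(spec)$values
  E1 <- expected_matrix(perturb_boundaries(spec, 0.5))$values
  # at every boundary the cross/within contact ratio strictly drops
  for (b in c(10, 20, 30)) {
    r0 <- E0[b, b + 1] / E0[b, b - 1]
    r1 <- E1[b, b + 1] / E1[b, b - 1]
    expect_lt(r1, r0)
  }
})

test_that("translocations are local, additive and detectable in ratio maps", {
  base <- genome_spec(c(chrA = 30 * 40000, chrB = 25 * 40000,
                        chrC = 20 * 40000), 40000, decay_floor = 0.01)
  tr1 <- insert_translocation(base, "chrA", 15 * 40000, "chrB", 10 * 40000)
  expect_error(insert_translocation(tr1, "chrA", 15 * 40000, "chrB", 10 * 40000),
               "duplicate")
  E0 <- expected_matrix(base)$values
  E1 <- expected_matrix(tr1)$values
  iA <- 1:30; iB <- 31:55; iC <- 56:75
  expect_equal(E1[iA, iA], E0[iA, iA])
  expect_equal(E1[iC, c(iA, iB)], E0[iC, c(iA, iB)])
  expect_false(isTRUE(all.equal(E1[iA, iB], E0[iA, iB])))
  # disjoint chromosome pairs act independently
  tr2 <- insert_translocation(tr1, "chrB", 5 * 40000, "chrC", 8 * 40000)
  only2 <- insert_translocation(base, "chrB", 5 * 40000, "chrC", 8 * 40000)
  E12 <- expected_matrix(tr2)$values
  expect_equal(E12[iA, iB], E1[iA, iB])
  expect_equal(E12[iB, iC], expected_matrix(only2)$values[iB, iC])
  # sampled log2 ratio map peaks at the fused corner
  mc <- scale_to_total(sample_counts(expected_matrix(base), 5e6, 1))
  mt <- scale_to_total(sample_counts(expected_matrix(tr1), 5e6, 2))
  rat <- log2_ratio_map(mt, mc)
  trans <- rat$values[iA, iB]
  peak <- which(trans == max(trans), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak[1] - 15), 1)   # bpA sits at bin 15|16
  expect_lte(abs(peak[2] - 10), 1)
})
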