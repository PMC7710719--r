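test_that("dense-tsv matrices round-trip through write/read", {
  m <- rand_sym_counts(3, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  m2 <- read_matrix(path)
  expect_identical(m2$values, m$values)
  expect_equal(m2$bins$start, m$bins$start)
  expect_identical(as.character(m2$bins$chrom), as.character(m$bins$chrom))
  # masked bins and non-integer values survive too
  b <- scale_to_total(ice_balance(rand_sym_counts(25, seed = 2)), 1e6)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(b, path2)
  b2 <- read_matrix(path2)
  expect_equal(b2$values, b$values, tolerance = 1e-12)
  expect_identical(b2$valid, b$valid)
  expect_true(b2$balanced)
})

test_that("malformed matrices are rejected", {
  bins <- make_bin_table(c(chr1 = 4 * 40000), 40000)
  expect_error(contact_matrix(bins, matrix(1, 5, 5)), "4 bins")
  asym <- matrix(1, 4, 4); asym[1, 2] <- 2
  expect_error(contact_matrix(bins, asym), "asymmetric")
  expect_error(contact_matrix(bins, -matrix(1, 4, 4)), "nonnegative")
  expect_error(read_matrix("nope.tsv", format = "cooler"), "cooler")
  # file whose bin table and matrix body disagree
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- rand_sym_counts(4, seed = 3)
  txt <- readLines(write_matrix(m, path))
  writeLines(c(txt, paste(rep(1, 4), collapse = "\t")), path)
  expect_error(read_matrix(path), "body holds")
})

test_that("ice_balance equalizes marginals and finds the known 2x2 scaling", {
  # [[4,2],[2,1]] = outer((2,1),(2,1)): bias proportional to (2,1)
  bins <- make_bin_table(c(chr1 = 2 * 40000), 40000)
  m <- contact_matrix(bins, matrix(c(4, 2, 2, 1), 2))
  b <- ice_balance(m, tol = 1e-10, algorithm = "ice", max_iter = 5000)
  expect_equal(b$bias[1] / b$bias[2], 2, tolerance = 1e-6)
  s <- rowSums(b$values)
  expect_lt(stats::sd(s) / mean(s), 1e-9)
  # corrections 1/bias are proportional to (1/2, 1)
  expect_equal((1 / b$bias)[1] / (1 / b$bias)[2], 0.5, tolerance = 1e-6)

  # an already-balanced matrix is a fixed point
  flat <- contact_matrix(bins, matrix(c(2, 1, 1, 2), 2))
  f <- ice_balance(flat, tol = 1e-8)
  expect_equal(f$values, flat$values, tolerance = 1e-6)
  expect_equal(f$bias, c(1, 1), tolerance = 1e-6)

  # KR and classic iteration agree on the same matrix
  mm <- rand_sym_counts(20, seed = 4)
  kr <- ice_balance(mm, tol = 1e-8)
  ice <- ice_balance(mm, tol = 1e-8, algorithm = "ice", max_iter = 20000)
  expect_equal(kr$bias, ice$bias, tolerance = 1e-4)
})

test_that("balancing recovers planted bin biases from sampled counts", {
  n <- 200
  set.seed(5)
  bias <- exp(stats::rnorm(n, 0, 0.3))
  spec <- genome_spec(c(chr1 = n * 40000), 40000, decay_floor = 1e-3,
                      bin_bias = bias)
  m <- sample_counts(expected_matrix(spec), 2e6, seed = 6)
  b <- ice_balance(m)
  ok <- !is.na(b$bias)
  expect_gt(stats::cor(b$bias[ok], bias[ok]), 0.95)
})

test_that("scale_to_total hits the target exactly and is idempotent", {
  m <- rand_sym_counts(15, seed = 7)
  s <- scale_to_total(m, 1e6)
  expect_equal(matrix_total(s), 1e6, tolerance = 1e-9)
  expect_equal(scale_to_total(s, 1e6)$values, s$values, tolerance = 1e-12)
  already <- scale_to_total(m, matrix_total(m))
  expect_equal(already$values, m$values, tolerance = 1e-12)
  zero <- contact_matrix(make_bin_table(c(chr1 = 2 * 40000), 40000),
                         matrix(0, 2, 2))
  expect_error(scale_to_total(zero), "positive")
})

test_that("balance and scale commute up to the final scaling", {
  m <- rand_sym_counts(30, seed = 8)
  a <- scale_to_total(ice_balance(m, tol = 1e-8))
  b <- scale_to_total(ice_balance(scale_to_total(m), tol = 1e-8))
  expect_equal(a$values, b$values, tolerance = 1e-6)
})

test_that("rebin sums counts, conserves totals and respects chromosomes", {
  bins <- make_bin_table(c(chr1 = 4 * 40000), 40000)
  ones <- contact_matrix(bins, matrix(1, 4, 4))
  r <- rebin(ones, 80000)
  expect_equal(r$values, matrix(4, 2, 2))
  expect_identical(rebin(ones, 40000), ones)
  expect_error(rebin(ones, 60000), "multiple")

  m <- rand_sym_counts(24, seed = 9)
  expect_equal(matrix_total(rebin(m, 120000)), matrix_total(m))

  # chromosome boundaries are never straddled
  two <- genome_spec(c(a = 5 * 40000, b = 5 * 40000), 40000, decay_floor = 0.1)
  mm <- sample_counts(expected_matrix(two), 1e5, seed = 1)
  rb <- rebin(mm, 80000)
  expect_equal(nrow(rb$bins), 3 + 3)   # ceiling(5/2) each
  expect_equal(as.character(rb$bins$chrom), rep(c("a", "b"), each = 3))
})

test_that("log2 ratio maps behave like log ratios", {
  m <- rand_sym_counts(10, seed = 10)
  expect_equal(log2_ratio_map(m, m)$values, matrix(0, 10, 10))
  twice <- m; twice$values <- m$values * 2
  r <- log2_ratio_map(twice, m, pseudocount = 1e-12)
  expect_equal(r$values, matrix(1, 10, 10), tolerance = 1e-6)
  other <- rand_sym_counts(11, seed = 11)
  expect_error(log2_ratio_map(m, other), "differ")
})

test_that("operations preserve symmetry and never unmask masked bins", {
  m <- rand_sym_counts(20, seed = 12)
  m$valid[c(3, 17)] <- FALSE
  m$values[c(3, 17), ] <- NA_real_
  m$values[, c(3, 17)] <- NA_real_
  for (op in list(function(x) ice_balance(x),
                  function(x) scale_to_total(x),
                  function(x) observed_expected(scale_to_total(x)))) {
    out <- op(m)
    expect_equal(out$values, t(out$values))
    expect_true(all(is.na(out$values[c(3, 17), ])))
  }
  r <- rebin(m, 80000)
  expect_equal(r$values, t(r$values))
  rat <- log2_ratio_map(m, m)
  expect_true(all(is.na(rat$values[c(3, 17), ])))
})
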