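test_that("expected heterozygosity matches plug-in and sample-corrected forms", {
  expect_equal(expected_heterozygosity(1.0), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  # 10/9 * 1/2, exact fractions
  expect_equal(expected_heterozygosity(c(0.5, 0.5), n = 10, unbiased = TRUE),
               5 / 9, tolerance = 1e-12)
  expect_error(expected_heterozygosity(c(0.5, 0.5), unbiased = TRUE),
               "sample size")
  expect_error(expected_heterozygosity(c(0.6, 0.6)), "sum to")
  expect_error(expected_heterozygosity(c(-0.1, 1.1)), "\\[0, 1\\]")
})

test_that("frequencies within tolerance are renormalized, larger deviations rejected", {
  # 1e-7 off: silently renormalized
  h <- expected_heterozygosity(c(0.5, 0.5 - 1e-7))
  expect_equal(h, 0.5, tolerance = 1e-6)
  expect_error(check_freqs(c(0.4, 0.4)), "sum to")
})

test_that("haplotype diversity applies the n/(n-1) correction", {
  expect_equal(haplotype_diversity(5), 0)
  expect_equal(haplotype_diversity(c(1, 1, 1, 1)), 1)
  expect_equal(haplotype_diversity(c(3, 1)), 0.5)
  expect_error(haplotype_diversity(c(0, 2)), "positive")
})

test_that("mean pairwise differences agree between SFS and matrix routes", {
  expect_equal(mean_pairwise_differences(sfs(c(0, 0, 0), n = 4)), 0)
  expect_equal(mean_pairwise_differences(sfs(3, n = 2)), 3)
  expect_equal(mean_pairwise_differences(sfs(c(2, 1, 0), n = 4)), 5 / 3)
  # explicit matrix realizing SFS (2, 1, 0): brute-force enumeration
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 1))
  expect_equal(sfs_from_matrix(m), c(2, 1, 0))
  expect_equal(oracle_k_matrix(m), 5 / 3)
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  expect_equal(mean_pairwise_differences(d), 5 / 3)
})

test_that("folded spectra give the same k as their unfolded source", {
  unf <- sfs(c(2, 1, 1), n = 4)
  fol <- sfs(c(2 + 1, 1), n = 4, folded = TRUE)  # classes 3 fold onto 1
  expect_equal(mean_pairwise_differences(unf), mean_pairwise_differences(fol))
})

test_that("nucleotide diversity is k/L with the product identity pi * L = k", {
  expect_equal(nucleotide_diversity(0, 100), 0)
  expect_equal(nucleotide_diversity(5, 100), 0.05)
  k <- mean_pairwise_differences(sfs(c(2, 1, 0), n = 4))
  pi <- nucleotide_diversity(k, 50)
  expect_identical(pi * 50, k)
  expect_error(nucleotide_diversity(5, 0), "L")
})

test_that("PIC matches exact-fraction evaluations and is bounded by heterozygosity", {
  expect_equal(pic(1.0), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(1, 3) / 3), 48 / 81, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    p <- as.vector(stats::rmultinom(1, 40, stats::runif(sample(2:6, 1)))) / 40
    p <- p[p > 0]
    expect_lte(pic(p), expected_heterozygosity(p) + 1e-12)
    expect_gte(pic(p), 0)
    expect_lte(expected_heterozygosity(p), 1)
  }
})
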