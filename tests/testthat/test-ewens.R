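test_that("Ewens pmf matches closed forms and the rising-factorial oracle", {
  expect_equal(ewens_k_pmf(5, 0), c(1, 0, 0, 0, 0))
  expect_equal(ewens_k_pmf(2, 1), c(0.5, 0.5), tolerance = 1e-12)
  # theta/(1+theta) closed form at n = 2 for several theta
  for (th in c(0.1, 1, 10))
    expect_equal(ewens_k_pmf(2, th), c(1, th) / (1 + th), tolerance = 1e-12)
  # exact fractions at n = 4, theta = 2 via Stirling numbers 6, 11, 6, 1
  expect_equal(ewens_k_pmf(4, 2), c(1 / 10, 11 / 30, 2 / 5, 2 / 15),
               tolerance = 1e-12)
  # Stirling route cross-check: pmf proportional to |s(n,k)| theta^k
  n <- 8; th <- 1.7
  s <- oracle_stirling1(n)
  expected <- s * th^seq_len(n) / sum(s * th^seq_len(n))
  expect_equal(ewens_k_pmf(n, th), expected, tolerance = 1e-12)
  expect_error(ewens_k_pmf(5, -1), "theta")
})

test_that("Ewens pmf normalizes to 1 for n up to 50", {
  for (n in c(2, 5, 10, 25, 50))
    for (th in c(0.1, 1, 10))
      expect_equal(sum(ewens_k_pmf(n, th)), 1, tolerance = 1e-9)
})

test_that("haplotype tests: Strobeck, Fu W/Fs, Watterson homozygosity", {
  expect_equal(haplotype_tests(2, theta = 1)$strobeck_s, 0.5,
               tolerance = 1e-12)                      # n = 2, K = 1
  expect_equal(haplotype_tests(c(1, 1), theta = 1)$fu_fs, 0,
               tolerance = 1e-12)                      # S' = 0.5
  expect_equal(haplotype_tests(5, theta = 2)$watterson_w, 1)
  # theta defaults to k but is never estimated silently
  expect_equal(haplotype_tests(c(2, 1), k = 1.5)$strobeck_s,
               haplotype_tests(c(2, 1), theta = 1.5)$strobeck_s)
  expect_error(haplotype_tests(c(2, 1)), "theta")
  expect_error(haplotype_tests(c(2, 1), theta = 0), "theta")
})

test_that("Strobeck's S and the K+1 upper tail are complementary", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    th <- stats::runif(1, 0.1, 10)
    K <- sample.int(n, 1)
    pmf <- ewens_k_pmf(n, th)
    lower <- sum(pmf[seq_len(K)])
    upper <- if (K == n) 0 else sum(pmf[(K + 1):n])
    expect_equal(lower + upper, 1, tolerance = 1e-9)
    counts <- c(rep(1, K - 1), n - K + 1)
    expect_equal(haplotype_tests(counts, theta = th)$strobeck_s, lower,
                 tolerance = 1e-12)
  }
})

test_that("Fu's Fs overflows to the infinite sentinel at degenerate tails", {
  # K = 1 makes S' = P(K >= 1) = 1 exactly
  expect_identical(haplotype_tests(4, theta = 1)$fu_fs, Inf)
})
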