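test_that("harmonic constants reproduce exact harmonic sums", {
  expect_equal(harmonic_constants(2)[c("a1", "a2")], list(a1 = 1, a2 = 1))
  expect_equal(harmonic_constants(4)$a1, 11 / 6, tolerance = 1e-12)
  expect_equal(harmonic_constants(5)$a1, 25 / 12, tolerance = 1e-12)
  expect_equal(harmonic_constants(5)$a2, 205 / 144, tolerance = 1e-12)
  expect_error(harmonic_constants(1), "n")
})

test_that("Watterson's theta estimator is S over the harmonic number", {
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(5, 2), 5)
  expect_equal(watterson_theta(10, 5), 4.8, tolerance = 1e-12)
})

test_that("Tajima's D matches the exact-rational oracle and its zero contract", {
  # frozen from an exact-fraction evaluation of all constants
  expect_equal(tajima_d(n = 4, S = 3, k = 2), 2.011869540407391,
               tolerance = 1e-9)
  a1 <- harmonic_constants(7)$a1
  expect_equal(tajima_d(n = 7, S = 5, k = 5 / a1), 0)
  expect_identical(tajima_d(n = 4, S = 0, k = 0), NA_real_)
})

test_that("Fu-Li tests match the pre-implementation exact-fraction oracle", {
  res <- fu_li_tests(n = 5, eta = 4, k = 1.8, eta_s = 1, eta_e = 1)
  expect_equal(res$D, 0.7565260847995368, tolerance = 1e-9)
  expect_equal(res$F, 0.5574364040727249, tolerance = 1e-9)
  expect_equal(res$D_star, 0.9570741825955765, tolerance = 1e-9)
  expect_equal(res$F_star, 0.4336178381751821, tolerance = 1e-9)
})

test_that("Fu-Li numerator-zero and eta-zero contracts hold", {
  # n = 2 has a_n = 1, so eta = eta_e makes the D numerator vanish exactly
  expect_equal(fu_li_tests(n = 2, eta = 1, eta_e = 1)$D, 0)
  expect_identical(fu_li_tests(n = 5, eta = 0, eta_e = 0)$D, NA_real_)
  expect_error(fu_li_tests(n = 5, eta = 4, tests = "D"), "missing inputs")
  expect_error(fu_li_tests(n = 2, eta = 1, eta_s = 1, tests = "D_star"),
               "missing inputs")
})

test_that("Fay-Wu/Zeng estimators match exact fractions and known identities", {
  res <- fay_wu_zeng(sfs(c(2, 1, 0), n = 4))
  expect_equal(res$theta_pi, 5 / 3, tolerance = 1e-12)
  expect_equal(res$theta_h, 1, tolerance = 1e-12)
  expect_equal(res$H, 2 / 3, tolerance = 1e-12)
  # H = 2 (theta_pi - theta_L) identity
  expect_equal(res$H, 2 * (res$theta_pi - res$theta_l), tolerance = 1e-12)
  # n = 2: theta_pi == theta_H for any singleton count
  expect_equal(fay_wu_zeng(sfs(7, n = 2))$H, 0)
  z <- fay_wu_zeng(sfs(c(0, 0, 0), n = 4))
  expect_equal(z$H, 0)
  expect_identical(z$Hn, NA_real_)
  expect_identical(z$E, NA_real_)
  expect_error(fay_wu_zeng(sfs(c(2, 1), n = 4, folded = TRUE)), "unfolded")
})

test_that("normalized Hn and E match the pre-implementation fraction oracle", {
  res <- fay_wu_zeng(sfs(c(3, 2, 1, 1, 0), n = 6))
  expect_equal(res$Hn, 0.46898296400168, tolerance = 1e-9)
  expect_equal(res$E, -0.3159525654893443, tolerance = 1e-9)
})

test_that("theta_pi equals mean pairwise differences on the same SFS", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    counts <- stats::rpois(n - 1, 2)
    expect_equal(fay_wu_zeng(sfs(counts, n = n))$theta_pi,
                 mean_pairwise_differences(sfs(counts, n = n)),
                 tolerance = 1e-12)
  }
})
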