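test_that("Nei decomposition matches exact fractions on the 0.7/0.3 table", {
  d <- nei_decomposition(two_pop_table())
  expect_equal(d$J_S, 0.58, tolerance = 1e-12)
  expect_equal(d$H_T, 0.5, tolerance = 1e-12)
  expect_equal(d$G_ST, 0.16, tolerance = 1e-12)
  expect_equal(d$D_ST, d$H_T - d$H_S, tolerance = 1e-12)
})

test_that("identical and fixed-alternative populations hit the extremes", {
  same <- rbind(c(0.4, 0.6), c(0.4, 0.6), c(0.4, 0.6))
  d <- nei_decomposition(same)
  expect_equal(d$G_ST, 0, tolerance = 1e-12)
  expect_equal(wright_f(same)$F_ST, 0, tolerance = 1e-12)
  fixed <- rbind(c(1, 0), c(0, 1))
  d <- nei_decomposition(fixed)
  expect_equal(d$H_S, 0)
  expect_equal(d$H_T, 0.5)
  expect_equal(d$G_ST, 1)
  expect_equal(hedrick_gst_prime(d$G_ST, d$H_S, 2), 1)
  expect_equal(jost_d(d$H_T, d$H_S, 2), 1)
  # same allele fixed everywhere: H_T = 0, undefined
  expect_identical(nei_decomposition(rbind(c(1, 0), c(1, 0)))$G_ST, NA_real_)
})

test_that("Hedrick's G'ST and Jost's D match exact fractions and bounds", {
  expect_equal(hedrick_gst_prime(0.16, 0.42, 2), 0.16 * 1.42 / 0.58,
               tolerance = 1e-12)
  expect_equal(hedrick_gst_prime(0, 0.3, 4), 0)
  expect_identical(hedrick_gst_prime(0.2, 1, 2), NA_real_)
  expect_equal(jost_d(0.5, 0.42, 2), 2 * 0.08 / 0.58, tolerance = 1e-12)
  expect_identical(jost_d(0.5, 1, 2), NA_real_)
  # G'ST >= GST whenever both defined
  set.seed(9)
  for (i in 1:25) {
    tab <- simulate_population_freqs(3, 3, concentration = 2, n_i = 60)
    d <- nei_decomposition(tab)
    if (!is.na(d$G_ST) && d$H_S < 1) {
      g <- hedrick_gst_prime(d$G_ST, d$H_S, tab$r)
      expect_gte(g - d$G_ST, -1e-12)
      expect_lte(g, 1 + 1e-9)
      expect_gte(jost_d(d$H_T, d$H_S, tab$r), -1e-12)
    }
  }
})

test_that("weighted and unweighted FST coincide only under equal sizes", {
  tab_eq <- pop_freqs(two_pop_table(), n = c(50, 50))
  f <- wright_f(tab_eq)
  expect_equal(f$F_ST, f$F_ST_weighted, tolerance = 1e-12)
  tab_uneq <- pop_freqs(two_pop_table(), n = c(20, 80))
  f <- wright_f(tab_uneq)
  expect_false(isTRUE(all.equal(f$F_ST, f$F_ST_weighted)))
  # oracle under unequal weights: pbar = 0.2*0.7 + 0.8*0.3 = 0.38
  hs_w <- 0.2 * 0.42 + 0.8 * 0.42
  ht_w <- 1 - (0.38^2 + 0.62^2)
  expect_equal(f$F_ST_weighted, (ht_w - hs_w) / ht_w, tolerance = 1e-12)
})

test_that("FIS is zero at Hardy-Weinberg observed heterozygosity", {
  tab <- two_pop_table()
  f <- wright_f(tab, obs_het = c(0.42, 0.42))
  expect_equal(f$F_IS, 0, tolerance = 1e-12)
  expect_identical(wright_f(tab)$F_IS, NA_real_)
  expect_error(wright_f(tab, obs_het = 0.4), "per subpopulation")
})

test_that("RST matches the variance-component oracle and extremes", {
  expect_equal(slatkin_rst(list(c(10, 12), c(14, 16))), 0.7,
               tolerance = 1e-12)
  expect_equal(slatkin_rst(list(c(10, 12), c(10, 12))), 1 - 2 / var(c(10, 12, 10, 12)),
               tolerance = 1e-12)
  expect_equal(slatkin_rst(list(c(10, 10), c(20, 20))), 1)
  expect_identical(slatkin_rst(list(c(10, 10), c(10, 10))), NA_real_)
})

test_that("Weir-Cockerham estimators match the exact-fraction oracle", {
  wc <- weir_cockerham(wc_fixture())
  # frozen: a = 19/180, b = 1/30, c = 1/6
  expect_equal(wc$theta_W, (19 / 180) / (19 / 180 + 1 / 30 + 1 / 6),
               tolerance = 1e-12)
  expect_equal(wc$f_W, 1 / 6, tolerance = 1e-12)
  # biallelic: the allele-combination variants coincide
  expect_equal(wc$theta_U, wc$theta_W, tolerance = 1e-12)
  expect_equal(wc$theta_RH, wc$theta_W, tolerance = 1e-12)
})

test_that("Weir-Cockerham extremes: fixed pops give theta 1, HWE gives small f", {
  fixed <- data.frame(pop = c("A", "B"),
                      allele1 = c("1", "2"), allele2 = c("1", "2"),
                      count = c(8, 8))
  expect_equal(weir_cockerham(fixed)$theta_W, 1, tolerance = 1e-12)
  # identical pops at exact HWE proportions (p = 0.5, n = 50): f = 1/(2n-1)
  hwe <- data.frame(pop = rep(c("A", "B"), each = 3),
                    allele1 = rep(c("1", "1", "2"), 2),
                    allele2 = rep(c("1", "2", "2"), 2),
                    count = rep(c(13, 25, 12), 2))  # ~HWE, h close to 2pq
  f <- weir_cockerham(hwe)$f_W
  expect_lt(abs(f), 0.05)
  mono <- data.frame(pop = c("A", "B"), allele1 = "1", allele2 = "1",
                     count = c(5, 5))
  expect_identical(weir_cockerham(mono)$theta_W, NA_real_)
})

test_that("negative estimates are reported unless truncation is requested", {
  # tiny samples with identical frequencies drift negative
  gt <- data.frame(pop = rep(c("A", "B"), each = 2),
                   allele1 = c("1", "2", "1", "2"),
                   allele2 = c("2", "2", "2", "2"),
                   count = c(2, 2, 2, 2))
  wc <- weir_cockerham(gt)
  expect_lt(wc$theta_W, 0)
  expect_gte(weir_cockerham(gt, truncate = TRUE)$theta_W, 0)
})

test_that("differentiation statistics are invariant to population order", {
  tab <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3), c(0.3, 0.3, 0.4))
  perm <- tab[c(3, 1, 2), ]
  expect_equal(nei_decomposition(tab), nei_decomposition(perm),
               tolerance = 1e-12)
  gt <- wc_fixture()
  gt_perm <- gt[nrow(gt):1, ]
  expect_equal(weir_cockerham(gt), weir_cockerham(gt_perm),
               tolerance = 1e-12)
  expect_equal(slatkin_rst(list(c(10, 12), c(14, 16))),
               slatkin_rst(list(c(14, 16), c(10, 12))), tolerance = 1e-12)
})
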