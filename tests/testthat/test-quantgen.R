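test_that("genotype and allele frequencies are computed over non-missing entries", {
  f <- compute_snp_frequencies(rep(c(0, 1, 2), c(25, 50, 25)))
  expect_equal(c(f$P11, f$P12, f$P22), c(0.25, 0.50, 0.25))
  expect_equal(f$p1, 0.5)

  f <- compute_snp_frequencies(rep(c(0, 1, 2), c(0, 30, 70)))
  expect_equal(f$P11, 0)
  expect_equal(f$p1, 0.15)

  # rare-recessive pattern: f_RR = 0.005, f_DR = 0.152 gives f_R = 0.081
  f <- compute_snp_frequencies(rep(c(0, 1, 2), c(5, 152, 843)))
  expect_equal(f$p1, 0.081)

  # missing entries are dropped, frequencies renormalized
  f <- compute_snp_frequencies(c(0, 0, 1, 1, NA, NA))
  expect_equal(f$n, 4L)
  expect_equal(f$P11 + f$P12 + f$P22, 1)

  expect_error(compute_snp_frequencies(c(NA, NA)), "untestable")
  expect_error(compute_snp_frequencies(c(0, 3)), "codes")
})

test_that("additive contrast coefficients match the HWD formula and its HWE reduction", {
  expect_equal(additive_contrast_coefficients(hwe_freqs(0.3)),
               c(0.3, 0.4, -0.7))
  expect_equal(additive_contrast_coefficients(hwe_freqs(0.5)),
               c(0.5, 0, -0.5))
  expect_equal(additive_contrast_coefficients(hwd_freqs(0.2, 0.2, 0.6)),
               c(2 / 3, 4 / 21, -6 / 7), tolerance = 1e-12)
  # HWE reduction (p1, p2 - p1, -p2) across a grid
  for (p in seq(0.01, 0.99, by = 0.01)) {
    expect_lt(max(abs(additive_contrast_coefficients(hwe_freqs(p)) -
                        c(p, 1 - 2 * p, -(1 - p)))), 1e-12)
  }
  expect_error(additive_contrast_coefficients(hwd_freqs(1, 0, 0)),
               "monomorphic")
})

test_that("dominance contrast coefficients are the fixed (-0.5, 1, -0.5)", {
  s_d <- dominance_contrast_coefficients()
  expect_identical(s_d, c(-0.5, 1, -0.5))
  expect_equal(sum(s_d * c(1, 0, -1)), 0)  # additive genotypic values
  expect_equal(sum(s_d * c(0, 1, 0)), 1)
})

test_that("additive decomposition reproduces allelic means, effects and alpha", {
  add <- additive_decomposition(c(1, 0, -1), hwe_freqs(0.5), mu_all = 0)
  expect_equal(add$mu1, 0.5)
  expect_equal(add$mu2, -0.5)
  expect_equal(add$alpha, 1.0)
  expect_equal(add$mu, 0)

  # constant genotypic values carry no additive signal
  add <- additive_decomposition(c(3, 3, 3), hwd_freqs(0.2, 0.2, 0.6))
  expect_equal(add$alpha, 0)
  expect_equal(c(add$a1, add$a2), c(0, 0))

  # alpha equals the additive contrast under HWD
  f <- hwd_freqs(0.2, 0.2, 0.6)
  add <- additive_decomposition(c(1, 0, -1), f)
  expect_equal(add$alpha, 32 / 21, tolerance = 1e-12)
  expect_equal(add$alpha,
               sum(additive_contrast_coefficients(f) * c(1, 0, -1)))

  # ae_i subtracts the cross-SNP mean
  add <- additive_decomposition(c(1, 0, -1), hwe_freqs(0.5), mu_all = 2)
  expect_equal(c(add$ae1, add$ae2), c(-1.5, -2.5))

  expect_error(additive_decomposition(c(1, 0, -1), hwd_freqs(0, 0, 1)),
               "monomorphic")
})

test_that("quantgen identities hold on randomized frequency/value configurations", {
  set.seed(42)
  for (i in 1:200) {
    P <- as.vector(stats::rgamma(3, 1)) + 0.01
    P <- P / sum(P)
    f <- hwd_freqs(P[1], P[2], P[3])
    g <- stats::rnorm(3, 0, 5)
    add <- additive_decomposition(g, f)
    dom <- dominance_decomposition(g, f)
    expect_lt(abs(f$p1 * add$a1 + f$p2 * add$a2), 1e-10)
    expect_lt(abs(add$alpha -
                    sum(additive_contrast_coefficients(f) * g)), 1e-10)
    # delta from dominance values equals delta from genotypic values
    expect_lt(abs(dom$delta - (g[2] - (g[1] + g[3]) / 2)), 1e-10)
    expect_lt(abs(dom$delta - (dom$d12 - (dom$d11 + dom$d22) / 2)), 1e-12)
  }
  # under HWE the frequency-weighted dominance values sum to zero
  for (p in seq(0.05, 0.95, by = 0.05)) {
    f <- hwe_freqs(p)
    g <- stats::rnorm(3, 0, 5)
    dom <- dominance_decomposition(g, f)
    expect_lt(abs(f$P11 * dom$d11 + f$P12 * dom$d12 + f$P22 * dom$d22),
              1e-10)
  }
})

test_that("dominance decomposition classifies overdominance and finds the recessive allele", {
  # purely additive SNP: no dominance deviations
  dom <- dominance_decomposition(c(1, 0, -1), hwe_freqs(0.5))
  expect_equal(c(dom$d11, dom$d12, dom$d22), c(0, 0, 0))
  expect_equal(dom$delta, 0)
  expect_identical(dom$classification, "none")

  # symmetric heterozygote advantage
  dom <- dominance_decomposition(c(0, 1, 0), hwe_freqs(0.5))
  expect_equal(c(dom$d11, dom$d12, dom$d22), c(-0.5, 0.5, -0.5))
  expect_equal(dom$delta, 1.0)
  expect_identical(dom$classification, "positive_overdominance")
  expect_true(is.na(dom$recessive_allele))  # tie: d11 == d22

  # heterozygote disadvantage mirror
  dom <- dominance_decomposition(c(0, -1, 0), hwe_freqs(0.5))
  expect_identical(dom$classification, "negative_overdominance")

  # dominance effect reconstructed from reported dominance values
  s_d <- dominance_contrast_coefficients()
  expect_equal(round(sum(s_d * c(-9.76, 0.62, -0.06)), 2), 5.53)
  expect_equal(round(sum(s_d * c(-9.72, 0.62, -0.06)), 2), 5.51)

  # asymmetric rare-recessive pattern: allele 1 homozygote most negative
  f <- hwe_freqs(0.081)
  oc <- make_overdominant_causal(0.081, -9.76, 0.62)
  dom <- dominance_decomposition(oc$g, f)
  expect_identical(dom$classification, "positive_overdominance")
  expect_identical(dom$recessive_allele, 1L)
  expect_lt(dom$d11, dom$d22)
})

test_that("a rare-recessive overdominance pattern is realizable under HWD genotype frequencies", {
  # at fixed allele frequency the heterozygote excess is the extra degree
  # of freedom: solving for it reproduces both reported dominance values
  p1 <- 0.081; p2 <- 1 - p1
  d_RR <- -9.76; d_DR <- 0.62
  t_het <- d_DR + (d_RR * p1 / p2) * (1 - 1 / (2 * p1 * p2))
  P12 <- -d_RR * p1 / (p2 * t_het)
  f <- hwd_freqs(p1 - P12 / 2, P12, p2 - P12 / 2)
  dom <- dominance_decomposition(c(0, t_het, 0), f)
  expect_equal(dom$d11, d_RR, tolerance = 1e-9)
  expect_equal(dom$d12, d_DR, tolerance = 1e-9)
  expect_equal(round(dom$delta, 2),
               round(d_DR - (d_RR + dom$d22) / 2, 2))
})
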