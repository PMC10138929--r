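test_that("phenotype adjustment subtracts the polygenic prediction elementwise", {
  ph <- data.frame(animal = c("a", "b"), y = c(-10, 5),
                   a_tilde = c(-2, 1))
  expect_equal(adjust_phenotypes(ph), c(-8, 4))
  ph$a_tilde <- 0
  expect_equal(adjust_phenotypes(ph), ph$y)
})

test_that("cell-means fit equals class means and matches the pseudoinverse solution", {
  y <- c(1, 1, 2, 2, 3, 3)
  codes <- c(0, 0, 1, 1, 2, 2)
  fit <- fit_snp(y, codes)
  expect_equal(fit$g_hat, c(1, 2, 3))
  expect_equal(fit$v2, 0)
  expect_equal(fit$k, 3L)

  fit <- fit_snp(rep(7, 6), codes)
  expect_equal(fit$g_hat, c(7, 7, 7))
  expect_equal(fit$v2, 0)

  # generalized-inverse least squares on the rank-deficient (mu, g) design
  set.seed(11)
  n <- 60
  codes <- sample(0:2, n, TRUE)
  y <- stats::rnorm(n)
  X <- cbind(1, sapply(0:2, function(c) as.numeric(codes == c)))
  b <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
  fit <- fit_snp(y, codes)
  for (s in list(c(1, 0, -1), c(-0.5, 1, -0.5), c(1, -2, 1)))
    expect_equal(sum(s * fit$g_hat), sum(s * b[2:4]), tolerance = 1e-9)
  rss <- sum((y - X %*% MASS::ginv(crossprod(X)) %*% crossprod(X, y))^2)
  expect_equal(fit$v2, rss / (n - 3), tolerance = 1e-9)

  # missing genotypes: complete-case per SNP
  fit <- fit_snp(c(1, 2, 3, 4), c(0, 0, 2, NA))
  expect_equal(fit$n, 3L)
  expect_false(fit$dominance_testable)

  expect_error(fit_snp(1:3, c(1, 1, 1)), "untestable")
})

test_that("contrast test matches the classical pooled t-test and handles edge cases", {
  # two equal-size classes, (1, 0, -1) contrast = two-sample t-test
  set.seed(5)
  y <- c(stats::rnorm(15, 0), stats::rnorm(15, 1))
  codes <- rep(c(0, 2), each = 15)
  fit <- fit_snp(y, codes)
  ct <- contrast_test(fit, c(1, 0, -1))
  tt <- stats::t.test(y[1:15], y[16:30], var.equal = TRUE)
  expect_equal(ct$t, abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(ct$p, tt$p.value, tolerance = 1e-10)
  expect_equal(ct$neglog10p, log10(1 / tt$p.value), tolerance = 1e-8)

  # zero contrast
  fit0 <- fit_snp(c(1, 2, 1, 2), c(0, 0, 2, 2))
  ct0 <- contrast_test(fit0, c(1, 0, -1))
  expect_equal(ct0$L, 0)
  expect_equal(ct0$t, 0)
  expect_equal(ct0$p, 1)
  expect_equal(ct0$neglog10p, 0)

  # neglog10p stays finite and exact when p underflows
  fit$v2 <- 1e-28
  ctu <- contrast_test(fit, c(1, 0, -1))
  expect_true(ctu$underflow)
  expect_identical(ctu$p, 0)
  expect_gt(ctu$neglog10p, 300)

  # zero variance with nonzero contrast is flagged
  fitz <- fit_snp(c(1, 1, 2, 2), c(0, 0, 2, 2))
  fitz$v2 <- 0
  ctz <- contrast_test(fitz, c(1, 0, -1))
  expect_true(ctz$zero_variance)
  expect_gt(ctz$neglog10p, 300)

  expect_error(contrast_test(fit0, c(-0.5, 1, -0.5)), "empty")
})

test_that("the additive test holds its nominal size on unrelated null data", {
  set.seed(101)
  n <- 300; m <- 2000
  y <- stats::rnorm(n)
  rej <- logical(m)
  for (j in 1:m) {
    codes <- stats::rbinom(n, 2, 0.3)
    fit <- fit_snp(y, codes)
    f <- compute_snp_frequencies(codes)
    ct <- contrast_test(fit, additive_contrast_coefficients(f))
    rej[j] <- ct$p < 0.05
  }
  mc_se <- sqrt(0.05 * 0.95 / m)
  expect_lt(abs(mean(rej) - 0.05), 3 * mc_se)
})

test_that("expected additive significance is monotone in the injected effect size", {
  set.seed(77)
  n <- 200; reps <- 40
  mean_nlp <- sapply(c(0, 0.5, 1, 2), function(alpha) {
    mean(replicate(reps, {
      codes <- stats::rbinom(n, 2, 0.5)
      y <- alpha * c(1, 0, -1)[codes + 1] + stats::rnorm(n, 0, 2)
      fit <- fit_snp(y, codes)
      f <- compute_snp_frequencies(codes)
      contrast_test(fit, additive_contrast_coefficients(f))$neglog10p
    }))
  })
  expect_true(all(diff(mean_nlp) > 0))
})

test_that("AGLS with exact BLUP reproduces the joint MME estimable contrasts", {
  set.seed(31)
  for (rep in 1:5) {
    inst <- random_mme_instance(n = 150 + 50 * rep)
    mme <- solve_mme(inst$y, inst$X, inst$spec)
    fit <- fit_snp(inst$y - mme$a_hat, inst$codes)
    f <- compute_snp_frequencies(inst$codes)
    for (s in list(additive_contrast_coefficients(f),
                   dominance_contrast_coefficients()))
      expect_equal(sum(s * fit$g_hat), sum(s * mme$b_hat),
                   tolerance = 1e-8)
  }
})

test_that("genome scan filters by MAF, flags significance, and is deterministic", {
  set.seed(13)
  n <- 1500
  codes_rare <- stats::rbinom(n, 2, 0.03)   # MAF below the filter
  codes_null <- stats::rbinom(n, 2, 0.4)
  codes_causal <- stats::rbinom(n, 2, 0.3)
  geno <- cbind(rare = codes_rare, null = codes_null,
                causal = codes_causal)
  rownames(geno) <- paste0("A", seq_len(n))
  y <- 4.5 * c(1, 0, -1)[codes_causal + 1] + stats::rnorm(n, 0, 10)
  ph <- data.frame(animal = paste0("A", seq_len(n)), y = y, a_tilde = 0)
  map <- data.frame(snp = colnames(geno), chr = c(1, 1, 2),
                    pos = c(100L, 200L, 300L))
  scan <- genome_scan(ph, geno, map)
  expect_false("rare" %in% scan$snp)
  expect_true(all(c("null", "causal") %in% scan$snp))
  expect_true(scan$sig_add[scan$snp == "causal"])
  expect_false(scan$sig_add[scan$snp == "null"])
  expect_equal(scan$chr[scan$snp == "causal"], 2)
  # mu_all is the unweighted mean of per-SNP genotypic means
  expect_equal(attr(scan, "mu_all"), mean(scan$mu))
  expect_equal(scan$ae1 - scan$ae2, scan$alpha, tolerance = 1e-10)

  scan2 <- genome_scan(ph, geno, map)
  expect_identical(scan, scan2)

  expect_warning(empty <- genome_scan(ph, geno[, "rare", drop = FALSE]),
                 "MAF")
  expect_equal(nrow(empty), 0L)
})

test_that("the dominance test is withheld when a genotype class is too thin", {
  set.seed(19)
  n <- 400
  codes <- c(rep(0, 5), stats::rbinom(n - 5, 1, 0.5) + 1)
  geno <- cbind(thin = codes)
  ph <- data.frame(animal = seq_len(n), y = stats::rnorm(n), a_tilde = 0)
  scan <- genome_scan(ph, geno, min_class_count_dom = 10L)
  expect_false(scan$dominance_tested[1])
  expect_true(is.na(scan$neglog10p_dom[1]))
  expect_false(is.na(scan$neglog10p_add[1]))
})
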