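#' Adjust phenotypes by the polygenic prediction
#'
#' The AGLS working phenotype is `y* = y - a_tilde`, where `a_tilde` is
#' twice the predicted transmitting ability (an external approximation of
#' the BLUP of the additive polygenic value). With `a_tilde = 0` the scan
#' degenerates to plain least squares on unadjusted residuals.
#'
#' @param phenotypes Data frame with numeric columns `y` and `a_tilde`
#'   (one row per animal, aligned with the genotype matrix rows).
#' @return Numeric vector `y - a_tilde`.
#' @export
adjust_phenotypes <- function(phenotypes) {
  stopifnot(is.data.frame(phenotypes),
            all(c("y", "a_tilde") %in% names(phenotypes)))
  y <- phenotypes$y
  at <- phenotypes$a_tilde
  if (length(y) != length(at)) stop("y and a_tilde length mismatch")
  y - at
}

#' Per-SNP cell-means fit of genotypic values
#'
#' Least-squares estimation of the three SNP genotypic values from
#' adjusted phenotypes. The design (intercept plus three genotype
#' indicators) is rank deficient, but every reported quantity is an
#' estimable function, so the fit uses the cell-means parameterization:
#' the estimate of each genotypic value is the class mean of `y_star`,
#' and the residual variance is the pooled within-class variance
#' `v2 = RSS / (n - k)` with `k` the number of non-empty classes.
#' Animals with missing genotype are dropped (per-SNP complete case).
#'
#' @param y_star Numeric vector of adjusted phenotypes.
#' @param codes Genotype codes in \{0, 1, 2, NA\}, same length as `y_star`.
#' @param min_class_count Classes with fewer observations than this are
#'   treated as empty for estimation (default 1: any observation counts).
#' @return An object of class `snp_fit`: list with `g_hat` (length-3,
#'   `NA` for empty classes), `class_counts`, `v2`, `n`, `k`, and
#'   `dominance_testable` (`FALSE` when any class, in particular the
#'   heterozygote, is empty).
#' @export
fit_snp <- function(y_star, codes, min_class_count = 1L) {
  if (length(y_star) != length(codes))
    stop("y_star and codes length mismatch")
  keep <- !is.na(codes) & !is.na(y_star)
  y <- y_star[keep]
  cds <- codes[keep]
  counts <- c(sum(cds == 0), sum(cds == 1), sum(cds == 2))
  use <- counts >= max(1L, min_class_count)
  if (sum(use) < 2L)
    stop("fewer than two non-empty genotype classes: SNP untestable")
  g_hat <- rep(NA_real_, 3)
  rss <- 0
  for (j in 1:3) {
    if (!use[j]) next
    yj <- y[cds == (j - 1)]
    g_hat[j] <- mean(yj)
    rss <- rss + sum((yj - g_hat[j])^2)
  }
  counts[!use] <- 0L
  k <- sum(use)
  n <- sum(counts)
  v2 <- if (n > k) rss / (n - k) else 0
  structure(
    list(g_hat = g_hat, class_counts = counts, v2 = v2, n = n, k = k,
         usable_class = use,
         dominance_testable = all(use)),
    class = "snp_fit"
  )
}

#' t-test of a contrast of genotype cell means
#'
#' Tests `L = s'g_hat` with `var(L) = v2 * sum_j s_j^2 / n_j`, the
#' least-squares variance under the cell-means design (the diagonal of the
#' generalized inverse of the genotype block of X'X is `1/n_j`). The
#' two-sided p-value uses a Student-t reference with `n - k` degrees of
#' freedom (`df_mode = "t"`) or the normal reference (`df_mode =
#' "normal"`, indistinguishable at large n). `log10(1/p)` is computed in
#' log space from the t survival function, so it stays finite and exact
#' even when the p-value underflows double precision (in which case `p`
#' is reported as 0 and flagged).
#'
#' @param est A `snp_fit` object.
#' @param s Numeric length-3 contrast coefficients (A1A1, A1A2, A2A2).
#' @param df_mode `"t"` (default) or `"normal"`.
#' @return An object of class `contrast_test`: list with `L`, `se`, `t`,
#'   `df`, `p`, `neglog10p`, and logical `underflow` / `zero_variance`
#'   flags.
#' @export
contrast_test <- function(est, s, df_mode = c("t", "normal")) {
  df_mode <- match.arg(df_mode)
  stopifnot(length(s) == 3)
  active <- which(s != 0)
  if (any(est$class_counts[active] == 0L))
    stop("contrast touches an empty genotype class")
  L <- sum(s[active] * est$g_hat[active])
  varL <- est$v2 * sum(s[active]^2 / est$class_counts[active])
  df <- est$n - est$k
  zero_variance <- varL <= 0
  if (zero_variance) {
    if (L == 0) {
      tstat <- 0; p <- 1; nlp <- 0; underflow <- FALSE
    } else {
      tstat <- Inf
      p <- .Machine$double.xmin
      nlp <- -log10(.Machine$double.xmin)
      underflow <- TRUE
    }
  } else {
    tstat <- abs(L) / sqrt(varL)
    logp <- log(2) + if (df_mode == "t" && df > 0) {
      stats::pt(tstat, df = df, lower.tail = FALSE, log.p = TRUE)
    } else {
      stats::pnorm(tstat, lower.tail = FALSE, log.p = TRUE)
    }
    logp <- min(logp, 0)  # guard log(2) overshoot at t ~ 0
    p <- exp(logp)
    nlp <- -logp / log(10)
    underflow <- p == 0
  }
  structure(
    list(L = L, se = sqrt(max(varL, 0)), t = tstat, df = df, p = p,
         neglog10p = nlp, underflow = underflow,
         zero_variance = zero_variance),
    class = "contrast_test"
  )
}

#' Genome scan: per-SNP AGLS estimation and additive/dominance tests
#'
#' Runs the single-SNP analysis over a genotype matrix: MAF filtering,
#' cell-means estimation of genotypic values from adjusted phenotypes,
#' frequency-adjusted additive contrast and fixed dominance contrast
#' t-tests, and the full quantitative-genetics decomposition. Allelic
#' effects comparable across SNPs (`ae1`, `ae2`) are taken against
#' `mu_all`, the unweighted mean of the per-SNP genotypic means over all
#' SNPs passing the MAF filter (computed in a first pass).
#'
#' @param phenotypes Data frame with columns `animal`, `y`, `a_tilde`.
#' @param genotypes Matrix of genotype codes \{0,1,2,NA\}, animals in rows
#'   (rownames = animal ids when available), SNPs in columns (colnames =
#'   SNP ids).
#' @param snp_map Optional data frame with columns `snp`, `chr`, `pos`
#'   (rows matched to genotype columns by `snp`); when `NULL`, chromosome
#'   and position are reported as `NA`.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param threshold Significance threshold on `log10(1/p)` (default 8,
#'   the genome-wide Bonferroni-scale constant).
#' @param df_mode Passed to [contrast_test()].
#' @param min_class_count_dom Minimum per-class count required to run the
#'   dominance test (default 10; guards against residual-variance-driven
#'   false positives when a homozygote class is nearly empty).
#' @param verbose Log filter counts and the realized `mu_all` to stderr.
#' @return A data frame of class `agls_scan` with one row per SNP passing
#'   the MAF filter; columns include frequencies, `g11..g22`, `v2`,
#'   `alpha`, `ae1`, `ae2`, additive and dominance test statistics,
#'   `delta`, `d11..d22`, overdominance classification and significance
#'   flags. `mu_all`, the threshold and filter counts are attached as
#'   attributes.
#' @export
genome_scan <- function(phenotypes, genotypes, snp_map = NULL,
                        maf_min = 0.05, threshold = 8,
                        df_mode = "t", min_class_count_dom = 10L,
                        verbose = FALSE) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(phenotypes))
    stop("genotype rows and phenotype rows must align (one animal each)")
  if (!is.null(rownames(genotypes)) && "animal" %in% names(phenotypes) &&
      !identical(as.character(phenotypes$animal), rownames(genotypes)))
    stop("animal ids of phenotypes and genotypes disagree")
  y_star <- adjust_phenotypes(phenotypes)
  snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))

  # pass 1: frequencies, fits, per-SNP genotypic means
  fits <- vector("list", ncol(genotypes))
  freqs <- vector("list", ncol(genotypes))
  keep <- logical(ncol(genotypes))
  mu <- rep(NA_real_, ncol(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    fj <- tryCatch(compute_snp_frequencies(genotypes[, j]),
                   error = function(e) NULL)
    if (is.null(fj) || minor_allele_frequency(fj) < maf_min) next
    fit <- tryCatch(fit_snp(y_star, genotypes[, j]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    keep[j] <- TRUE
    freqs[[j]] <- fj
    fits[[j]] <- fit
    g <- fit$g_hat
    if (!anyNA(g))
      mu[j] <- additive_decomposition(g, fj)$mu
  }
  n_fail <- sum(!keep)
  if (!any(keep)) {
    warning("no SNPs pass the MAF filter")
    res <- empty_scan_frame()
    attr(res, "mu_all") <- NA_real_
    attr(res, "threshold") <- threshold
    attr(res, "n_snps_read") <- ncol(genotypes)
    attr(res, "n_snps_filtered") <- n_fail
    class(res) <- c("agls_scan", class(res))
    return(res)
  }
  mu_all <- mean(mu[keep], na.rm = TRUE)
  if (verbose)
    message(sprintf(
      "genome_scan: %d SNPs read, %d filtered out (MAF < %s or untestable), %d tested; mu_all = %.6g",
      ncol(genotypes), n_fail, format(maf_min), sum(keep), mu_all))

  # pass 2: decompositions and contrast tests
  idx <- which(keep)
  rows <- lapply(idx, function(j) {
    fj <- freqs[[j]]; fit <- fits[[j]]
    g <- fit$g_hat
    add_t <- tryCatch(
      contrast_test(fit, additive_contrast_coefficients(fj), df_mode),
      error = function(e) NULL)
    dom_ok <- fit$dominance_testable &&
      all(fit$class_counts >= min_class_count_dom)
    dom_t <- if (dom_ok)
      contrast_test(fit, dominance_contrast_coefficients(), df_mode)
    else NULL
    dec_ok <- !anyNA(g)
    add <- if (dec_ok) additive_decomposition(g, fj, mu_all) else NULL
    dom <- if (dec_ok) dominance_decomposition(g, fj) else NULL
    data.frame(
      snp = snp_ids[j],
      n = fit$n,
      n11 = fit$class_counts[1], n12 = fit$class_counts[2],
      n22 = fit$class_counts[3],
      p1 = fj$p1, p2 = fj$p2, maf = minor_allele_frequency(fj),
      P11 = fj$P11, P12 = fj$P12, P22 = fj$P22,
      g11 = g[1], g12 = g[2], g22 = g[3], v2 = fit$v2,
      mu = if (dec_ok) add$mu else NA_real_,
      alpha = if (dec_ok) add$alpha else NA_real_,
      ae1 = if (dec_ok) add$ae1 else NA_real_,
      ae2 = if (dec_ok) add$ae2 else NA_real_,
      t_add = if (!is.null(add_t)) add_t$t else NA_real_,
      p_add = if (!is.null(add_t)) add_t$p else NA_real_,
      neglog10p_add = if (!is.null(add_t)) add_t$neglog10p else NA_real_,
      delta = if (dec_ok) dom$delta else NA_real_,
      d11 = if (dec_ok) dom$d11 else NA_real_,
      d12 = if (dec_ok) dom$d12 else NA_real_,
      d22 = if (dec_ok) dom$d22 else NA_real_,
      classification = if (dec_ok) dom$classification else NA_character_,
      recessive_allele = if (dec_ok) dom$recessive_allele else NA_integer_,
      dominance_tested = dom_ok,
      t_dom = if (!is.null(dom_t)) dom_t$t else NA_real_,
      p_dom = if (!is.null(dom_t)) dom_t$p else NA_real_,
      neglog10p_dom = if (!is.null(dom_t)) dom_t$neglog10p else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$sig_add <- !is.na(res$neglog10p_add) & res$neglog10p_add > threshold
  res$sig_dom <- !is.na(res$neglog10p_dom) & res$neglog10p_dom > threshold
  if (!is.null(snp_map)) {
    m <- match(res$snp, snp_map$snp)
    res$chr <- snp_map$chr[m]
    res$pos <- snp_map$pos[m]
  } else {
    res$chr <- NA
    res$pos <- NA_integer_
  }
  res <- res[, c("snp", "chr", "pos",
                 setdiff(names(res), c("snp", "chr", "pos")))]
  attr(res, "mu_all") <- mu_all
  attr(res, "threshold") <- threshold
  attr(res, "n_snps_read") <- ncol(genotypes)
  attr(res, "n_snps_filtered") <- n_fail
  class(res) <- c("agls_scan", class(res))
  res
}

empty_scan_frame <- function() {
  data.frame(snp = character(), chr = character(), pos = integer(),
             n = integer(), n11 = integer(), n12 = integer(),
             n22 = integer(), p1 = numeric(), p2 = numeric(),
             maf = numeric(), P11 = numeric(), P12 = numeric(),
             P22 = numeric(), g11 = numeric(), g12 = numeric(),
             g22 = numeric(), v2 = numeric(), mu = numeric(),
             alpha = numeric(), ae1 = numeric(), ae2 = numeric(),
             t_add = numeric(), p_add = numeric(),
             neglog10p_add = numeric(), delta = numeric(),
             d11 = numeric(), d12 = numeric(), d22 = numeric(),
             classification = character(),
             recessive_allele = integer(),
             dominance_tested = logical(), t_dom = numeric(),
             p_dom = numeric(), neglog10p_dom = numeric(),
             sig_add = logical(), sig_dom = logical(),
             stringsAsFactors = FALSE)
}
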