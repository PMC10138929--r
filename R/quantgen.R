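#' Allele and genotype frequencies of a biallelic SNP
#'
#' Counts the three genotype classes of one SNP and derives genotype and
#' allele frequencies without assuming Hardy-Weinberg equilibrium.
#' Genotype codes count copies of allele 2: code 0 = A1A1, 1 = A1A2,
#' 2 = A2A2. Missing genotypes (`NA`) are dropped; all frequencies refer
#' to the non-missing subset, the same subset the association tests use.
#'
#' @param codes Integer/numeric vector with values in \{0, 1, 2\} or `NA`.
#' @return An object of class `snp_frequencies`: a list with genotype
#'   counts `n11`, `n12`, `n22`, genotype frequencies `P11`, `P12`, `P22`,
#'   allele frequencies `p1`, `p2`, and `n` (non-missing observations).
#' @examples
#' f <- compute_snp_frequencies(c(0, 0, 1, 1, 2, 2))
#' f$p1  # 0.5
#' @export
compute_snp_frequencies <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L)
    stop("all genotypes missing: SNP is untestable")
  if (!all(codes %in% c(0, 1, 2)))
    stop("genotype codes must be 0, 1, 2 or NA")
  n11 <- sum(codes == 0)
  n12 <- sum(codes == 1)
  n22 <- sum(codes == 2)
  n <- n11 + n12 + n22
  P11 <- n11 / n
  P12 <- n12 / n
  P22 <- n22 / n
  p1 <- P11 + P12 / 2
  structure(
    list(n11 = n11, n12 = n12, n22 = n22,
         P11 = P11, P12 = P12, P22 = P22,
         p1 = p1, p2 = 1 - p1, n = n),
    class = "snp_frequencies"
  )
}

#' Minor allele frequency
#'
#' @param freqs A `snp_frequencies` object.
#' @return `min(p1, p2)`.
#' @export
minor_allele_frequency <- function(freqs) min(freqs$p1, freqs$p2)

#' Additive contrast coefficients, valid under Hardy-Weinberg disequilibrium
#'
#' The additive contrast of the three genotype cell means estimates the
#' average effect of gene substitution (alpha). The coefficients are
#' frequency-adjusted so the contrast equals `mu1 - mu2` (difference of
#' allelic means) for arbitrary genotype frequencies:
#' `s_a = (P11/p1, 0.5 P12 (p2 - p1)/(p1 p2), -P22/p2)`.
#' Under Hardy-Weinberg equilibrium this reduces to `(p1, p2 - p1, -p2)`.
#'
#' @param freqs A `snp_frequencies` object (or list with `P11`, `P12`,
#'   `P22`, `p1`, `p2`).
#' @return Numeric vector of length 3, ordered (A1A1, A1A2, A2A2).
#' @export
additive_contrast_coefficients <- function(freqs) {
  p1 <- freqs$p1; p2 <- freqs$p2
  if (p1 <= 0 || p1 >= 1)
    stop("monomorphic SNP: additive contrast undefined")
  c(freqs$P11 / p1,
    0.5 * freqs$P12 * (p2 - p1) / (p1 * p2),
    -freqs$P22 / p2)
}

#' Dominance contrast coefficients
#'
#' Fixed coefficients `(-0.5, 1, -0.5)` applied to the genotype cell means;
#' the contrast equals the dominance effect `delta = d12 - (d11 + d22)/2`
#' because additive components cancel. No frequency adjustment is used.
#'
#' @return Numeric vector `c(-0.5, 1, -0.5)`, ordered (A1A1, A1A2, A2A2).
#' @export
dominance_contrast_coefficients <- function() c(-0.5, 1, -0.5)

#' Additive decomposition of SNP genotypic values
#'
#' Computes, for one SNP with genotypic values `g = (g11, g12, g22)` and
#' observed genotype frequencies (HWD allowed), the allelic means
#' `mu1 = P11.1 g11 + 0.5 P12.1 g12` and `mu2 = 0.5 P12.2 g12 + P22.2 g22`
#' (conditional frequencies `Pij.k = Pij / pk`), the SNP genotypic mean
#' `mu = p1 mu1 + p2 mu2`, allelic effects `a_i = mu_i - mu`, the average
#' effect of gene substitution `alpha = mu1 - mu2 = a1 - a2`, and
#' cross-SNP comparable allelic effects `ae_i = mu_i - mu_all` where
#' `mu_all` is the average of genotypic means over all analysed SNPs.
#'
#' @param g Numeric length-3 vector of genotypic values (g11, g12, g22).
#' @param freqs A `snp_frequencies` object.
#' @param mu_all Scalar cross-SNP mean of genotypic means (default 0, i.e.
#'   `ae_i` reduces to the allelic mean itself when no scan context exists).
#' @return An object of class `additive_decomposition`: list with `mu1`,
#'   `mu2`, `mu`, `a1`, `a2`, `ae1`, `ae2`, `alpha`, `f1`, `f2`.
#' @export
additive_decomposition <- function(g, freqs, mu_all = 0) {
  stopifnot(length(g) == 3, all(is.finite(g)), is.finite(mu_all))
  p1 <- freqs$p1; p2 <- freqs$p2
  if (p1 <= 0 || p1 >= 1)
    stop("monomorphic SNP: allelic means undefined")
  mu1 <- (freqs$P11 / p1) * g[1] + 0.5 * (freqs$P12 / p1) * g[2]
  mu2 <- 0.5 * (freqs$P12 / p2) * g[2] + (freqs$P22 / p2) * g[3]
  mu <- p1 * mu1 + p2 * mu2
  structure(
    list(mu1 = mu1, mu2 = mu2, mu = mu,
         a1 = mu1 - mu, a2 = mu2 - mu,
         ae1 = mu1 - mu_all, ae2 = mu2 - mu_all,
         alpha = mu1 - mu2, f1 = p1, f2 = p2),
    class = "additive_decomposition"
  )
}

#' Dominance decomposition of SNP genotypic values
#'
#' Dominance values (deviations) `d_ij = g_ij - mu - a_i - a_j` and the
#' dominance effect `delta = d12 - (d11 + d22)/2`, which equals
#' `g12 - (g11 + g22)/2` since additive terms cancel. A SNP is classified
#' as positive overdominance when the heterozygote dominance value exceeds
#' both homozygote dominance values (heterozygote advantage), negative
#' overdominance for the mirror pattern, `none` otherwise. For positive
#' overdominance the recessive allele is the allele whose homozygote has
#' the strictly more negative dominance value (`NA` on ties).
#'
#' @inheritParams additive_decomposition
#' @return An object of class `dominance_decomposition`: list with `d11`,
#'   `d12`, `d22`, `delta`, `classification` (one of
#'   `"positive_overdominance"`, `"negative_overdominance"`, `"none"`) and
#'   `recessive_allele` (1, 2 or `NA`).
#' @export
dominance_decomposition <- function(g, freqs) {
  add <- additive_decomposition(g, freqs)
  d11 <- g[1] - add$mu - 2 * add$a1
  d12 <- g[2] - add$mu - add$a1 - add$a2
  d22 <- g[3] - add$mu - 2 * add$a2
  classification <- if (d12 > d11 && d12 > d22) {
    "positive_overdominance"
  } else if (d12 < d11 && d12 < d22) {
    "negative_overdominance"
  } else "none"
  recessive_allele <- NA_integer_
  if (classification == "positive_overdominance") {
    if (d11 < d22) recessive_allele <- 1L
    else if (d22 < d11) recessive_allele <- 2L
  }
  structure(
    list(d11 = d11, d12 = d12, d22 = d22,
         delta = d12 - (d11 + d22) / 2,
         classification = classification,
         recessive_allele = recessive_allele),
    class = "dominance_decomposition"
  )
}
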