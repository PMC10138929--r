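#' Simulation configuration for a pedigreed study population
#'
#' Defines the data-generating conditions the analysis assumes: a founder
#' generation with uniform founder allele frequencies, discrete
#' generations bred by random mating with a limited number of sires
#' (half-sib family structure typical of dairy cattle), unlinked
#' biallelic SNPs transmitted by Mendelian gene dropping, polygenic
#' values with covariance `sigma2_a * A`, optional causal SNPs acting
#' through their genotypic values, and Gaussian residuals. Defaults give
#' an adjusted-phenotype standard deviation of about 11 days with
#' narrow-sense heritability 0.2 on the residual (yield-deviation) scale.
#'
#' @param n_founders Founder generation size (also the size of each
#'   descendant generation when `offspring_per_mating = 1`).
#' @param n_generations Number of descendant generations.
#' @param offspring_per_mating Offspring per dam slot per generation.
#' @param n_sires Sires sampled per generation (half-sib structure).
#' @param n_snps Number of unlinked SNPs.
#' @param maf_range Range for founder allele-2 frequencies (default
#'   `c(0.05, 0.5)`).
#' @param causal List of causal SNP specs, each a list with `snp` (column
#'   index), `g` (length-3 genotypic values for codes 0/1/2) and
#'   optionally `freq1` (founder frequency of allele 1, e.g. from
#'   [make_overdominant_causal()]).
#' @param sigma2_a Additive polygenic variance (squared days).
#' @param sigma2_e Residual variance (squared days).
#' @param pta_mode How the polygenic prediction `a_tilde` (the 2*PTA
#'   column) is produced: `"exact_blup"` (pedigree BLUP of y),
#'   `"noisy"` (BLUP plus noise for reliability `pta_reliability`), or
#'   `"zero"` (no adjustment).
#' @param pta_reliability Squared correlation for `"noisy"` mode.
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 500L, n_generations = 3L,
                       offspring_per_mating = 1L, n_sires = 25L,
                       n_snps = 1000L, maf_range = c(0.05, 0.5),
                       causal = list(), sigma2_a = 25, sigma2_e = 100,
                       pta_mode = c("exact_blup", "noisy", "zero"),
                       pta_reliability = 0.8, seed = 1L) {
  pta_mode <- match.arg(pta_mode)
  stopifnot(sigma2_a > 0, sigma2_e > 0, n_founders > n_sires,
            n_generations >= 0, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  for (cs in causal)
    stopifnot(cs$snp >= 1, cs$snp <= n_snps, length(cs$g) == 3)
  structure(
    list(n_founders = as.integer(n_founders),
         n_generations = as.integer(n_generations),
         offspring_per_mating = as.integer(offspring_per_mating),
         n_sires = as.integer(n_sires), n_snps = as.integer(n_snps),
         maf_range = maf_range, causal = causal,
         sigma2_a = sigma2_a, sigma2_e = sigma2_e,
         pta_mode = pta_mode, pta_reliability = pta_reliability,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic per-stage child seed, kept inside 32-bit integer range
child_seed <- function(master, stage)
  as.integer((as.numeric(master) * 7L + stage * 104729) %% 2147483647)

# one gamete per row from a genotype-code matrix (codes count allele 2)
draw_gametes <- function(G) {
  het <- G == 1
  out <- (G == 2) * 1
  if (any(het))
    out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

#' Simulate a pedigreed population with retained ground truth
#'
#' Founders are drawn at the configured allele frequencies under
#' Hardy-Weinberg proportions; descendants receive one gamete from a
#' randomly assigned sire (from the generation's sire subset) and dam by
#' Mendelian gene dropping, so genotype correlations between relatives
#' are consistent with the numerator relationship matrix. Polygenic
#' values are sampled with covariance `sigma2_a * A` via a Cholesky
#' factor of A; phenotypes are
#' `y = sum of causal genotypic values + a + e`. The polygenic
#' prediction `a_tilde` follows `pta_mode`. Fully reproducible from the
#' config seed.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `sim_population` with `pedigree` (animal,
#'   sire, dam), `genotypes` (animals x SNPs, dimnames set), `phenotypes`
#'   (animal, y, a_tilde), `snp_map` (snp, chr, pos; 29 autosomes filled
#'   round-robin), `A`, and `truth` (list: `a`, `causal`, and per-causal
#'   `effects` data frame with alpha/delta from realized frequencies).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$n_snps

  set.seed(child_seed(cfg$seed, 1L))  # founder frequencies + genotypes
  q2 <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  for (cs in cfg$causal)
    if (!is.null(cs$freq1)) q2[cs$snp] <- 1 - cs$freq1
  geno <- matrix(stats::rbinom(cfg$n_founders * m, 2L, rep(q2, each = cfg$n_founders)),
                 nrow = cfg$n_founders)
  sire <- rep(NA_character_, cfg$n_founders)
  dam <- rep(NA_character_, cfg$n_founders)
  gen_of <- rep(0L, cfg$n_founders)

  set.seed(child_seed(cfg$seed, 2L))  # matings + gene dropping
  prev <- seq_len(cfg$n_founders)
  for (g in seq_len(cfg$n_generations)) {
    sires <- sample(prev, cfg$n_sires)
    n_off <- length(prev) * cfg$offspring_per_mating
    s_idx <- sample(sires, n_off, replace = TRUE)
    d_idx <- sample(prev, n_off, replace = TRUE)
    clash <- d_idx == s_idx
    while (any(clash)) {
      d_idx[clash] <- sample(prev, sum(clash), replace = TRUE)
      clash <- d_idx == s_idx
    }
    off <- draw_gametes(geno[s_idx, , drop = FALSE]) +
      draw_gametes(geno[d_idx, , drop = FALSE])
    new_rows <- nrow(geno) + seq_len(n_off)
    geno <- rbind(geno, off)
    sire <- c(sire, sprintf("A%06d", s_idx))
    dam <- c(dam, sprintf("A%06d", d_idx))
    gen_of <- c(gen_of, rep(g, n_off))
    prev <- new_rows
  }
  n <- nrow(geno)
  ids <- sprintf("A%06d", seq_len(n))
  snp_ids <- sprintf("snp%05d", seq_len(m))
  dimnames(geno) <- list(ids, snp_ids)
  ped <- data.frame(animal = ids, sire = sire, dam = dam,
                    generation = gen_of, stringsAsFactors = FALSE)

  A <- build_A(ped)

  set.seed(child_seed(cfg$seed, 3L))  # polygenic values + residuals
  R <- tryCatch(chol(A), error = function(e) chol(A + 1e-10 * diag(n)))
  a <- sqrt(cfg$sigma2_a) * drop(crossprod(R, stats::rnorm(n)))
  e <- stats::rnorm(n, 0, sqrt(cfg$sigma2_e))
  y <- a + e
  for (cs in cfg$causal)
    y <- y + cs$g[geno[, cs$snp] + 1L]

  set.seed(child_seed(cfg$seed, 4L))  # PTA noise (noisy mode only)
  a_tilde <- switch(cfg$pta_mode,
    zero = rep(0, n),
    exact_blup = blup_intercept(y, A, cfg$sigma2_a, cfg$sigma2_e)$a_hat,
    noisy = {
      ah <- blup_intercept(y, A, cfg$sigma2_a, cfg$sigma2_e)$a_hat
      r2 <- cfg$pta_reliability
      ah + stats::rnorm(n, 0, sqrt((1 - r2) * stats::var(ah)))
    })

  effects <- do.call(rbind, lapply(cfg$causal, function(cs) {
    fr <- compute_snp_frequencies(geno[, cs$snp])
    add <- additive_decomposition(cs$g, fr)
    dom <- dominance_decomposition(cs$g, fr)
    data.frame(snp = snp_ids[cs$snp], alpha = add$alpha,
               delta = dom$delta, d11 = dom$d11, d12 = dom$d12,
               d22 = dom$d22, p1 = fr$p1, stringsAsFactors = FALSE)
  }))

  chr <- rep_len(1:29, m)
  snp_map <- data.frame(snp = snp_ids, chr = chr,
                        pos = 50000L * (seq_len(m) %/% 29 + 1L),
                        stringsAsFactors = FALSE)
  structure(
    list(pedigree = ped, genotypes = geno,
         phenotypes = data.frame(animal = ids, y = y, a_tilde = a_tilde,
                                 stringsAsFactors = FALSE),
         snp_map = snp_map, A = A,
         truth = list(a = a, causal = cfg$causal, effects = effects)),
    class = "sim_population"
  )
}

#' Genotypic values realizing a rare-recessive overdominance pattern
#'
#' Constructs genotypic values `g = (0, s, 0)` (pure heterozygote
#' advantage) whose dominance decomposition at Hardy-Weinberg
#' proportions with recessive-allele (allele 1) frequency `f_R`
#' reproduces the requested recessive-homozygote dominance value `d_RR`
#' exactly. At fixed genotype frequencies the dominance deviations of
#' any genotypic values lie on a one-parameter line (additive components
#' are annihilated), which at HWE is proportional to
#' `(-2 p2^2, 2 p1 p2, -2 p1^2)`; the heterozygote value is therefore
#' determined as `d_DR = -d_RR * f_R / (1 - f_R)` and the request is
#' honoured exactly only when it already satisfies that proportion (as
#' the symmetric case `f_R = 0.5`, `d_RR = -d_DR` does). The scale is
#' fitted to `d_RR`, the feature that drives the culling statistic; when
#' `d_RR = 0` it is fitted to `d_DR` instead.
#'
#' @param f_R Recessive allele (allele 1) frequency, in (0, 0.5].
#' @param d_RR Target dominance value of the recessive homozygote.
#' @param d_DR Requested heterozygote dominance value (see above).
#' @return List with `g` (genotypic values for codes 0/1/2), `d` (the
#'   implied dominance values d11, d12, d22 at HWE), and `f_R`.
#' @export
make_overdominant_causal <- function(f_R, d_RR, d_DR) {
  stopifnot(f_R > 0, f_R <= 0.5)
  p1 <- f_R; p2 <- 1 - f_R
  s <- if (d_RR != 0) -d_RR / (2 * p2^2) else d_DR / (2 * p1 * p2)
  g <- c(0, s, 0)
  d <- c(d11 = -2 * p2^2 * s, d12 = 2 * p1 * p2 * s, d22 = -2 * p1^2 * s)
  list(g = g, d = d, f_R = f_R)
}

#' Count Mendelian inconsistencies between offspring and parents
#'
#' A genotype code is inconsistent when it cannot be formed from one
#' gamete of each parent (e.g. a homozygous 0/0 x 0/0 mating producing a
#' carrier of allele 2). Founders and missing genotypes are skipped.
#'
#' @param genotypes Genotype matrix (animals x SNPs), rownames = ids.
#' @param pedigree Data frame with `animal`, `sire`, `dam`.
#' @return Total number of (animal, SNP) Mendelian violations.
#' @export
check_mendelian <- function(genotypes, pedigree) {
  ids <- rownames(genotypes)
  viol <- 0L
  for (i in seq_len(nrow(pedigree))) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (is.na(s) || is.na(d)) next
    cg <- genotypes[pedigree$animal[i], ]
    sg <- genotypes[s, ]
    dg <- genotypes[d, ]
    ok <- !is.na(cg) & !is.na(sg) & !is.na(dg)
    # allele from sire must exist in sire's genotype, likewise dam
    bad <- ok & ((sg == 0 & cg == 2) | (sg == 2 & cg == 0) |
                   (dg == 0 & cg == 2) | (dg == 2 & cg == 0) |
                   (sg == 0 & dg == 0 & cg != 0) |
                   (sg == 2 & dg == 2 & cg != 2) |
                   (sg == 0 & dg == 2 & cg != 1) |
                   (sg == 2 & dg == 0 & cg != 1))
    viol <- viol + sum(bad)
  }
  viol
}
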