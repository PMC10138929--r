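#' Contribution of a genotype class to the population mean
#'
#' The contribution of one genotype's dominance value to the population
#' mean of the SNP's dominance values is the product `d * f` of the
#' dominance value and the genotype frequency. Comparing the heterozygote
#' and recessive-homozygote contributions shows whether heterozygote
#' advantage offsets a rare, very negative recessive genotype at the
#' population level.
#'
#' @param d Dominance value (trait units).
#' @param f Genotype frequency in `[0, 1]`.
#' @return `d * f`.
#' @export
contribution_to_mean <- function(d, f) {
  stopifnot(all(f >= 0 & f <= 1))
  d * f
}

#' Negative impact of a recessive genotype
#'
#' Difference between the mean phenotype of animals carrying the
#' recessive genotype and the mean of the phenotype means of the two
#' other genotype classes: `y_RR - (y_DR + y_DD) / 2`. Invariant to
#' adding a constant to all class means. The statistic quantifies, per
#' trait, what culling carriers of the recessive genotype would remove.
#'
#' @param y_means Named numeric vector of per-genotype phenotype means
#'   with names `"11"`, `"12"`, `"22"` (NA marks an empty class).
#' @param recessive Label of the recessive homozygote: `"11"` or `"22"`.
#' @return Scalar negative impact in the trait's units.
#' @export
negative_impact <- function(y_means, recessive = c("11", "22")) {
  recessive <- match.arg(recessive)
  stopifnot(all(c("11", "12", "22") %in% names(y_means)))
  if (anyNA(y_means[c("11", "12", "22")]))
    stop("all three genotype classes must be non-empty")
  others <- setdiff(c("11", "22"), recessive)
  unname(y_means[recessive] - (y_means["12"] + y_means[others]) / 2)
}

#' Flag animals homozygous for recessive alleles (culling candidates)
#'
#' For each listed SNP, lists the animals homozygous for the recessive
#' allele. Genotype codes count copies of allele 2, so recessive allele 1
#' means code 0 and recessive allele 2 means code 2.
#'
#' @param genotypes Genotype matrix (animals x SNPs, codes 0/1/2/NA),
#'   with animal ids as rownames and SNP ids as colnames.
#' @param snp_ids Character vector of SNPs to screen (must be columns of
#'   `genotypes`).
#' @param recessive_alleles Integer vector (1 or 2) aligned with
#'   `snp_ids`.
#' @return A list of class `culling_report`: per-SNP entries with
#'   `snp_id`, `recessive_genotype` ("11" or "22"), `carrier_animals`,
#'   `n_carriers`; plus attribute `n_any` = number of animals carrying
#'   the recessive genotype of at least one listed SNP.
#' @export
flag_cull_candidates <- function(genotypes, snp_ids, recessive_alleles) {
  genotypes <- as.matrix(genotypes)
  stopifnot(length(snp_ids) == length(recessive_alleles),
            all(recessive_alleles %in% c(1L, 2L)))
  missing_snp <- setdiff(snp_ids, colnames(genotypes))
  if (length(missing_snp))
    stop("unknown snp_id: ", paste(missing_snp, collapse = ", "))
  animals <- rownames(genotypes)
  if (is.null(animals)) animals <- as.character(seq_len(nrow(genotypes)))
  any_carrier <- logical(nrow(genotypes))
  reports <- lapply(seq_along(snp_ids), function(k) {
    code <- if (recessive_alleles[k] == 1L) 0 else 2
    carr <- !is.na(genotypes[, snp_ids[k]]) &
      genotypes[, snp_ids[k]] == code
    any_carrier <<- any_carrier | carr
    list(snp_id = snp_ids[k],
         recessive_genotype = if (code == 0) "11" else "22",
         carrier_animals = animals[carr],
         n_carriers = sum(carr))
  })
  names(reports) <- snp_ids
  structure(reports, n_any = sum(any_carrier), class = "culling_report")
}

#' Feature flags of a positive-overdominance SNP
#'
#' Checks the characteristic pattern of heterozygote-advantage SNPs for
#' age at first calving: (1) the recessive homozygote has a very negative
#' dominance value; (2) the heterozygote dominance value is positive but
#' small; (3) the dominant homozygote behaves like a neutral genotype
#' (dominance value near zero); (4) the recessive allele is rare
#' (frequency < 0.10); (5) the recessive homozygote is very rare
#' (genotype frequency < 0.01). All flags are `FALSE` unless the SNP is
#' classified as positive overdominance with an identified recessive
#' allele.
#'
#' @param dom A `dominance_decomposition` object.
#' @param freqs The matching `snp_frequencies` object.
#' @param d_rr_max Threshold for "very negative" recessive-homozygote
#'   dominance value (default -5 trait units).
#' @param d_het_max Upper bound for a "small" positive heterozygote
#'   dominance value (default 2).
#' @param d_dd_max Bound on `|d_DD|` for a near-neutral dominant
#'   homozygote (default 1).
#' @param f_r_max Recessive allele frequency bound (default 0.10).
#' @param f_rr_max Recessive genotype frequency bound (default 0.01).
#' @return Named logical vector with elements `recessive_very_negative`,
#'   `het_positive_small`, `dominant_near_zero`, `rare_recessive_allele`,
#'   `rare_recessive_genotype`.
#' @export
overdominance_features <- function(dom, freqs,
                                   d_rr_max = -5, d_het_max = 2,
                                   d_dd_max = 1, f_r_max = 0.10,
                                   f_rr_max = 0.01) {
  out <- c(recessive_very_negative = FALSE,
           het_positive_small = FALSE,
           dominant_near_zero = FALSE,
           rare_recessive_allele = FALSE,
           rare_recessive_genotype = FALSE)
  if (dom$classification != "positive_overdominance" ||
      is.na(dom$recessive_allele))
    return(out)
  if (dom$recessive_allele == 1L) {
    d_rr <- dom$d11; d_dd <- dom$d22
    f_r <- freqs$p1; f_rr <- freqs$P11
  } else {
    d_rr <- dom$d22; d_dd <- dom$d11
    f_r <- freqs$p2; f_rr <- freqs$P22
  }
  out["recessive_very_negative"] <- d_rr < d_rr_max
  out["het_positive_small"] <- dom$d12 > 0 && dom$d12 < d_het_max
  out["dominant_near_zero"] <- abs(d_dd) < d_dd_max
  out["rare_recessive_allele"] <- f_r < f_r_max
  out["rare_recessive_genotype"] <- f_rr < f_rr_max
  out
}
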