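#!/usr/bin/env Rscript

# Step 3: overdominance screening and the culling report.
#
# Takes the scan results, examines every SNP classified as positive
# overdominance among the significant dominance effects, checks the five
# rare-recessive features (very negative d_RR, small positive d_DR,
# near-neutral d_DD, f_R < 0.10, f_RR < 0.01), quantifies each
# genotype's contribution to the population mean (d x f), lists the
# animals carrying the recessive genotype, and computes the per-trait
# negative impact y_RR - (y_DR + y_DD)/2 on the raw phenotypes.

suppressPackageStartupMessages(library(aglsgwas))

scan <- read_results("results/02_scan.tsv")
geno <- read_genotypes("scratch/sim/genotypes.tsv")
phen <- read_phenotypes("scratch/sim/phenotypes.csv")

cand <- scan[!is.na(scan$sig_dom) & scan$sig_dom &
               scan$classification == "positive_overdominance" &
               !is.na(scan$recessive_allele), ]
message(nrow(cand), " significant positive-overdominance SNP(s)")

dir.create("results", showWarnings = FALSE)
if (nrow(cand) == 0) {
  utils::write.table(
    data.frame(snp = character(), recessive_genotype = character(),
               n_carriers = integer(), negative_impact_days = numeric()),
    "results/03_culling_report.tsv", sep = "\t", quote = FALSE,
    row.names = FALSE)
  quit(status = 0)
}

rows <- lapply(seq_len(nrow(cand)), function(i) {
  s <- cand[i, ]
  codes <- geno[, s$snp]
  f <- compute_snp_frequencies(codes)
  dom <- structure(list(d11 = s$d11, d12 = s$d12, d22 = s$d22,
                        delta = s$delta, classification = s$classification,
                        recessive_allele = s$recessive_allele),
                   class = "dominance_decomposition")
  flags <- overdominance_features(dom, f)
  rec_code <- if (s$recessive_allele == 1L) 0 else 2
  het_f <- f$P12
  rec_f <- if (rec_code == 0) f$P11 else f$P22
  y_means <- tapply(phen$y, factor(codes, 0:2, c("11", "12", "22")),
                    mean)
  impact <- negative_impact(y_means,
                            if (rec_code == 0) "11" else "22")
  cull <- flag_cull_candidates(geno, s$snp, s$recessive_allele)
  message(sprintf(
    "%s: delta = %.2f, %d/5 features, het contribution %.3f, recessive contribution %.3f",
    s$snp, s$delta, sum(flags),
    contribution_to_mean(s$d12, het_f),
    contribution_to_mean(if (rec_code == 0) s$d11 else s$d22, rec_f)))
  data.frame(snp = s$snp,
             recessive_genotype = if (rec_code == 0) "11" else "22",
             n_features = sum(flags),
             het_contribution = contribution_to_mean(s$d12, het_f),
             recessive_contribution =
               contribution_to_mean(if (rec_code == 0) s$d11 else s$d22,
                                    rec_f),
             n_carriers = cull[[s$snp]]$n_carriers,
             negative_impact_days = impact,
             stringsAsFactors = FALSE)
})
report <- do.call(rbind, rows)
utils::write.table(report, "results/03_culling_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/03_culling_report.tsv")
print(report, digits = 3)
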