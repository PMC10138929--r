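Package: aglsgwas
Title: Additive and Dominance GWAS by Approximate Generalized Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-SNP genome-wide association analysis for pedigreed
    populations using approximate generalized least squares (AGLS):
    phenotypes pre-adjusted by twice the predicted transmitting ability
    are fitted per SNP as genotype cell means, and additive and dominance
    effects are tested with frequency-adjusted contrasts that remain valid
    under Hardy-Weinberg disequilibrium. Includes the full quantitative
    genetics decomposition of genotypic values (allelic means and effects,
    average effect of gene substitution, dominance deviations),
    overdominance screening with recessive-genotype culling statistics,
    an exact small-scale mixed-model oracle (numerator relationship
    matrix, Henderson's mixed model equations, GLS), nearest-gene SNP
    annotation, and a pedigreed gene-dropping simulator with retained
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    rtracklayer,
    stats,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
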