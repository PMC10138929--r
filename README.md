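# aglsgwas

Single-SNP genome-wide association analysis of additive and dominance
effects in large pedigreed populations, built around the *approximate
generalized least squares* (AGLS) shortcut used for dairy-cattle traits
such as age at first calving (AFC, recorded in negative days so larger
is younger). The package is organised as an analysis workflow: the
estimators live in `R/`, and the numbered scripts under `analysis/`
drive a complete simulate → scan → screen → annotate study on a
synthetic pedigreed population (the motivating cow data are held by
third parties, so a gene-dropping simulator with retained ground truth
stands in for them).

## The method

For phenotypic residuals `y` and polygenic predictions `ã = 2·PTA`,
AGLS analyses `y* = y − ã` per SNP with the cell-means model: the
estimates of the genotypic values `g = (g₁₁, g₁₂, g₂₂)` are the class
means of `y*`. Two contrasts are tested with
`t = |s′ĝ| / √(v² Σⱼ sⱼ²/nⱼ)`:

* additive: `s_a = (P₁₁/p₁, 0.5·P₁₂(p₂−p₁)/(p₁p₂), −P₂₂/p₂)`, the
  frequency-adjusted contrast equal to the average effect of gene
  substitution `α = μ₁ − μ₂` under arbitrary Hardy–Weinberg
  disequilibrium (it reduces to `(p₁, p₂−p₁, −p₂)` under equilibrium);
* dominance: `s_d = (−0.5, 1, −0.5)`, equal to
  `δ = d₁₂ − (d₁₁ + d₂₂)/2` with `d_ij = g_ij − μ − a_i − a_j`.

Around the tests sit the full quantitative-genetics decomposition
(allelic means `μᵢ`, allelic effects `aᵢ` and cross-SNP effects
`aeᵢ = μᵢ − μ_all`), positive-overdominance classification with
five-feature screening of rare-recessive heterozygote-advantage loci,
genotype contributions to the population mean (`d × f`), the
recessive-genotype culling statistic `y_RR − (y_DR + y_DD)/2`, an exact
small-scale mixed-model oracle (tabular-method `A`, Henderson MME,
explicit-V GLS) that validates the shortcut, and nearest-gene SNP
annotation in the `GENE (N bp u/d)` convention. See the methods
vignette (`vignettes/agls-gwas-methods.Rmd`) for assumptions,
parameter choices and known limitations.

## Worked example

The four analysis scripts run from the repository root:

```sh
Rscript analysis/01_simulate.R   # population + ground truth
Rscript analysis/02_scan.R       # AGLS genome scan
Rscript analysis/03_screen.R     # overdominance screening, culling report
Rscript analysis/04_annotate.R   # candidate-gene annotation
```

Step 1 simulates 2,000 cows (500 founders, three generations bred from
25 sires each), 2,000 unlinked SNPs, heritability 0.2 on the adjusted
scale, exact pedigree-BLUP polygenic predictions, and three causal
SNPs — two additive (α = +1 and −1.5 days) and one rare-recessive
overdominant locus (founder recessive-allele frequency 0.081,
recessive-homozygote dominance value −9.76 days). It prints the
realized truth, e.g.:

```
       snp  alpha    delta      d11       d12      d22    p1
1 snp00101  0.997 5.55e-17  0.00361  0.001070 -0.00147 0.289
3 snp00901  4.259 5.78e+00 -8.69646  1.340776 -0.17829 0.125
```

Step 2 reports the scan summary and top effects:

```
1965 SNPs tested; 1 significant additive and 1 significant dominance effects at log10(1/p) > 8
         snp chr     pos   alpha neglog10p_add  delta neglog10p_dom classification
883 snp00901   2 1600000  2.8684        10.412  5.131         8.207 positive_overdominance
```

The overdominant locus is recovered as the top signal in both tests
(its heterozygote-advantage pattern also induces a genuine additive
effect because the allele frequencies are asymmetric). Step 3 screens
it and quantifies the culling case:

```
snp00901: delta = 5.13, 3/5 features, het contribution 0.259, recessive contribution -0.135
       snp recessive_genotype n_features n_carriers negative_impact_days
1 snp00901                 11          3         35                -3.05
```

Thirty-five of 2,000 animals carry the recessive homozygote; their mean
phenotype is 3.05 days worse (older first calving) than the average of
the other two genotype classes. At this population size the recessive
allele has drifted from 0.081 to 0.125, so the two rarity flags are
off — the feature screen reflects the population the SNP is actually
observed in, not the founder configuration. Step 4 attaches nearest
genes, e.g. `GENE2_11 (21822 bp d)`.

All tables land under `results/`; large intermediate files (genotype
matrices) go to `scratch/`.

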