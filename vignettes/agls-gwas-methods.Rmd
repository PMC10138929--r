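---
title: "Additive and dominance GWAS by approximate generalized least squares: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive and dominance GWAS by approximate generalized least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Age at first calving (AFC) in dairy cattle is recorded on a negative-days
scale (a larger value means a younger, more desirable first calving).
Routine genetic evaluation leaves, for each cow, a phenotypic residual
("yield deviation") after removal of fixed non-genetic effects, together
with a predicted transmitting ability (PTA); twice the PTA approximates
the cow's additive breeding value. Given such residuals, a dense SNP
panel and a pedigree, the task is to test every SNP for additive and
dominance effects, decompose significant genotypic values into
quantitative-genetics quantities (allelic means and effects, the average
effect of gene substitution, dominance deviations), screen for
heterozygote-advantage ("positive overdominance") loci driven by a rare
deleterious recessive allele, and quantify what culling carriers of the
recessive genotype would gain.

At national-evaluation scale neither the phenotypic covariance matrix
`V` nor the numerator relationship matrix `A` can be inverted, which
rules out exact GLS or mixed-model estimation per SNP. The package
implements the *approximate generalized least squares* (AGLS) shortcut:
subtract the polygenic prediction from the phenotype once,

    y* = y - a~,   a~ = 2 x PTA,

then analyse `y*` per SNP by ordinary least squares.

## Per-SNP model and estimation

The working model for one SNP is `y = mu 1 + Xg g + Z a + e`, with
`g = (g11, g12, g22)` the genotypic values, `var(a) = sigma2_a A` and
`var(e) = sigma2_e I`. The fixed design `(1, Xg)` is rank deficient; all
reported quantities (contrasts of `g`, with coefficients summing to
zero) are estimable functions, so `fit_snp()` uses the cell-means
parameterization: the estimate of each genotypic value is the class
mean of `y*`, the residual variance `v2` is the pooled within-class
variance with `n - k` degrees of freedom (`k` = non-empty classes), and
the diagonal of the generalized inverse of the genotype block of `X'X`
is `1/n_j`. This choice avoids picking an arbitrary generalized
inverse; the test suite verifies that Moore–Penrose solutions of the
full rank-deficient design give identical contrasts to 1e-9.

Two contrasts of the cell means are tested with t statistics
`t = |s'g_hat| / sqrt(v2 * sum(s_j^2 / n_j))`:

* **additive** — `s_a = (P11/p1, 0.5 P12 (p2 - p1)/(p1 p2), -P22/p2)`,
  where `P_ij` are genotype frequencies and `p_i` allele frequencies of
  the non-missing calls. These frequency-adjusted coefficients make the
  contrast equal to `mu1 - mu2`, the difference of allelic means, for
  *arbitrary* genotype frequencies; under Hardy–Weinberg equilibrium
  they reduce to `(p1, p2 - p1, -p2)` (verified to 1e-12 across a
  frequency grid).
* **dominance** — the fixed `s_d = (-0.5, 1, -0.5)`, equal to
  `delta = d12 - (d11 + d22)/2` because additive components cancel; no
  frequency adjustment is applied, matching the method's definition.

`log10(1/p)` is computed from the log survival function of the t
distribution, so it remains finite and exact when the p-value
underflows double precision (the p-value itself is then stored as 0 and
flagged). Zero residual variance with a non-zero contrast is reported
at the smallest representable p-value and flagged rather than dividing
by zero.

## Quantitative-genetics decomposition

For each SNP passing the minor-allele-frequency filter,
`additive_decomposition()` computes allelic means
`mu1 = (P11/p1) g11 + 0.5 (P12/p1) g12` and
`mu2 = 0.5 (P12/p2) g12 + (P22/p2) g22`, the SNP genotypic mean
`mu = p1 mu1 + p2 mu2`, allelic effects `a_i = mu_i - mu`, and the
average effect of gene substitution `alpha = mu1 - mu2 = a1 - a2`.
Because `a_i` depends on the SNP's own mean, allelic effects are not
comparable across SNPs; for reporting, effects are re-expressed against
`mu_all`, the unweighted mean of per-SNP genotypic means over all SNPs
passing the MAF filter, computed in a first pass of the scan. (Whether
that average should be taken before or after significance filtering is
genuinely open; pre-filtering is the package's choice because it makes
`mu_all` a property of the dataset rather than of a threshold.)

`dominance_decomposition()` computes dominance values
`d_ij = g_ij - mu - a_i - a_j` and `delta = d12 - (d11 + d22)/2`. A SNP
is *positive overdominant* when `d12 > d11` and `d12 > d22`, and the
recessive allele is the one whose homozygote has the strictly more
negative dominance value; on ties the recessive allele is undefined
(`NA`), since the definition requires a strictly more negative
homozygote. The identities `p1 a1 + p2 a2 = 0`,
`alpha = s_a' g` under arbitrary Hardy–Weinberg disequilibrium, the
equality of `delta` computed in d-space and g-space, and
`sum(P_ij d_ij) = 0` under equilibrium are all enforced at 1e-10 on
randomized inputs.

## Screening statistics

Three biology-facing statistics support the culling recommendation:

* `contribution_to_mean(d, f) = d * f`, the contribution of a genotype
  class's dominance value to the population mean; comparing the
  heterozygote and recessive-homozygote products shows whether
  heterozygote advantage offsets a rare very negative recessive
  genotype (and hence why such alleles persist).
* `negative_impact(y_means, recessive) = y_RR - (y_DR + y_DD)/2` on raw
  per-genotype phenotype means, per trait, invariant to adding a
  constant to all classes.
* `overdominance_features()` flags the five-part rare-recessive
  pattern: `d_RR < -5` days (very negative recessive homozygote),
  `0 < d_DR < 2` days (heterozygote positive but small),
  `|d_DD| < 1` day (near-neutral dominant homozygote), `f_R < 0.10` and
  `f_RR < 0.01`. The `d_RR` cutoff is the natural boundary of the
  reported range of top effects (-9.76 to -5.18 days); the heterozygote
  cutoff is set an order of magnitude below it because under exact
  Hardy–Weinberg proportions a `d_RR` of -9.76 at `f_R = 0.081` forces
  `d_DR = -d_RR f_R/(1 - f_R) = 0.86`, so a cutoff at 1.0 would
  misclassify the generator's own ground truth. All flags are defined
  only for SNPs classified positive overdominant, so a purely additive
  SNP reports all-false rather than a vacuous "near-zero" pass.

## Exact mixed-model oracle

At desk scale the package solves the model exactly and uses the
solution to validate the shortcut. `build_A()` constructs the numerator
relationship matrix by the tabular method (unknown parents are
unrelated founders; the pedigree is topologically sorted internally).
`solve_mme()` solves Henderson's mixed model equations with
`lambda = sigma2_e / sigma2_a` and `gls_estimate()` forms
`(X'V^-1 X)^- X'V^-1 y` with explicit `V`. Three routes to the same
estimable contrasts — explicit-V GLS, the MME solution, and ordinary
least squares on `y - Z a_hat` with `a_hat` taken from the joint MME —
agree to 1e-8 on randomized pedigreed instances; this is the identity
that motivates AGLS. Variance components are always inputs, never
estimated: the method consumes PTAs from an external evaluation, and
REML is out of scope. Numerically, symmetric inverses go through
Cholesky factorization with a 1e-8 ridge fallback (with a warning) for
near-singular matrices; the intercept-only BLUP used by the simulator
avoids forming `A^-1` via `(I + lambda A^-1)^-1 = (A + lambda I)^-1 A`,
one Cholesky of `A + lambda I`.

## The synthetic population

Because the motivating cow data are proprietary, every stage is
exercised on `simulate_population()`: founders drawn at uniform founder
allele frequencies in [0.05, 0.5] under Hardy–Weinberg proportions;
discrete generations of constant size bred by random mating with a
limited sire subset (default 25 per generation), giving the half-sib
family structure typical of dairy; unlinked SNPs transmitted by
Mendelian gene dropping (zero Mendelian violations, by construction and
by test); polygenic values sampled with covariance `sigma2_a A` through
a Cholesky factor of `A`; phenotypes as causal genotypic values plus
polygenic value plus Gaussian residual. Defaults `sigma2_a = 25`,
`sigma2_e = 100` (days^2) give an adjusted-phenotype standard deviation
near 11 days and a narrow-sense heritability of 0.2 on the residual
scale — deliberately at the upper end of what is plausible for a
reproduction trait, so that polygenic confounding and its correction
are clearly visible in the test suite. The `a_tilde` column is, by
`pta_mode`, the exact intercept-only pedigree BLUP of `y`
(`"exact_blup"`), that BLUP plus noise calibrated to a reliability
(`"noisy"`), or zero. One master seed drives deterministic per-stage
child seeds; identical configurations reproduce bit-identical
populations.

`make_overdominant_causal(f_R, d_RR, d_DR)` builds causal genotypic
values `(0, s, 0)` whose decomposition at Hardy–Weinberg proportions
reproduces the requested `d_RR` exactly. The requested pair
`(d_RR, d_DR)` cannot in general both be honoured: the map from
genotypic values to dominance deviations annihilates additive values,
so at fixed genotype frequencies the deviations lie on a
one-dimensional line — at equilibrium proportional to
`(-2 p2^2, 2 p1 p2, -2 p1^2)`, forcing `d_DR = -d_RR f_R/(1 - f_R)`.
The reported rare-recessive pattern (-9.76 with 0.62 at `f_R = 0.081`)
corresponds to genotype frequencies in Hardy–Weinberg *disequilibrium*
(heterozygote excess: 0.152 observed vs 0.149 expected, and 0.005
homozygotes vs 0.0066); the test suite reconstructs that exact pattern
by additionally solving for the heterozygote frequency. For gene
dropping, which produces near-equilibrium genotypes, matching `d_RR` —
the quantity that drives the culling statistic and the feature flags —
is the right anchor, and symmetric equilibrium-consistent requests
round-trip exactly.

### What the simulator does not emulate

No linkage or LD (SNPs segregate independently), no selection across
generations, no genotyping or imputation error, no herd-year-season
structure (residuals are generated directly on the adjusted scale), and
no national multi-trait evaluation behind the PTAs (the exact-BLUP and
noisy modes bracket it). Tests passing on this generator therefore
validate the estimators and their algebra, the filtering and screening
logic, and the pipeline's determinism — not robustness to LD pruning,
selection-induced disequilibrium, or PTA biases.

## What the validation runs show

Three findings from the acceptance suite are worth stating plainly; the
numbers below are the ones the tests and `scripts/acceptance.R`
themselves compute.

**Calibration.** On 10,000 null gene-dropped SNPs with 2,000 animals,
exact-BLUP adjustment and heritability 0.2, the dominance test holds
its nominal 0.05 size (observed ~0.047–0.050) and no SNP in either test
reaches `log10(1/p) > 8`. The additive test, however, is *conservative*
(observed size ~0.022). The mechanism is visible in two companion runs:
with no polygenic variance both tests are nominal, and with polygenic
variance left unadjusted the additive test inflates (~0.10) while the
dominance test stays near nominal. The allele-content contrast lies in
the family-structured directions of the data; BLUP adjustment removes
variance along exactly those directions from `y*`, while the
least-squares variance formula `v2 sum(s_j^2/n_j)` — the method's
second approximation — does not see that removal. The dominance
contrast is orthogonal to additive family structure and is unaffected.

**Attenuation.** For the same reason, the additive effect of a causal
SNP is attenuated under exact-BLUP adjustment: the intercept-only BLUP
absorbs the pedigree-predictable part of the SNP's own additive signal.
At `alpha = 1` day, heritability 0.2 and dense half-sib structure the
attenuation is roughly 45%, while with `pta_mode = "zero"` the
estimator is unbiased. Dominance effects, being orthogonal to the
absorbed additive family signal, are recovered without detectable bias,
and the five overdominance feature flags are all recovered at
n = 5,000. Practically: with PTA-adjusted phenotypes this additive test
ranks SNPs and controls false positives conservatively, but its effect
sizes are lower bounds, and the dominance results are the more directly
interpretable ones.

**Exact identities.** Everything above sits on machinery whose algebra
is checked exactly: GLS = MME = BLUP-adjusted least squares on
estimable contrasts (1e-8 over random pedigreed instances), the
quantitative-genetics identities (1e-10), the Hardy–Weinberg reduction
of `s_a` (1e-12), and the published worked-example arithmetic
(`0.622 x 0.152 = 0.095`, `-9.76 x 0.005 = -0.049`, the dominance
effects 5.53 and 5.51 reconstructed from their dominance values, the
substitution effects -1.02 and -1.04 reconstructed from their allelic
effects).

## Problem sizes and runtime choices

The validation suite uses n = 2,000 animals x 10,000 SNPs for the null
calibration and n = 5,000 x 300 for effect recovery; the analysis
scripts use n = 2,000 x 2,000 with three injected causal SNPs. These
sizes keep every A-matrix operation comfortably dense (the largest
Cholesky is 5,000 x 5,000) while leaving Monte-Carlo error well below
the tolerances being checked. The dense MME/GLS oracle is capped at
n = 2,000 by default — it exists to validate, not to scale; the AGLS
path itself is linear in animals and SNPs.

## Known limitations

* The dominance test requires all three genotype classes; it is
  withheld (not failed) when any class has fewer than 10 observations,
  a guard against residual-variance-driven false positives for rare
  homozygotes. The paper-scale convention of a fixed `log10(1/p) = 8`
  genome-wide threshold is adopted as a constant rather than recomputed
  from the number of tests (0.05 / (2 x 75,524) would give ~7.5 on that
  scale); it is configurable.
* Additive effect sizes under PTA adjustment are attenuated (above);
  comparisons of `alpha` across datasets with different pedigree
  density or heritability are not like-for-like.
* `mu_all` — and therefore the cross-SNP allelic effects `ae_i` —
  depends on the SNP panel through the MAF filter.
* Annotation reports the nearest gene boundary within a window (default
  1 Mb), strand-aware by default (5' side = upstream, genomic-left for
  unknown strand); it is not a transcript-aware consequence predictor.
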