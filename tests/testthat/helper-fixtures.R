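# Shared fixture builders (all generated in code; no stored data).

# exact-HWE frequency object for allele-1 frequency p (bypasses counts)
hwe_freqs <- function(p) {
  structure(list(n11 = NA, n12 = NA, n22 = NA,
                 P11 = p^2, P12 = 2 * p * (1 - p), P22 = (1 - p)^2,
                 p1 = p, p2 = 1 - p, n = NA),
            class = "snp_frequencies")
}

# arbitrary (possibly HWD) frequency object from genotype proportions
hwd_freqs <- function(P11, P12, P22) {
  stopifnot(abs(P11 + P12 + P22 - 1) < 1e-12)
  p1 <- P11 + P12 / 2
  structure(list(n11 = NA, n12 = NA, n22 = NA,
                 P11 = P11, P12 = P12, P22 = P22,
                 p1 = p1, p2 = 1 - p1, n = NA),
            class = "snp_frequencies")
}

# random pedigree: nf unrelated founders, n - nf offspring of random
# earlier animals (parents always precede offspring)
random_pedigree <- function(n, nf = max(4L, n %/% 4L)) {
  sire <- rep(NA_integer_, n)
  dam <- rep(NA_integer_, n)
  for (i in (nf + 1L):n) {
    pair <- sample(seq_len(i - 1L), 2L)
    sire[i] <- pair[1]
    dam[i] <- pair[2]
  }
  data.frame(animal = as.character(seq_len(n)),
             sire = as.character(sire), dam = as.character(dam),
             stringsAsFactors = FALSE)
}

# one random mixed-model instance with a full-rank cell-means SNP design
random_mme_instance <- function(n = 200, sigma2_a = 4, sigma2_e = 9) {
  repeat {
    codes <- sample(0:2, n, TRUE, prob = c(0.3, 0.5, 0.2))
    if (all(tabulate(codes + 1L, 3L) > 0)) break
  }
  ped <- random_pedigree(n)
  A <- build_A(ped)
  spec <- mixed_model_spec(sigma2_a, sigma2_e, A)
  Xg <- sapply(0:2, function(c) as.numeric(codes == c))
  y <- stats::rnorm(n, 0, 3)
  list(y = y, X = Xg, codes = codes, spec = spec)
}
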