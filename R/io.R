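#' Read a genotype matrix
#'
#' Accepts either a plain TSV (first column `animal`, remaining columns
#' one SNP each, header row of SNP ids) or a PLINK `.raw` additive-coded
#' file (header `FID IID PAT MAT SEX PHENOTYPE snp_A ...`; the allele
#' suffix is stripped from SNP names). Codes must be 0, 1, 2 or NA;
#' anything else raises an error naming the offending animal and SNP.
#'
#' @param path Input file; `.raw` is detected by extension (override
#'   with `format`).
#' @param format `"tsv"` or `"raw"`.
#' @return Integer matrix animals x SNPs with dimnames.
#' @export
read_genotypes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "raw") "raw" else "tsv"
  if (format == "raw") {
    df <- utils::read.table(path, header = TRUE, sep = "",
                            stringsAsFactors = FALSE, check.names = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    snp_cols <- setdiff(names(df), meta)
    G <- as.matrix(df[, snp_cols, drop = FALSE])
    rownames(G) <- as.character(df$IID)
    colnames(G) <- sub("_[ACGT0-9]+$", "", snp_cols)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    G <- as.matrix(df[, -1, drop = FALSE])
    rownames(G) <- as.character(df[[1]])
  }
  storage.mode(G) <- "double"
  bad <- which(!is.na(G) & !(G %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid genotype code %s (animal %s, SNP %s)",
                 G[bad[1, 1], bad[1, 2]],
                 rownames(G)[bad[1, 1]], colnames(G)[bad[1, 2]]))
  storage.mode(G) <- "integer"
  G
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes Matrix animals x SNPs with dimnames.
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(animal = rownames(genotypes),
                   as.data.frame(genotypes), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read / write a pedigree (3-column CSV: animal, sire, dam)
#'
#' `0`, empty or `NA` mark unknown parents (normalized to `NA`).
#'
#' @param path CSV path.
#' @return Data frame with character columns `animal`, `sire`, `dam`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  for (col in c("sire", "dam"))
    df[[col]][df[[col]] %in% c("0", "", "NA")] <- NA_character_
  df
}

#' @rdname read_pedigree
#' @param pedigree Data frame with `animal`, `sire`, `dam`.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree[, c("animal", "sire", "dam")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read / write a phenotype table (CSV: animal, y, a_tilde)
#'
#' @param path CSV path.
#' @return Data frame with `animal` (character), `y`, `a_tilde`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal", "y", "a_tilde") %in% names(df)))
  df$animal <- as.character(df$animal)
  df
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame with `animal`, `y`, `a_tilde`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes[, c("animal", "y", "a_tilde")], path,
                   row.names = FALSE, quote = FALSE)
}

#' Read / write a SNP map (TSV: snp, chr, pos)
#'
#' @param path TSV path.
#' @return Data frame with `snp`, `chr`, `pos`.
#' @export
read_snp_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("snp", "chr", "pos") %in% names(df)))
  df$snp <- as.character(df$snp)
  df
}

#' @rdname read_snp_map
#' @param snp_map Data frame with `snp`, `chr`, `pos`.
#' @export
write_snp_map <- function(snp_map, path) {
  utils::write.table(snp_map[, c("snp", "chr", "pos")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a genome-scan results table (TSV)
#'
#' Column semantics mirror the reporting convention for significant
#' effects: SNP, chromosome, position, effect sizes (`alpha`, `delta`),
#' allele/genotype frequencies, allelic effects or dominance values, and
#' `log10(1/p)` for both tests.
#'
#' @param path TSV path.
#' @return Data frame (scan attributes are not round-tripped).
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_results
#' @param results A scan results data frame ([genome_scan()] output).
#' @export
write_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
}

#' Export Manhattan-plot data
#'
#' Writes a long-format TSV of `(chrom, position, neglog10p, test)` with
#' `test` in \{additive, dominance\}, ordered by chromosome (numeric
#' chromosomes first in numeric order, then others lexically) and
#' position, ready for any plotting tool.
#'
#' @param results Scan results data frame with `chr`, `pos`,
#'   `neglog10p_add`, `neglog10p_dom`.
#' @param path Output TSV path.
#' @return The exported data frame, invisibly.
#' @export
export_manhattan <- function(results, path) {
  results <- as.data.frame(results)
  mk <- function(col, label) {
    keep <- !is.na(results[[col]])
    data.frame(chrom = results$chr[keep], position = results$pos[keep],
               neglog10p = results[[col]][keep],
               test = rep(label, sum(keep)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk("neglog10p_add", "additive"),
               mk("neglog10p_dom", "dominance"))
  if (nrow(out) > 0) {
    chr_chr <- as.character(out$chrom)
    num <- suppressWarnings(as.numeric(chr_chr))
    key <- order(is.na(num), num, chr_chr, out$position, out$test)
    out <- out[key, , drop = FALSE]
    rownames(out) <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
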