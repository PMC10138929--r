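#' Annotate a SNP with the nearest gene
#'
#' Reports whether the SNP lies inside a gene (`relation = "in"`,
#' distance 0) or, failing that, the nearest gene within `max_dist` bp
#' with the distance to its nearer boundary. With `strand_aware = TRUE`
#' (default), a SNP on the 5' side of the gene is labelled `upstream` and
#' one on the 3' side `downstream`; for genes of unknown strand (and in
#' the `strand_aware = FALSE` mode) genomic-left is upstream. No gene
#' within the window yields `relation = "none"` with a blank gene name.
#'
#' @param chrom Chromosome of the SNP.
#' @param pos 1-based bp position of the SNP.
#' @param genes Data frame of gene features with columns `chrom`,
#'   `start`, `end` (1-based inclusive), `strand` (`"+"`, `"-"` or
#'   `"*"`), `name`.
#' @param max_dist Maximum distance to report a gene (default 1 Mb).
#' @param strand_aware Use gene orientation for the upstream/downstream
#'   label (default `TRUE`).
#' @param snp_id Optional SNP identifier carried into the result.
#' @return A one-row data frame with `snp_id`, `gene_name` (`""` when no
#'   gene in range), `relation` (`"in"`, `"upstream"`, `"downstream"`,
#'   `"none"`), `distance_bp`.
#' @export
annotate_snp <- function(chrom, pos, genes, max_dist = 1e6,
                         strand_aware = TRUE, snp_id = NA_character_) {
  g <- genes[as.character(genes$chrom) == as.character(chrom), ,
             drop = FALSE]
  none <- data.frame(snp_id = snp_id, gene_name = "",
                     relation = "none", distance_bp = NA_integer_,
                     stringsAsFactors = FALSE)
  if (nrow(g) == 0) {
    if (!any(as.character(genes$chrom) == as.character(chrom)))
      warning("no gene features on chromosome ", chrom)
    return(none)
  }
  inside <- g$start <= pos & pos <= g$end
  if (any(inside)) {
    hit <- g[inside, , drop = FALSE][1, ]
    return(data.frame(snp_id = snp_id, gene_name = hit$name,
                      relation = "in", distance_bp = 0L,
                      stringsAsFactors = FALSE))
  }
  dist <- ifelse(pos < g$start, g$start - pos, pos - g$end)
  j <- which.min(dist)
  if (dist[j] > max_dist) return(none)
  hit <- g[j, , drop = FALSE]
  left_of_gene <- pos < hit$start
  strand <- as.character(hit$strand)
  relation <- if (strand_aware && strand %in% c("+", "-")) {
    if ((strand == "+") == left_of_gene) "upstream" else "downstream"
  } else {
    if (left_of_gene) "upstream" else "downstream"
  }
  data.frame(snp_id = snp_id, gene_name = hit$name, relation = relation,
             distance_bp = as.integer(dist[j]), stringsAsFactors = FALSE)
}

#' Annotate a table of SNPs with nearest genes
#'
#' Vectorized wrapper around [annotate_snp()] adding a rendered
#' `candidate_gene` column in the conventional form `GENE` (SNP inside
#' the gene), `GENE (9664 bp u)` (upstream) / `GENE (3151 bp d)`
#' (downstream), or blank when no gene falls within the window.
#'
#' @param snps Data frame with columns `snp`, `chr`, `pos`.
#' @param genes Gene feature data frame (see [annotate_snp()]).
#' @inheritParams annotate_snp
#' @return Data frame with one row per SNP: `snp_id`, `gene_name`,
#'   `relation`, `distance_bp`, `candidate_gene`.
#' @export
annotate_snps <- function(snps, genes, max_dist = 1e6,
                          strand_aware = TRUE) {
  rows <- lapply(seq_len(nrow(snps)), function(i)
    annotate_snp(snps$chr[i], snps$pos[i], genes, max_dist,
                 strand_aware, snp_id = as.character(snps$snp[i])))
  out <- do.call(rbind, rows)
  out$candidate_gene <- format_annotation(out)
  out
}

#' Render annotations in the "GENE (N bp u/d)" convention
#'
#' @param ann Data frame as returned by [annotate_snp()]/[annotate_snps()].
#' @return Character vector, one rendered label per row.
#' @export
format_annotation <- function(ann) {
  mapply(function(gene, rel, d) {
    switch(rel,
           "in" = gene,
           "upstream" = sprintf("%s (%d bp u)", gene, d),
           "downstream" = sprintf("%s (%d bp d)", gene, d),
           "")
  }, ann$gene_name, ann$relation, ann$distance_bp, USE.NAMES = FALSE)
}

#' Read gene features from GFF3 or BED
#'
#' GFF3 files are filtered to `type == "gene"` records; gene names are
#' taken from the `Name` attribute, falling back to `gene_id` then `ID`.
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; the 4th column supplies the name.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format Override format detection (`"gff3"` or `"bed"`).
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, suitable for [annotate_snp()].
#' @export
read_gene_features <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
    else if (ext == "bed") "bed"
    else stop("cannot infer format from extension: ", ext)
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    name <- df$Name
    if (is.null(name)) name <- rep(NA_character_, nrow(df))
    for (alt in c("gene_id", "ID"))
      if (!is.null(df[[alt]]))
        name <- ifelse(is.na(name), df[[alt]], name)
  } else {
    name <- df$name
    if (is.null(name)) name <- paste0("feature", seq_len(nrow(df)))
  }
  data.frame(chrom = as.character(df$seqnames),
             start = df$start, end = df$end,
             strand = as.character(df$strand),
             name = as.character(name), stringsAsFactors = FALSE)
}
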