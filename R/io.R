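# Plain-text readers/writers for the pipeline's tabular interchange
# formats. All tables are TSV with a header; matrices carry row names in
# the first column. The SNP table and gene annotation can additionally be
# exported as minimal VCF / BED12 for interoperability.

#' Write / read a numeric matrix as TSV
#'
#' @param m matrix with row and column names.
#' @param path file path.
#' @param what name of the first (row name) column.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   the matrix.
#' @export
write_matrix_tsv <- function(m, path, what = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- what
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a data frame as TSV (and read it back)
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export the strain-distinguishing SNP table as VCF
#'
#' Minimal VCFv4.2 with the B6 allele as REF and the Cast allele as ALT;
#' the quality flag and indel distance travel in the INFO column, the
#' containing gene in the ID-adjacent INFO key GENE.
#'
#' @param snp_table data frame as produced by the simulator.
#' @param path output path (uncompressed).
#' @export
write_snp_vcf <- function(snp_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QUAL2,Number=1,Type=String,Description=\"SNP quality class\">",
    "##INFO=<ID=INDELDIST,Number=1,Type=Integer,Description=\"Distance to nearest Cast indel (bp)\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Containing gene\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- sprintf("QUAL2=%s;INDELDIST=%d;GENE=%s", snp_table$quality,
                  snp_table$indel_dist, snp_table$gene)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s",
                     snp_table$chrom, snp_table$pos, snp_table$snp_id,
                     snp_table$b6_allele, snp_table$cast_allele,
                     ifelse(snp_table$quality == "high", "PASS", "LOWQUAL"),
                     info), con)
  invisible(path)
}

#' Export the gene annotation as BED12
#'
#' Single-block BED12 records (one exon spanning the gene model used by
#' the synthetic genome).
#'
#' @param annotation gene annotation data frame.
#' @param path output path.
#' @export
write_gene_bed12 <- function(annotation, path) {
  start0 <- annotation$start - 1L # BED is 0-based half-open
  size <- annotation$end - start0
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                     annotation$chrom, start0, annotation$end,
                     annotation$gene, annotation$strand, start0,
                     annotation$end, size),
             path)
  invisible(path)
}

#' Write the simulation truth ledger as JSON
#'
#' @param truth a [simulation_truth()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    cis = as.list(truth$cis), maternal = as.list(truth$maternal),
    imprinted = truth$imprinted, somite_total = as.list(truth$somite_total),
    somite_allele = as.list(truth$somite_allele),
    hotspot = truth$hotspot), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
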