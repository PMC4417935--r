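#' Expression matrix with library-size normalization
#'
#' Bundles raw per-(gene, embryo) read counts with per-embryo library sizes
#' (total mapped reads) and the derived reads-per-million (RPM) matrix:
#' `rpm = counts / library_size * 1e6`.
#'
#' @param counts integer matrix, genes x embryos.
#' @param library_size positive numeric vector, one entry per embryo;
#'   defaults to the column sums of `counts`.
#' @return list of class `expression_matrix` with elements `counts`,
#'   `library_size`, `rpm`.
#' @export
expression_matrix <- function(counts, library_size = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(library_size) == ncol(counts), all(counts >= 0))
  if (any(library_size <= 0)) stop("library sizes must be positive")
  rpm <- sweep(counts, 2, library_size, `/`) * 1e6
  structure(list(counts = counts, library_size = library_size, rpm = rpm),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d embryos, median library %.3g reads\n",
              nrow(x$counts), ncol(x$counts),
              stats::median(x$library_size)))
  invisible(x)
}

#' Allele-specific read vote table
#'
#' Per-(gene, embryo) fractional read votes for the B6 allele, the Cast
#' allele, and calls matching neither strain ("other"). A read covering n
#' usable SNPs contributes 1/n vote per SNP call, so total vote mass per
#' read is at most 1.
#'
#' @param b6,cast,other non-negative numeric matrices of identical shape.
#' @param snp_reads integer matrix: SNP-covering read count per entry.
#' @return list of class `allele_votes`.
#' @export
allele_votes <- function(b6, cast, other = 0 * b6, snp_reads = NULL) {
  stopifnot(identical(dim(b6), dim(cast)), identical(dim(b6), dim(other)),
            all(b6 >= 0), all(cast >= 0), all(other >= 0))
  if (is.null(snp_reads)) snp_reads <- ceiling(b6 + cast + other)
  stopifnot(identical(dim(b6), dim(snp_reads)))
  if (any(b6 + cast + other > snp_reads + 1e-9)) {
    stop("vote mass exceeds the number of SNP-covering reads")
  }
  structure(list(b6 = b6, cast = cast, other = other, snp_reads = snp_reads),
            class = "allele_votes")
}

#' @export
print.allele_votes <- function(x, ...) {
  cat(sprintf("allele_votes: %d genes x %d embryos, %.4g total informative votes\n",
              nrow(x$b6), ncol(x$b6), sum(x$b6) + sum(x$cast)))
  invisible(x)
}

#' Tally fractional allele votes from read-level SNP calls
#'
#' Implements the 1/n voting rule: a read covering n usable SNPs contributes
#' 1/n vote per SNP to the B6, Cast or "other" total of its gene, so e.g. a
#' read covering 3 SNPs of which 2 match B6 and 1 matches neither allele
#' adds 0.67 B6 votes and 0.33 other votes. Usable SNPs are high-quality
#' calls at least `min_indel_dist` bp from any annotated Cast indel; reads
#' covering no usable SNP contribute nothing.
#'
#' @param read_snp_calls data frame with columns `read_id`, `embryo`,
#'   `gene`, `snp_id`, `call` (the base observed in the read at that SNP).
#' @param snp_table data frame with columns `snp_id`, `b6_allele`,
#'   `cast_allele`, `quality` ("high"/"low"), `indel_dist`.
#' @param gene_annotation gene annotation; calls for genes absent from it
#'   are ignored.
#' @param embryos optional character vector fixing the embryo (column)
#'   order of the result.
#' @param min_indel_dist minimum distance (bp) to the nearest Cast indel.
#' @return an [allele_votes()] table.
#' @export
count_allele_votes <- function(read_snp_calls, snp_table, gene_annotation,
                               embryos = NULL, min_indel_dist = 50) {
  usable <- snp_table$snp_id[snp_table$quality == "high" &
                               snp_table$indel_dist >= min_indel_dist]
  x <- read_snp_calls[read_snp_calls$snp_id %in% usable &
                        read_snp_calls$gene %in% gene_annotation$gene, ,
                      drop = FALSE]
  genes <- gene_annotation$gene
  if (is.null(embryos)) embryos <- sort(unique(read_snp_calls$embryo))
  dims <- list(genes, embryos)
  zero <- matrix(0, nrow = length(genes), ncol = length(embryos),
                 dimnames = dims)
  if (!nrow(x)) {
    return(allele_votes(zero, zero, zero, zero))
  }
  m <- match(x$snp_id, snp_table$snp_id)
  vote_class <- ifelse(x$call == snp_table$b6_allele[m], "b6",
                       ifelse(x$call == snp_table$cast_allele[m], "cast", "other"))
  per_read <- 1 / tapply(rep(1, nrow(x)), x$read_id, sum)[as.character(x$read_id)]
  tally <- function(cls) {
    sel <- vote_class == cls
    if (!any(sel)) return(zero)
    t <- tapply(per_read[sel], list(factor(x$gene[sel], levels = genes),
                                    factor(x$embryo[sel], levels = embryos)),
                sum, default = 0)
    t[is.na(t)] <- 0
    dimnames(t) <- dims
    t
  }
  # SNP-covering read count: distinct reads per (gene, embryo)
  rd <- tapply(as.character(x$read_id), list(factor(x$gene, levels = genes),
                                             factor(x$embryo, levels = embryos)),
               function(v) length(unique(v)), default = 0)
  rd <- matrix(as.numeric(rd), nrow = length(genes), dimnames = dims)
  allele_votes(tally("b6"), tally("cast"), tally("other"), rd)
}

#' Count exon-overlapping reads per gene and derive RPM
#'
#' Assigns filtered alignments to genes by exon overlap (via
#' `GenomicRanges::findOverlaps`); alignments overlapping no exon, or more
#' than one gene, are discarded. Library size is the total number of mapped
#' reads per embryo (including unassigned ones), the denominator of RPM.
#'
#' @param alignments data frame with columns `embryo`, `chrom`, `pos`
#'   (1-based alignment start) and optionally `width` (default 1).
#' @param gene_annotation data frame with `gene`, `chrom`, `start`, `end`
#'   (exonic span per gene; for multi-exon models supply one row per exon).
#' @param embryos optional character vector fixing embryo order.
#' @return an [expression_matrix()].
#' @export
quantify_expression <- function(alignments, gene_annotation, embryos = NULL) {
  if (is.null(embryos)) embryos <- sort(unique(alignments$embryo))
  w <- if ("width" %in% names(alignments)) alignments$width else 1L
  reads <- GenomicRanges::GRanges(alignments$chrom,
                                  IRanges::IRanges(alignments$pos, width = w))
  exons <- GenomicRanges::GRanges(gene_annotation$chrom,
                                  IRanges::IRanges(gene_annotation$start,
                                                   gene_annotation$end))
  hits <- GenomicRanges::findOverlaps(reads, exons)
  qh <- S4Vectors_queryHits(hits)
  gene_of_hit <- gene_annotation$gene[S4Vectors_subjectHits(hits)]
  # drop reads assigned to more than one distinct gene
  ngene <- tapply(gene_of_hit, qh, function(g) length(unique(g)))
  ok_reads <- as.integer(names(ngene)[ngene == 1L])
  keep <- !duplicated(qh) & qh %in% ok_reads
  genes <- unique(gene_annotation$gene)
  counts <- tapply(rep(1L, sum(keep)),
                   list(factor(gene_of_hit[keep], levels = genes),
                        factor(alignments$embryo[qh[keep]], levels = embryos)),
                   sum, default = 0L)
  counts <- matrix(as.integer(counts), nrow = length(genes),
                   dimnames = list(genes, embryos))
  libsize <- as.numeric(table(factor(alignments$embryo, levels = embryos)))
  expression_matrix(counts, stats::setNames(libsize, embryos))
}

# thin indirection so the package works with the plain generics
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' Gene inclusion mask for downstream analyses
#'
#' A gene is kept iff its mean RPM across embryos is at least `min_rpm`, at
#' most 5% of its mapped reads were removed by the ambiguous-alignment
#' filter, it is not on the retrogene exclusion list, and it is autosomal.
#'
#' @param expr an [expression_matrix()].
#' @param filtered_read_fraction named numeric vector in \[0, 1\]: per gene,
#'   the fraction of mapped reads discarded by the second-best-hit filter
#'   (missing genes are treated as 0).
#' @param retrogenes character vector of genes to exclude.
#' @param gene_annotation annotation with `gene` and `chrom` columns.
#' @param min_rpm expression floor, in RPM.
#' @param max_filtered_fraction ambiguity ceiling.
#' @param autosomes chromosome names considered autosomal.
#' @return named logical vector over the genes of `expr`.
#' @export
apply_gene_filters <- function(expr, filtered_read_fraction = NULL,
                               retrogenes = character(0),
                               gene_annotation = NULL,
                               min_rpm = 5, max_filtered_fraction = 0.05,
                               autosomes = paste0("chr", 1:19)) {
  genes <- rownames(expr$rpm)
  frac <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(filtered_read_fraction)) {
    stopifnot(all(filtered_read_fraction >= 0 & filtered_read_fraction <= 1))
    shared <- intersect(names(filtered_read_fraction), genes)
    frac[shared] <- filtered_read_fraction[shared]
  }
  autosomal <- rep(TRUE, length(genes))
  if (!is.null(gene_annotation)) {
    autosomal <- gene_annotation$chrom[match(genes, gene_annotation$gene)] %in%
      autosomes
  }
  rowMeans(expr$rpm) >= min_rpm & frac <= max_filtered_fraction &
    !(genes %in% retrogenes) & autosomal
}

#' Call embryo sex from Xist expression
#'
#' Xist RPM is bimodal across embryos (robust expression in females, little
#' or none in males). Sexes are assigned by 1-D 2-means clustering: the
#' threshold is the midpoint between the two cluster means and the high mode
#' is female. If the two modes are not separated (cluster means closer than
#' `min_separation`-fold, or a degenerate constant vector) every embryo is
#' returned as "unknown" with a warning.
#'
#' @param xist_rpm numeric vector of Xist RPM, one entry per embryo.
#' @param min_separation minimum ratio of high to low cluster mean
#'   (computed on log1p scale) required to call the distribution bimodal.
#' @return character vector of "F", "M" or "unknown", same length/names as
#'   `xist_rpm`.
#' @export
assign_sex <- function(xist_rpm, min_separation = 4) {
  out <- stats::setNames(rep("unknown", length(xist_rpm)), names(xist_rpm))
  if (length(unique(xist_rpm)) < 2) {
    warning("Xist expression is constant; sex cannot be assigned")
    return(out)
  }
  km <- stats::kmeans(log1p(xist_rpm), centers = range(log1p(xist_rpm)))
  lo <- min(km$centers)
  hi <- max(km$centers)
  if (expm1(hi) < min_separation * (expm1(lo) + 1)) {
    warning("Xist expression does not separate into two modes; sex unknown")
    return(out)
  }
  threshold <- (lo + hi) / 2
  ifelse(log1p(xist_rpm) > threshold, "F", "M")
}

#' Subset an allele vote table by embryo
#'
#' @param votes an [allele_votes()] table.
#' @param embryos column names or indices to keep.
#' @return an [allele_votes()] table over the selected embryos.
#' @export
subset_votes <- function(votes, embryos) {
  allele_votes(b6 = votes$b6[, embryos, drop = FALSE],
               cast = votes$cast[, embryos, drop = FALSE],
               other = votes$other[, embryos, drop = FALSE],
               snp_reads = votes$snp_reads[, embryos, drop = FALSE])
}

#' Per-gene or per-entry B6 allele fraction
#'
#' BAF = b6 / (b6 + cast); "other" votes are excluded from the denominator.
#' Entries with fewer than `min_votes` informative votes are NA.
#'
#' @param votes an [allele_votes()] table.
#' @param min_votes minimum informative (B6 + Cast) votes.
#' @param pool if TRUE, return one pooled BAF per gene (votes summed across
#'   embryos, optionally restricted with `use`); otherwise a matrix.
#' @param use optional logical matrix selecting the (gene, embryo) entries
#'   that may contribute (e.g. heterozygous embryos only).
#' @return numeric matrix (genes x embryos) or named vector (pooled).
#' @export
baf <- function(votes, min_votes = 1, pool = FALSE, use = NULL) {
  b6 <- votes$b6
  cast <- votes$cast
  if (!is.null(use)) {
    b6 <- b6 * use
    cast <- cast * use
  }
  if (pool) {
    tot <- rowSums(b6) + rowSums(cast)
    out <- rowSums(b6) / tot
    out[tot < min_votes] <- NA_real_
    return(out)
  }
  tot <- b6 + cast
  out <- b6 / tot
  out[tot < min_votes] <- NA_real_
  out
}
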