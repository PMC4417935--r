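#' Test genes for allele-specific expression
#'
#' For every embryo heterozygous at a gene, the allelic difference
#' d = (Cast votes - B6 votes) / library size x 1e6 puts both deeply and
#' shallowly sequenced embryos on a common per-million scale; a one-sample
#' (paired) t-test then asks whether the differences deviate from 0 across
#' embryos. F1 and N2 heterozygotes are pooled. Significance requires a
#' Bonferroni-corrected p below `alpha` and a mean B6 allele fraction
#' outside the `baf_window` (biological-effect filter).
#'
#' @param votes an [allele_votes()] table.
#' @param genotypes genes x embryos integer matrix (1 = heterozygous); only
#'   heterozygous embryos contribute.
#' @param library_size per-embryo total mapped reads.
#' @param min_embryos minimum contributing embryos for a gene to be tested.
#' @param alpha significance level on the Bonferroni-corrected p.
#' @param baf_window mean-BAF interval inside which a gene is never called
#'   (balanced expression).
#' @return data frame per gene: `mean_baf` (mean of per-embryo BAFs),
#'   `mean_diff` (mean normalized allelic difference), `t`, `p`,
#'   `p_bonferroni`, `n_embryos`, `significant`. Untested genes carry NA
#'   and are excluded from the Bonferroni denominator.
#' @export
test_ase <- function(votes, genotypes, library_size, min_embryos = 3,
                     alpha = 0.01, baf_window = c(0.45, 0.55)) {
  stopifnot(identical(dim(votes$b6), dim(genotypes)),
            ncol(votes$b6) == length(library_size))
  het <- !is.na(genotypes) & genotypes == 1L
  informative <- (votes$b6 + votes$cast) > 0 & het
  d <- sweep(votes$cast - votes$b6, 2, library_size, `/`) * 1e6
  d[!informative] <- NA_real_
  tt <- row_t_test(d)
  bafs <- baf(votes)
  bafs[!informative] <- NA_real_
  mean_baf <- rowMeans(bafs, na.rm = TRUE)
  mean_baf[tt$n == 0] <- NA_real_
  tested <- tt$n >= min_embryos & !is.na(tt$p)
  p_bonf <- ifelse(tested, pmin(tt$p * sum(tested), 1), NA_real_)
  significant <- tested & p_bonf < alpha &
    (mean_baf < baf_window[1] | mean_baf > baf_window[2])
  data.frame(gene = rownames(votes$b6), mean_baf = mean_baf,
             mean_diff = tt$mean, t = ifelse(tested, tt$t, NA_real_),
             p = ifelse(tested, tt$p, NA_real_), p_bonferroni = p_bonf,
             n_embryos = tt$n, significant = significant,
             row.names = rownames(votes$b6), stringsAsFactors = FALSE)
}

#' Test genes for genomic imprinting via the reciprocal cross
#'
#' Parent-of-origin effects flip the favored allele between the two sides
#' of a reciprocal cross, while cis effects bias both sides the same way.
#' Votes of heterozygous embryos are pooled within each cross direction
#' (mothers that transmit the B6 allele to heterozygotes versus mothers
#' that transmit the Cast allele), and the pooled count of maternal-allele
#' votes is tested against the expectation under no parent-of-origin
#' effect: the gene's direction-pooled B6 fraction mapped into
#' maternal-allele space. Significance requires a Bonferroni-corrected
#' two-sided binomial p below `alpha` and deviations of the two cross
#' directions in opposite allele directions.
#'
#' @param votes an [allele_votes()] table.
#' @param genotypes genes x embryos matrix (1 = heterozygous).
#' @param metadata metadata with `cross` and `mother` columns.
#' @param alpha significance level on the corrected p.
#' @param min_votes minimum pooled informative votes per direction.
#' @return data frame per gene: `baf_b6_mother`, `baf_other_mother` (Cast
#'   or F1 mother), `cross_difference` (B6-mother minus other-mother BAF),
#'   `p`, `p_bonferroni`, `significant`. Genes with votes in only one
#'   direction are untested (NA).
#' @export
test_imprinting <- function(votes, genotypes, metadata, alpha = 0.01,
                            min_votes = 1) {
  het <- !is.na(genotypes) & genotypes == 1L
  b6_mother <- metadata$mother == "B6"
  pool <- function(m, sel) rowSums(m[, sel, drop = FALSE] * het[, sel, drop = FALSE])
  b6_1 <- pool(votes$b6, b6_mother)
  cast_1 <- pool(votes$cast, b6_mother)
  b6_2 <- pool(votes$b6, !b6_mother)
  cast_2 <- pool(votes$cast, !b6_mother)
  n1 <- b6_1 + cast_1
  n2 <- b6_2 + cast_2
  baf1 <- b6_1 / n1
  baf2 <- b6_2 / n2
  pooled_baf <- (b6_1 + b6_2) / (n1 + n2)
  # maternal allele: B6 in the B6-mother direction, Cast otherwise
  maternal <- b6_1 + cast_2
  p0 <- (n1 * pooled_baf + n2 * (1 - pooled_baf)) / (n1 + n2)
  genes <- rownames(votes$b6)
  p <- rep(NA_real_, length(genes))
  tested <- n1 >= min_votes & n2 >= min_votes
  for (g in which(tested)) {
    p[g] <- stats::binom.test(round(maternal[g]), round(n1[g] + n2[g]),
                              p = p0[g])$p.value
  }
  p_bonf <- ifelse(tested, pmin(p * sum(tested), 1), NA_real_)
  opposite <- (baf1 - pooled_baf) * (baf2 - pooled_baf) < 0
  significant <- tested & p_bonf < alpha & opposite
  significant[is.na(significant)] <- FALSE
  data.frame(gene = genes, baf_b6_mother = baf1, baf_other_mother = baf2,
             cross_difference = baf1 - baf2, p = p, p_bonferroni = p_bonf,
             significant = significant, row.names = genes,
             stringsAsFactors = FALSE)
}

#' Somite-dependent allele-specific expression
#'
#' Correlates each gene's per-embryo B6 allele fraction (heterozygous
#' embryos only) with somite count by Spearman correlation, with
#' Benjamini-Hochberg q-values. Detects alleles whose relative expression
#' changes over developmental time.
#'
#' @param votes an [allele_votes()] table.
#' @param genotypes genes x embryos matrix (1 = heterozygous).
#' @param metadata metadata with a `somites` column (NA allowed).
#' @param q_threshold FDR threshold for the `significant` flag.
#' @param min_embryos minimum heterozygous embryos with a defined BAF.
#' @param min_somite_levels minimum distinct somite counts spanned.
#' @return data frame per gene: `rho`, `p`, `q`, `n_embryos`,
#'   `significant`.
#' @export
test_developmental_ase <- function(votes, genotypes, metadata,
                                   q_threshold = 0.10, min_embryos = 10,
                                   min_somite_levels = 5) {
  bafs <- baf(votes)
  het <- !is.na(genotypes) & genotypes == 1L
  bafs[!het] <- NA_real_
  res <- row_spearman(bafs, metadata$somites, min_n = min_embryos)
  levels_ok <- vapply(seq_len(nrow(bafs)), function(g) {
    ok <- !is.na(bafs[g, ]) & !is.na(metadata$somites)
    length(unique(metadata$somites[ok])) >= min_somite_levels
  }, logical(1))
  tested <- !is.na(res$p) & levels_ok
  res$p[!tested] <- NA_real_
  q <- rep(NA_real_, length(res$p))
  q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  data.frame(gene = rownames(votes$b6), rho = ifelse(tested, res$rho, NA),
             p = res$p, q = q, n_embryos = res$n,
             significant = tested & q < q_threshold,
             row.names = rownames(votes$b6), stringsAsFactors = FALSE)
}

#' Somite-dependent total expression
#'
#' Spearman correlation of library-normalized expression (RPM) with somite
#' count per gene, Benjamini-Hochberg corrected.
#'
#' @param expr an [expression_matrix()].
#' @param metadata metadata with a `somites` column.
#' @param q_threshold FDR threshold for the `significant` flag.
#' @param genes optional subset of genes to test (e.g. those passing
#'   [apply_gene_filters()]).
#' @param min_embryos minimum embryos with recorded somite counts.
#' @return data frame per tested gene: `rho`, `p`, `q`, `significant`.
#' @export
test_developmental_expression <- function(expr, metadata, q_threshold = 0.05,
                                          genes = NULL, min_embryos = 10) {
  Y <- expr$rpm
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  res <- row_spearman(Y, metadata$somites, min_n = min_embryos)
  tested <- !is.na(res$p)
  q <- rep(NA_real_, length(res$p))
  q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  data.frame(gene = rownames(Y), rho = res$rho, p = res$p, q = q,
             n_embryos = res$n, significant = tested & q < q_threshold,
             row.names = rownames(Y), stringsAsFactors = FALSE)
}
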