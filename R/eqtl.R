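#' Covariate- and hidden-factor-normalized expression
#'
#' Removes known technical and developmental covariates (sex, sequencing
#' batch, somite count; missing somite counts are mean-imputed) from
#' log(RPM + 1) by linear regression, then removes the top `k` principal
#' factors of the residual matrix to absorb unknown structure. Residuals
#' have per-gene mean 0 and are orthogonal to the covariate columns.
#'
#' @param expr an [expression_matrix()].
#' @param metadata metadata with `sex` (or supply `sex`), `batch`,
#'   `somites` columns.
#' @param k_hidden_factors number of residual principal factors to remove;
#'   must be smaller than the number of embryos.
#' @param genes optional subset of genes.
#' @param embryos optional subset of embryos (column names).
#' @param sex optional per-embryo sex vector overriding `metadata$sex`.
#' @return genes x embryos matrix of class `normalized_expression`.
#' @export
normalize_expression <- function(expr, metadata, k_hidden_factors = 5,
                                 genes = NULL, embryos = NULL, sex = NULL) {
  Y <- log(expr$rpm + 1)
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  if (!is.null(embryos)) {
    keep <- match(embryos, colnames(Y))
    Y <- Y[, keep, drop = FALSE]
    metadata <- metadata[keep, , drop = FALSE]
    if (!is.null(sex)) sex <- sex[keep]
  }
  n <- ncol(Y)
  if (k_hidden_factors >= n) stop("k_hidden_factors must be < number of embryos")
  if (is.null(sex)) sex <- metadata$sex
  somites <- metadata$somites
  somites[is.na(somites)] <- mean(somites, na.rm = TRUE)
  covars <- data.frame(sex = factor(sex), batch = factor(metadata$batch),
                       somites = somites)
  keep_cov <- vapply(covars, function(v) length(unique(v)) > 1, logical(1))
  X <- stats::model.matrix(~ ., covars[, keep_cov, drop = FALSE])
  Q <- qr.Q(qr(X))
  R <- Y - (Y %*% Q) %*% t(Q)
  if (k_hidden_factors > 0) {
    sv <- svd(R, nu = 0, nv = k_hidden_factors)
    V <- sv$v
    R <- R - (R %*% V) %*% t(V)
  }
  structure(R, class = c("normalized_expression", "matrix", "array"),
            covariates = X, k = k_hidden_factors)
}

# rank cache so that markers sharing an embryo-inclusion pattern (usually
# "all embryos") rank the expression matrix only once per scan
make_rank_cache <- function(Y) {
  cache <- new.env(parent = emptyenv())
  function(incl) {
    key <- paste(incl, collapse = ",")
    got <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(got)) {
      got <- row_ranks(Y, incl)
      assign(key, got, envir = cache)
    }
    got
  }
}

# Rank-sum p-value matrix: genes x markers. markers$genotypes is the
# regions x embryos consensus matrix (0 hom / 1 het / NA). Markers without
# both classes at min_per_class embryos are skipped (NA column). `perm`,
# when given, is a global embryo relabeling applied within each marker's
# genotyped embryos (the order it induces on them reshuffles their
# genotype labels), so permutation scans keep every marker's missingness
# pattern — and therefore the rank cache — unchanged.
scan_pvalue_matrix <- function(norm, marker_geno, min_per_class = 5,
                               rank_for = make_rank_cache(unclass(norm)),
                               perm = NULL) {
  n_marker <- nrow(marker_geno)
  P <- matrix(NA_real_, nrow = nrow(norm), ncol = n_marker,
              dimnames = list(rownames(norm), rownames(marker_geno)))
  for (m in seq_len(n_marker)) {
    g <- marker_geno[m, ]
    incl <- which(!is.na(g))
    if (!length(incl)) next
    grp <- g[incl] == 1L
    if (!is.null(perm)) grp <- grp[order(perm[incl])]
    if (sum(grp) < min_per_class || sum(!grp) < min_per_class) next
    rr <- rank_for(incl)
    P[, m] <- ranksum_from_ranks(rr, grp)$p
  }
  P
}

#' Scan for expression QTL across marker regions
#'
#' For every (gene, marker region) pair, compares normalized expression in
#' heterozygous versus homozygous embryos with a two-sided Wilcoxon
#' rank-sum test (embryos with unknown consensus genotype at the marker are
#' excluded; markers lacking `min_per_class` embryos in either class are
#' skipped). To remove the effect of correlated markers, only the most
#' significant marker region on each chromosome is retained per gene.
#'
#' @param norm a [normalize_expression()] matrix (any genes x embryos
#'   matrix works).
#' @param markers a `marker_regions` object from [build_marker_regions()].
#' @param min_per_class minimum embryos per genotype class at a marker.
#' @param keep_full if TRUE the full gene x marker p-value matrix is
#'   attached (needed for hotspot analysis).
#' @return data frame of class `eqtl_scan`, one row per (gene, chromosome
#'   with a testable marker): `gene`, `marker`, `marker_chrom`, `p`; the
#'   full matrix is in `attr(, "pmatrix")` when requested.
#' @export
scan_eqtl <- function(norm, markers, min_per_class = 5, keep_full = FALSE) {
  stopifnot(inherits(markers, "marker_regions"),
            ncol(norm) == ncol(markers$genotypes))
  P <- scan_pvalue_matrix(norm, markers$genotypes, min_per_class)
  best <- best_marker_per_chromosome(P, markers)
  if (keep_full) attr(best, "pmatrix") <- P
  best
}

# reduce a gene x marker p matrix to the min-p marker per (gene, chromosome)
best_marker_per_chromosome <- function(P, markers) {
  chroms <- markers$regions$chrom
  out <- list()
  for (ch in unique(chroms)) {
    cols <- which(chroms == ch)
    sub <- P[, cols, drop = FALSE]
    ok_marker <- colSums(!is.na(sub)) > 0
    if (!any(ok_marker)) next
    sub <- sub[, ok_marker, drop = FALSE]
    j <- max.col(-replace(sub, is.na(sub), Inf), ties.method = "first")
    pmin_ <- sub[cbind(seq_len(nrow(sub)), j)]
    out[[ch]] <- data.frame(
      gene = rownames(P), marker = colnames(sub)[j], marker_chrom = ch,
      p = pmin_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("eqtl_scan", "data.frame")
  res
}

#' Permutation-based false discovery rates for an eQTL scan
#'
#' Embryo labels of the marker genotype matrix are permuted as a block
#' (preserving the correlation structure among genes) and the identical
#' scan is repeated `n_permutations` times. For each observed record,
#' q(p) = (average permuted count of records with p' <= p, with a
#' pseudocount of one permutation-scale event) / (observed count with
#' p' <= p), monotonized to be non-decreasing in p. The pseudocount
#' (add-one in permutation units) keeps q away from an exact zero that a
#' finite permutation set cannot support.
#'
#' @param norm,markers,min_per_class as in [scan_eqtl()].
#' @param annotation gene annotation (for cis/trans classification of the
#'   returned records).
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @param q_threshold threshold stored in the `significant` column.
#' @param keep_full keep the observed full p matrix (for hotspot testing).
#' @return the observed scan with columns `q`, `classification` ("cis" if
#'   the marker chromosome equals the gene chromosome), and `significant`;
#'   permutation best-p records are attached as `attr(, "perm_p")`, the
#'   full observed and permuted p matrices as `attr(, "pmatrix")` /
#'   `attr(, "perm_pmatrix")` when `keep_full`.
#' @export
eqtl_fdr <- function(norm, markers, annotation, n_permutations = 20,
                     seed = 1, q_threshold = 0.01, min_per_class = 5,
                     keep_full = FALSE) {
  obs <- scan_eqtl(norm, markers, min_per_class, keep_full = keep_full)
  n <- ncol(norm)
  perm_p <- vector("list", n_permutations)
  perm_mats <- if (keep_full) vector("list", n_permutations) else NULL
  rank_for <- make_rank_cache(unclass(norm))
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    P <- scan_pvalue_matrix(norm, markers$genotypes, min_per_class,
                            rank_for, perm = idx)
    bm <- best_marker_per_chromosome(P, markers)
    perm_p[[b]] <- bm$p
    if (keep_full) perm_mats[[b]] <- P
  }
  all_perm <- sort(unlist(perm_p))
  ord <- order(obs$p)
  p_sorted <- obs$p[ord]
  perm_count <- (findInterval(p_sorted, all_perm) + 1) / (n_permutations + 1)
  obs_count <- seq_along(p_sorted)
  q_raw <- perm_count / obs_count
  q_mono <- rev(cummin(rev(q_raw))) # non-decreasing in p
  q <- numeric(length(q_raw))
  q[ord] <- pmin(q_mono, 1)
  obs$q <- q
  obs <- classify_cis_trans(obs, annotation)
  obs$significant <- obs$q < q_threshold
  attr(obs, "perm_p") <- perm_p
  if (keep_full) {
    attr(obs, "perm_pmatrix") <- perm_mats
  }
  attr(obs, "n_permutations") <- n_permutations
  obs
}

#' Classify eQTL records as cis or trans
#'
#' A record is cis iff its marker region lies on the same chromosome as the
#' target gene (a conservative, distance-free definition); otherwise trans.
#'
#' @param results an `eqtl_scan` data frame with `gene` and `marker_chrom`.
#' @param annotation gene annotation (`gene`, `chrom`).
#' @return `results` with a `classification` column.
#' @export
classify_cis_trans <- function(results, annotation) {
  gene_chrom <- annotation$chrom[match(results$gene, annotation$gene)]
  results$classification <- ifelse(results$marker_chrom == gene_chrom,
                                   "cis", "trans")
  results
}

#' Cis/trans eQTL counts as a function of FDR cutoff
#'
#' @param results output of [eqtl_fdr()].
#' @param cutoffs FDR cutoffs to tabulate.
#' @return data frame: cutoff, n_cis, n_trans, trans_fraction.
#' @export
summarize_cis_trans <- function(results, cutoffs = c(0.01, 0.05, 0.1, 0.2)) {
  do.call(rbind, lapply(cutoffs, function(cut) {
    sel <- results$q < cut
    n_cis <- sum(sel & results$classification == "cis")
    n_trans <- sum(sel & results$classification == "trans")
    data.frame(cutoff = cut, n_cis = n_cis, n_trans = n_trans,
               trans_fraction = if (n_cis + n_trans > 0)
                 n_trans / (n_cis + n_trans) else NA_real_)
  }))
}

#' Test for trans-eQTL hotspots
#'
#' A hotspot is a marker whose genotype correlates with expression of
#' unusually many target genes. For every marker the number of target genes
#' with scan p below `threshold` is counted, and the observed distribution
#' of per-marker counts is compared with the pooled counts from
#' permutation scans by a two-sample Kolmogorov-Smirnov test. Optionally
#' the comparison is repeated restricted to markers containing genes in the
#' top half of ASE effect size (|BAF - 0.5|), probing whether strong ASE
#' genes act as trans-controlling loci.
#'
#' @param pmatrix observed gene x marker p matrix (from
#'   [scan_eqtl()]`(keep_full = TRUE)` or [eqtl_fdr()]).
#' @param perm_pmatrices list of permuted p matrices of the same shape.
#' @param threshold per-pair p threshold defining a "significant target".
#' @param markers optional `marker_regions` object plus `ase_effect` (named
#'   |BAF - 0.5| per gene) to run the ASE-subset comparison.
#' @param ase_effect optional named vector of ASE effect sizes.
#' @return list of class `hotspot_test`: `counts`, `null_counts`,
#'   `ks_statistic`, `p` (permutation-calibrated: the KS statistic is
#'   compared against the KS statistics of each permutation scan versus the
#'   pooled null, since per-marker counts are mutually dependent and the
#'   asymptotic two-sample p would be anticonservative), `p_asymptotic`,
#'   and (when requested) `ase_subset` with the same fields for the
#'   restricted marker set.
#' @export
test_hotspots <- function(pmatrix, perm_pmatrices, threshold = 0.005,
                          markers = NULL, ase_effect = NULL) {
  count_of <- function(P) colSums(P < threshold, na.rm = TRUE)
  counts <- count_of(pmatrix)
  perm_counts <- lapply(perm_pmatrices, count_of)
  null_counts <- unlist(perm_counts)
  ks <- suppressWarnings(stats::ks.test(counts, null_counts,
                                        exact = FALSE))
  # per-marker counts are dependent (one gene hits many correlated
  # markers), so the asymptotic two-sample KS p is not trustworthy;
  # calibrate the KS statistic against the permutation scans themselves
  d_of <- function(cts) suppressWarnings(
    stats::ks.test(cts, null_counts, exact = FALSE)$statistic)
  d_perm <- vapply(perm_counts, d_of, numeric(1))
  B <- length(perm_counts)
  p_cal <- (1 + sum(d_perm >= unname(ks$statistic))) / (B + 1)
  out <- list(counts = counts, null_counts = null_counts,
              ks_statistic = unname(ks$statistic), p = p_cal,
              p_asymptotic = ks$p.value, threshold = threshold)
  if (!is.null(markers) && !is.null(ase_effect)) {
    eff <- ase_effect[!is.na(ase_effect)]
    top <- names(eff)[eff >= stats::median(eff)]
    top_regions <- unique(markers$gene_region[top])
    sel <- colnames(pmatrix) %in% top_regions
    if (any(sel)) {
      ks2 <- suppressWarnings(stats::ks.test(
        counts[sel], unlist(lapply(perm_pmatrices,
                                   function(P) count_of(P)[sel])),
        exact = FALSE))
      out$ase_subset <- list(counts = counts[sel],
                             ks_statistic = unname(ks2$statistic),
                             p = ks2$p.value)
    }
  }
  class(out) <- "hotspot_test"
  out
}

#' Predicted versus measured allelic imbalance
#'
#' Under a purely cis model the mean total expression of B6/B6 embryos
#' (two B6 alleles) and of B6/Cast embryos (one of each) determines the
#' expected B6 allele fraction: with baf_exp = mu_hom / (mu_hom + mu_het),
#' the prediction is baf_pred = baf_exp / (2 (1 - baf_exp)), which recovers
#' 0.5 when the genotype classes express equally and 1.0 when the Cast
#' allele is silent (mu_het = mu_hom / 2); sampling noise in the class
#' means can push baf_pred above 1. The record is compared with the BAF
#' measured directly from allele votes in heterozygotes.
#'
#' @param expr an [expression_matrix()].
#' @param genotypes genes x embryos matrix (0 hom / 1 het / NA) — each
#'   gene's own genotype across embryos.
#' @param votes an [allele_votes()] table for the measured BAF.
#' @param min_per_class minimum embryos per genotype class.
#' @param top_n size of the high-coverage subset for the second
#'   correlation (ranked by informative allele votes).
#' @return list of class `concordance`: per-gene data frame (`mu_hom`,
#'   `mu_het`, `baf_exp`, `baf_pred`, `baf_measured`, `coverage`),
#'   `rho_all`, `rho_top` (Spearman correlations of predicted vs measured).
#' @export
ase_eqtl_concordance <- function(expr, genotypes, votes, min_per_class = 5,
                                 top_n = 1000) {
  het <- genotypes == 1L
  hom <- genotypes == 0L
  n_het <- rowSums(het, na.rm = TRUE)
  n_hom <- rowSums(hom, na.rm = TRUE)
  R <- expr$rpm
  mu_het <- rowSums(replace(R, !het | is.na(het), 0)) / pmax(n_het, 1)
  mu_hom <- rowSums(replace(R, !hom | is.na(hom), 0)) / pmax(n_hom, 1)
  baf_exp <- mu_hom / (mu_hom + mu_het)
  baf_pred <- ifelse(baf_exp >= 1, NA_real_, baf_exp / (2 * (1 - baf_exp)))
  use <- !is.na(genotypes) & genotypes == 1L
  baf_measured <- baf(votes, pool = TRUE, use = use)
  coverage <- rowSums((votes$b6 + votes$cast) * use)
  ok <- n_het >= min_per_class & n_hom >= min_per_class &
    !is.na(baf_pred) & !is.na(baf_measured)
  df <- data.frame(gene = rownames(R), mu_hom = mu_hom, mu_het = mu_het,
                   baf_exp = baf_exp, baf_pred = baf_pred,
                   baf_measured = baf_measured, coverage = coverage,
                   testable = ok, row.names = rownames(R),
                   stringsAsFactors = FALSE)
  rho_all <- if (sum(ok) >= 3)
    stats::cor(df$baf_pred[ok], df$baf_measured[ok], method = "spearman")
  else NA_real_
  top <- ok & rank(-coverage, ties.method = "first") <= top_n
  rho_top <- if (sum(top) >= 3)
    stats::cor(df$baf_pred[top], df$baf_measured[top], method = "spearman")
  else NA_real_
  structure(list(records = df, rho_all = rho_all, rho_top = rho_top),
            class = "concordance")
}

#' Correlate regulatory effect with an external conservation score
#'
#' Tests whether genes under stronger cis-regulatory divergence are less
#' evolutionarily constrained: Spearman correlation between a per-gene
#' conservation score (e.g. an average coding GERP score, supplied
#' externally) and a regulatory effect measure — either -log10 of the
#' cis-eQTL p-value or the ASE effect size |BAF - 0.5|. Because very lowly
#' expressed genes are enriched for low scores, genes below an expression
#' floor are removed first.
#'
#' @param effect named numeric vector: the per-gene effect measure, larger
#'   = stronger regulatory effect (e.g. `-log10(p)` or `abs(baf - 0.5)`).
#' @param scores named numeric vector of conservation scores.
#' @param mean_rpm named per-gene mean expression used for the floor.
#' @param min_rpm expression floor.
#' @param min_genes minimum genes after filtering.
#' @return list: `rho`, `p`, `n`.
#' @export
conservation_correlation <- function(effect, scores, mean_rpm = NULL,
                                     min_rpm = 5, min_genes = 20) {
  genes <- intersect(names(effect), names(scores))
  if (!is.null(mean_rpm)) {
    genes <- genes[mean_rpm[genes] >= min_rpm]
  }
  genes <- genes[!is.na(effect[genes]) & !is.na(scores[genes])]
  if (length(genes) < min_genes) {
    stop("fewer than ", min_genes, " genes after expression filtering")
  }
  ct <- suppressWarnings(stats::cor.test(effect[genes], scores[genes],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(genes))
}
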