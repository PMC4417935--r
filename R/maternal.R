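#' Test genes for maternal genetic effects on embryonic expression
#'
#' The backcross design gives N2 embryos genotypically distinct mothers
#' (B6/B6 versus B6/Cast F1) while every N2 carries B6 mitochondria, so a
#' dependence of embryonic expression on the mother's class that is not
#' explained by the embryo's own genotype indicates a maternal effect.
#' Library-normalized expression (RPM) is compared between the two maternal
#' classes with a two-sided Mann-Whitney U test, Bonferroni-corrected over
#' the genes actually tested.
#'
#' @param expr an [expression_matrix()] covering (at least) the N2 embryos.
#' @param metadata metadata with `generation` and `mother` columns.
#' @param genes optional subset of genes to test.
#' @param min_per_class minimum embryos per maternal class.
#' @param alpha significance level on the corrected p.
#' @return data frame per gene: `mean_rpm_f1_mother`, `mean_rpm_b6_mother`,
#'   `fold_change` (larger mean over smaller), `percent_change` (B6-mother
#'   relative to F1-mother), `U`, `p`, `p_bonferroni`, `significant`.
#' @export
test_maternal_effect <- function(expr, metadata, genes = NULL,
                                 min_per_class = 5, alpha = 0.01) {
  stopifnot(nrow(metadata) == ncol(expr$rpm))
  n2 <- metadata$generation == "N2"
  Y <- expr$rpm[, n2, drop = FALSE]
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  b6mom <- metadata$mother[n2] == "B6"
  if (sum(b6mom) < min_per_class || sum(!b6mom) < min_per_class) {
    stop("a maternal class has fewer than min_per_class embryos")
  }
  rs <- row_ranksum_test(Y, b6mom)
  m_b6 <- rowMeans(Y[, b6mom, drop = FALSE])
  m_f1 <- rowMeans(Y[, !b6mom, drop = FALSE])
  tested <- !is.na(rs$p)
  p_bonf <- ifelse(tested, pmin(rs$p * sum(tested), 1), NA_real_)
  data.frame(
    gene = rownames(Y),
    mean_rpm_f1_mother = m_f1, mean_rpm_b6_mother = m_b6,
    fold_change = pmax(m_b6, m_f1) / pmin(m_b6, m_f1),
    percent_change = (m_b6 - m_f1) / m_f1 * 100,
    U = rs$U, p = rs$p, p_bonferroni = p_bonf,
    significant = tested & p_bonf < alpha,
    row.names = rownames(Y), stringsAsFactors = FALSE
  )
}

#' Confound-exclusion battery for maternal-effect calls
#'
#' Re-examines each significant maternal-effect gene under four alternative
#' explanations, flagging the gene when the maternal signal does not
#' survive the re-test:
#' \describe{
#'   \item{sex}{restricted to female embryos (X-dosage confounds): flag if
#'     the effect direction reverses or nominal p >= `recheck_alpha`.}
#'   \item{litter}{litters replace embryos as the unit (expression averaged
#'     within litter): flag as for sex.}
#'   \item{somite}{embryos stratified into somite tertiles: flag if the
#'     effect direction is inconsistent across evaluable tertiles.}
#'   \item{imprinted_locus}{for every supplied imprinted gene, embryos are
#'     regrouped by their own genotype at that locus; flag if any such
#'     embryonic-genotype grouping explains the gene better (smaller MWU p)
#'     than the maternal grouping, i.e. the signal may be a trans effect
#'     downstream of an imprinted locus.}
#' }
#' Checks that cannot be evaluated (too few embryos in a stratum) are NA.
#'
#' @param results output of [test_maternal_effect()].
#' @param expr,metadata as in [test_maternal_effect()].
#' @param genotypes genes x embryos genotype matrix (for the
#'   imprinted-locus check).
#' @param imprinted_genes character vector of imprinted loci.
#' @param sex per-embryo sex calls ("F"/"M"/"unknown"); defaults to
#'   `metadata$sex`.
#' @param recheck_alpha nominal level used by the re-tests.
#' @param min_per_class minimum embryos per group within a re-test.
#' @return data frame: gene plus logical flag columns `flag_sex`,
#'   `flag_litter`, `flag_somite`, `flag_imprinted_locus`.
#' @export
check_confounds <- function(results, expr, metadata, genotypes = NULL,
                            imprinted_genes = character(0),
                            sex = metadata$sex, recheck_alpha = 0.05,
                            min_per_class = 5) {
  sig_genes <- results$gene[results$significant %in% TRUE]
  n2 <- metadata$generation == "N2"
  Y <- expr$rpm[sig_genes, n2, drop = FALSE]
  meta <- metadata[n2, , drop = FALSE]
  sex <- sex[n2]
  b6mom <- meta$mother == "B6"
  base_dir <- sign(results[sig_genes, "mean_rpm_b6_mother"] -
                     results[sig_genes, "mean_rpm_f1_mother"])
  retest <- function(Ysub, grp) {
    # returns per-gene list of (p, direction); NA when not evaluable
    if (sum(grp, na.rm = TRUE) < min_per_class ||
        sum(!grp, na.rm = TRUE) < min_per_class) {
      return(list(p = rep(NA_real_, nrow(Ysub)),
                  dir = rep(NA_real_, nrow(Ysub))))
    }
    rs <- row_ranksum_test(Ysub, grp)
    dirs <- sign(rowMeans(Ysub[, which(grp), drop = FALSE]) -
                   rowMeans(Ysub[, which(!grp), drop = FALSE]))
    list(p = rs$p, dir = dirs)
  }
  # (a) females only
  fem <- sex == "F"
  a <- retest(Y[, fem, drop = FALSE], b6mom[fem])
  flag_sex <- a$p >= recheck_alpha | a$dir != base_dir
  # (b) litter means
  litters <- unique(meta$litter)
  Ylit <- sapply(litters, function(l) rowMeans(Y[, meta$litter == l, drop = FALSE]))
  if (is.null(dim(Ylit))) Ylit <- matrix(Ylit, nrow = nrow(Y), dimnames = list(rownames(Y), litters))
  lit_mom <- vapply(litters, function(l) meta$mother[meta$litter == l][1] == "B6",
                    logical(1))
  b <- retest(Ylit, lit_mom)
  flag_litter <- b$p >= recheck_alpha | b$dir != base_dir
  # (c) somite tertiles: direction must agree in every evaluable tertile
  tert <- cut(meta$somites, stats::quantile(meta$somites, c(0, 1/3, 2/3, 1),
                                            na.rm = TRUE),
              include.lowest = TRUE, labels = FALSE)
  dirs <- sapply(1:3, function(k) {
    sel <- !is.na(tert) & tert == k
    r <- retest(Y[, sel, drop = FALSE], b6mom[sel])
    r$dir
  })
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = nrow(Y))
  flag_somite <- vapply(seq_len(nrow(Y)), function(i) {
    v <- dirs[i, ]
    if (all(is.na(v))) return(NA)
    any(v[!is.na(v)] != base_dir[i])
  }, logical(1))
  # (d) imprinted-locus embryonic genotype as the competing predictor
  flag_imp <- rep(NA, length(sig_genes))
  if (length(imprinted_genes) && !is.null(genotypes)) {
    p_maternal <- results[sig_genes, "p"]
    flag_imp <- vapply(seq_along(sig_genes), function(i) {
      best <- Inf
      for (loc in imprinted_genes) {
        grp <- genotypes[loc, n2] == 1L
        if (sum(grp, na.rm = TRUE) < min_per_class ||
            sum(!grp, na.rm = TRUE) < min_per_class) next
        pv <- row_ranksum_test(Y[i, , drop = FALSE], grp)$p
        best <- min(best, pv, na.rm = TRUE)
      }
      if (!is.finite(best)) return(NA)
      best < p_maternal[i]
    }, logical(1))
  }
  data.frame(gene = sig_genes, flag_sex = flag_sex, flag_litter = flag_litter,
             flag_somite = flag_somite, flag_imprinted_locus = flag_imp,
             row.names = sig_genes, stringsAsFactors = FALSE)
}

#' Validate the mitochondrial design assumption
#'
#' All F1 dams used in the backcross derive from B6 x Cast matings, so every
#' N2 embryo must carry the B6 mitochondrial genome; a mitochondrial
#' confound of maternal effects is thereby excluded structurally rather
#' than statistically. This check asserts the design rule on the metadata.
#'
#' @param metadata metadata with `generation` and `cross` columns.
#' @return invisibly TRUE; stops if an N2 embryo's cross implies non-B6
#'   mitochondria.
#' @export
validate_mitochondrial_design <- function(metadata) {
  n2 <- metadata[metadata$generation == "N2", , drop = FALSE]
  ok <- n2$cross %in% c("F1xB6", "B6xF1")
  if (!all(ok)) {
    stop("N2 embryos with unexpected cross direction (mitochondrial ",
         "background not guaranteed B6): ",
         paste(n2$embryo[!ok], collapse = ", "))
  }
  invisible(TRUE)
}
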