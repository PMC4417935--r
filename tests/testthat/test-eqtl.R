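toy_norm <- function(n_genes = 8, n_embryos = 24, seed = 2) {
  set.seed(seed)
  Y <- matrix(rnorm(n_genes * n_embryos), n_genes, n_embryos,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("e", seq_len(n_embryos))))
  Y
}

toy_markers <- function(geno) {
  ann <- data.frame(gene = rownames(geno),
                    chrom = sub("_.*", "", rownames(geno)),
                    stringsAsFactors = FALSE)
  build_marker_regions(geno, ann)
}

test_that("normalization centers genes and removes covariate structure", {
  cfg <- small_config(seed = 3, batch_sd = 0.3)
  d <- simulate_backcross(cfg)
  norm <- normalize_expression(d$expression, d$metadata, k_hidden_factors = 0)
  expect_lt(max(abs(rowMeans(norm))), 1e-10)
  X <- attr(norm, "covariates")
  expect_lt(max(abs(unclass(norm) %*% X)), 1e-8)
  # between-batch variance collapses relative to the raw matrix
  raw <- log(d$expression$rpm + 1)
  batch_var <- function(M) {
    mean(apply(M, 1, function(v)
      stats::var(tapply(v, d$metadata$batch, mean))))
  }
  expect_lt(batch_var(unclass(norm)) / batch_var(raw), 0.05)
  expect_error(normalize_expression(d$expression, d$metadata,
                                    k_hidden_factors = 500), "k_hidden")
})

test_that("hidden factors absorb batch structure without erasing genotype signal", {
  cfg <- small_config(seed = 31, batch_sd = 0.25,
                      baseline_log_mean = log(150),
                      n_n2_f1xb6 = 65L, n_n2_b6xf1 = 89L)
  tr <- simulation_truth(cis = c(g01_0010 = 2, g02_0010 = 2, g03_0010 = 2))
  d <- simulate_backcross(cfg, tr)
  n2 <- d$metadata$generation == "N2"
  norm <- normalize_expression(d$expression, d$metadata, k_hidden_factors = 3,
                               embryos = d$metadata$embryo[n2])
  for (g in names(tr$cis)) {
    grp <- d$genotypes[g, n2] == 1L
    p <- stats::wilcox.test(norm[g, grp], norm[g, !grp],
                            exact = FALSE)$p.value
    expect_lt(p, 1e-4)
  }
})

test_that("the scan reproduces wilcox.test per marker, excluding unknowns", {
  Y <- toy_norm()
  geno <- matrix(rep(c(0L, 1L), each = 12), nrow = 3, ncol = 24, byrow = TRUE,
                 dimnames = list(c("chr1_0001", "chr1_0002", "chr2_0001"),
                                 colnames(Y)))
  geno[2, ] <- rep(c(0L, 1L), 12)
  geno[3, 1:4] <- NA_integer_
  rownames(Y)[1:3] <- rownames(geno)
  mk <- toy_markers(geno)
  res <- scan_eqtl(Y, mk, min_per_class = 3, keep_full = TRUE)
  P <- attr(res, "pmatrix")
  for (m in seq_len(nrow(mk$genotypes))) {
    g <- mk$genotypes[m, ]
    incl <- !is.na(g)
    for (i in seq_len(nrow(Y))) {
      ref <- stats::wilcox.test(Y[i, incl & g == 1L & !is.na(g)],
                                Y[i, incl & g == 0L & !is.na(g)],
                                exact = FALSE, correct = TRUE)$p.value
      expect_equal(P[i, m], ref, tolerance = 1e-12)
    }
  }
})

test_that("per-gene records keep the most significant marker per chromosome", {
  Y <- toy_norm(n_genes = 5)
  set.seed(8)
  geno <- matrix(rbinom(6 * 24, 1, 0.5), nrow = 6, ncol = 24,
                 dimnames = list(paste0("chr", rep(1:2, each = 3), "_",
                                        sprintf("%04d", rep(1:3, 2))),
                                 colnames(Y)))
  mk <- toy_markers(geno)
  res <- scan_eqtl(Y, mk, min_per_class = 3, keep_full = TRUE)
  P <- attr(res, "pmatrix")
  for (r in seq_len(nrow(res))) {
    cols <- mk$regions$region[mk$regions$chrom == res$marker_chrom[r]]
    expect_equal(res$p[r], min(P[res$gene[r], cols], na.rm = TRUE))
  }
  # the cis/trans partition is exhaustive and exclusive
  ann <- data.frame(gene = rownames(Y), chrom = c("chr1", "chr1", "chr2",
                                                  "chr2", "chr2"))
  cls <- classify_cis_trans(res, ann)
  expect_true(all(cls$classification %in% c("cis", "trans")))
  expect_equal(sum(cls$classification == "cis") +
                 sum(cls$classification == "trans"), nrow(cls))
})

test_that("permutation q-values are monotone, reproducible and order-invariant", {
  cfg <- small_config(seed = 47)
  d <- simulate_backcross(cfg)
  n2 <- d$metadata$generation == "N2"
  mk <- build_marker_regions(d$genotypes[, n2], d$annotation)
  norm <- normalize_expression(d$expression, d$metadata, k_hidden_factors = 2,
                               embryos = d$metadata$embryo[n2])
  res <- eqtl_fdr(norm, mk, d$annotation, n_permutations = 5, seed = 11)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  res2 <- eqtl_fdr(norm, mk, d$annotation, n_permutations = 5, seed = 11)
  expect_equal(res$q, res2$q)
  # shuffling gene rows leaves each gene's q unchanged
  shuffle <- sample(nrow(norm))
  res3 <- eqtl_fdr(norm[shuffle, ], mk, d$annotation, n_permutations = 5,
                   seed = 11)
  key <- paste(res$gene, res$marker_chrom)
  key3 <- paste(res3$gene, res3$marker_chrom)
  expect_equal(res3$q[match(key, key3)], res$q)
})

test_that("a planted cis effect maps to its own chromosome at low q", {
  cfg <- small_config(seed = 53, baseline_log_mean = log(150))
  tr <- simulation_truth(cis = c(g02_0015 = 2))
  d <- simulate_backcross(cfg, tr)
  n2 <- d$metadata$generation == "N2"
  mk <- build_marker_regions(d$genotypes[, n2], d$annotation)
  norm <- normalize_expression(d$expression, d$metadata, k_hidden_factors = 2,
                               embryos = d$metadata$embryo[n2])
  res <- eqtl_fdr(norm, mk, d$annotation, n_permutations = 20, seed = 5,
                  q_threshold = 0.05)
  hit <- res[res$gene == "g02_0015" & res$classification == "cis", ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$q, 0.05)
})

test_that("predicted allele fraction follows the two-genotype mean model", {
  # equal class means: no cis effect predicted
  em <- expression_matrix(matrix(c(100, 100, 100, 100), 1, 4,
                                 dimnames = list("g1", paste0("e", 1:4))),
                          rep(1e6, 4))
  geno <- matrix(c(0L, 0L, 1L, 1L), 1, 4, dimnames = dimnames(em$counts))
  v <- allele_votes(b6 = matrix(10, 1, 4, dimnames = dimnames(em$counts)),
                    cast = matrix(10, 1, 4, dimnames = dimnames(em$counts)))
  cc <- ase_eqtl_concordance(em, geno, v, min_per_class = 2)
  expect_equal(cc$records["g1", "baf_exp"], 0.5)
  expect_equal(cc$records["g1", "baf_pred"], 0.5)
  # silent Cast allele: heterozygote mean is half the homozygote mean
  em2 <- expression_matrix(matrix(c(100, 100, 50, 50), 1, 4,
                                  dimnames = dimnames(em$counts)), rep(1e6, 4))
  cc2 <- ase_eqtl_concordance(em2, geno, v, min_per_class = 2)
  expect_equal(cc2$records["g1", "baf_exp"], 2 / 3)
  expect_equal(cc2$records["g1", "baf_pred"], 1)
  # beyond the silent-allele limit the prediction exceeds 1
  em3 <- expression_matrix(matrix(c(100, 100, 40, 40), 1, 4,
                                  dimnames = dimnames(em$counts)), rep(1e6, 4))
  cc3 <- ase_eqtl_concordance(em3, geno, v, min_per_class = 2)
  expect_gt(cc3$records["g1", "baf_pred"], 1)
  # degenerate: heterozygotes silent entirely -> baf_exp = 1, record NA
  em4 <- expression_matrix(matrix(c(100, 100, 0, 0), 1, 4,
                                  dimnames = dimnames(em$counts)), rep(1e6, 4))
  cc4 <- ase_eqtl_concordance(em4, geno, v, min_per_class = 2)
  expect_true(is.na(cc4$records["g1", "baf_pred"]))
})

test_that("predicted and measured allele fractions agree on simulation", {
  cfg <- small_config(seed = 59, baseline_log_mean = log(250),
                      baseline_log_sd = 0.4, n_n2_f1xb6 = 60L,
                      n_n2_b6xf1 = 60L)
  ann <- simulate_gene_annotation(cfg)
  set.seed(77)
  folds <- stats::setNames(exp(rnorm(nrow(ann), 0, 0.5)), ann$gene)
  d <- simulate_backcross(cfg, simulation_truth(cis = folds))
  n2 <- d$metadata$generation == "N2"
  cc <- ase_eqtl_concordance(
    expression_matrix(d$expression$counts[, n2],
                      d$expression$library_size[n2]),
    d$genotypes[, n2], subset_votes(d$votes, n2))
  expect_gt(cc$rho_all, 0.8)
  # the prediction is a monotone recalibration of the class-mean ratio:
  # rank agreement with the truth matches that of the raw ratio
  ok <- cc$records$testable
  true_baf <- 1 / (1 + folds[rownames(cc$records)])
  s_pred <- cor(cc$records$baf_pred[ok], true_baf[ok], method = "spearman")
  s_exp <- cor(cc$records$baf_exp[ok], true_baf[ok], method = "spearman")
  expect_gte(s_pred, s_exp - 1e-12)
})

test_that("hotspot counts conserve the number of sub-threshold pairs", {
  Y <- toy_norm(n_genes = 30, n_embryos = 30, seed = 13)
  geno <- matrix(rbinom(4 * 30, 1, 0.5), 4, 30,
                 dimnames = list(paste0("chr", 1:4, "_0001"), colnames(Y)))
  mk <- toy_markers(geno)
  res <- eqtl_fdr(Y, mk, data.frame(gene = rownames(Y), chrom = "chr9"),
                  n_permutations = 3, seed = 2, keep_full = TRUE)
  P <- attr(res, "pmatrix")
  ht <- test_hotspots(P, attr(res, "perm_pmatrix"), threshold = 0.1)
  expect_equal(sum(ht$counts), sum(P < 0.1, na.rm = TRUE))
  expect_true(ht$p >= 0 && ht$p <= 1)
})

test_that("conservation correlation recovers a planted coupling and its sign", {
  set.seed(4)
  n <- 2000
  effect <- stats::setNames(abs(rnorm(n, 0, 0.2)), paste0("g", 1:n))
  # stronger regulatory effect -> lower conservation score
  scores <- stats::setNames(-0.6 * scale(effect)[, 1] + rnorm(n),
                            names(effect))
  res <- conservation_correlation(effect, scores)
  expect_lt(res$rho, -0.3)
  expect_lt(res$p, 1e-6)
  # independent scores: no correlation
  res0 <- conservation_correlation(effect, stats::setNames(sample(unname(scores)),
                                                           names(scores)))
  expect_lt(abs(res0$rho), 0.08)
  # expression floor and minimum-gene guard
  mean_rpm <- stats::setNames(rep(1, n), names(effect))
  expect_error(conservation_correlation(effect, scores, mean_rpm = mean_rpm),
               "filtering")
})
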