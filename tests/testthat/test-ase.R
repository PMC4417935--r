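balanced_votes <- function(n_genes = 4, n_embryos = 12, b6 = 30, cast = 30) {
  genes <- paste0("g", seq_len(n_genes))
  embryos <- paste0("e", seq_len(n_embryos))
  m <- function(v) matrix(v, n_genes, n_embryos, dimnames = list(genes, embryos))
  allele_votes(b6 = m(b6), cast = m(cast))
}

test_that("perfectly balanced votes are never called as ASE", {
  v <- balanced_votes()
  geno <- matrix(1L, 4, 12, dimnames = dimnames(v$b6))
  res <- test_ase(v, geno, rep(1e6, 12))
  expect_true(all(res$significant %in% FALSE))
  expect_equal(res$mean_baf, rep(0.5, 4), ignore_attr = TRUE)
})

test_that("the balanced-BAF window vetoes statistically strong but tiny shifts", {
  set.seed(2)
  n <- 60
  genes <- "g1"
  b6 <- matrix(rbinom(n, 400, 0.52), 1, n, dimnames = list(genes, NULL))
  cast <- 400 - b6
  v <- allele_votes(b6 = b6, cast = cast)
  geno <- matrix(1L, 1, n, dimnames = dimnames(b6))
  res <- test_ase(v, geno, rep(1e6, n))
  expect_lt(res$p_bonferroni, 0.01)      # strongly non-zero difference
  expect_gt(res$mean_baf, 0.45)          # but inside the balanced window
  expect_false(res$significant)
})

test_that("embryo and vote floors control which genes are tested", {
  v <- balanced_votes(n_genes = 2, n_embryos = 4)
  geno <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L), 2, 4, byrow = TRUE,
                 dimnames = dimnames(v$b6))
  res <- test_ase(v, geno, rep(1e6, 4), min_embryos = 3)
  expect_true(is.na(res["g2", "p"])) # only 2 heterozygous embryos
  # untested genes do not enter the Bonferroni denominator
  v2 <- balanced_votes(n_genes = 2, n_embryos = 12)
  v2$b6[1, ] <- rpois(12, 40) + 10
  geno2 <- matrix(1L, 2, 12, dimnames = dimnames(v2$b6))
  geno2[2, ] <- NA_integer_
  res2 <- test_ase(v2, geno2, rep(1e6, 12))
  expect_equal(res2["g1", "p_bonferroni"], min(res2["g1", "p"] * 1, 1))
})

test_that("a strong planted cis effect is detected against nulls", {
  cfg <- small_config(seed = 19, baseline_log_mean = log(120),
                      baseline_log_sd = 0.4)
  tr <- simulation_truth(cis = c(g01_0010 = 2))
  d <- simulate_backcross(cfg, tr)
  res <- test_ase(d$votes, d$genotypes, d$expression$library_size)
  expect_true(res["g01_0010", "significant"])
  expect_lt(res["g01_0010", "mean_baf"], 0.45) # true BAF 1/3
  expect_equal(sum(res$significant[res$gene != "g01_0010"]), 0)
})

test_that("paired t-test type-I error is at or below nominal on null data", {
  set.seed(71)
  reps <- 40
  hits <- 0
  tests <- 0
  for (r in seq_len(reps)) {
    n <- 30
    tot <- matrix(rpois(50 * n, 60), 50, n,
                  dimnames = list(paste0("g", 1:50), NULL))
    b6 <- matrix(rbinom(length(tot), tot, 0.5), 50, n,
                 dimnames = dimnames(tot))
    v <- allele_votes(b6 = b6, cast = tot - b6)
    geno <- matrix(1L, 50, n, dimnames = dimnames(tot))
    res <- test_ase(v, geno, rep(1e6, n))
    hits <- hits + sum(res$p < 0.05, na.rm = TRUE)
    tests <- tests + sum(!is.na(res$p))
  }
  rate <- hits / tests
  # conservative or nominal, never anticonservative (3 SE slack)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / tests))
})

test_that("imprinting requires opposite allelic bias across the reciprocal cross", {
  genes <- c("imp", "flat", "cis")
  embryos <- paste0("e", 1:40)
  meta <- data.frame(embryo = embryos,
                     cross = rep(c("B6xF1", "F1xB6"), each = 20),
                     mother = rep(c("B6", "F1"), each = 20),
                     generation = "N2", stringsAsFactors = FALSE)
  b6mom <- meta$mother == "B6"
  b6 <- matrix(0, 3, 40, dimnames = list(genes, embryos))
  cast <- b6
  # fully maternally expressed: B6-mother embryos express only B6
  b6["imp", b6mom] <- 50; cast["imp", !b6mom] <- 50
  # balanced gene
  b6["flat", ] <- 25; cast["flat", ] <- 25
  # pure cis gene: BAF 0.3 in both directions
  b6["cis", ] <- 15; cast["cis", ] <- 35
  v <- allele_votes(b6 = b6, cast = cast)
  geno <- matrix(1L, 3, 40, dimnames = dimnames(b6))
  res <- test_imprinting(v, geno, meta)
  expect_true(res["imp", "significant"])
  expect_equal(res["imp", "cross_difference"], 1)
  expect_false(res["flat", "significant"])
  expect_false(res["cis", "significant"])
  expect_gt(res["cis", "p"], 0.5) # cis bias is not parent-of-origin signal
})

test_that("imprinting and ASE calls separate cis from parent-of-origin truth", {
  cfg <- small_config(seed = 27, baseline_log_mean = log(200))
  tr <- simulation_truth(
    cis = c(g01_0012 = 3),
    imprinted = data.frame(gene = "g02_0012", silenced_origin = "maternal",
                           residual = 0, stringsAsFactors = FALSE))
  d <- simulate_backcross(cfg, tr)
  imp <- test_imprinting(d$votes, d$genotypes, d$metadata)
  expect_true(imp["g02_0012", "significant"])
  expect_false(imp["g01_0012", "significant"]) # pure cis never imprinted
})

test_that("F1-only and N2-only allele fraction estimates agree", {
  cfg <- small_config(seed = 37, baseline_log_mean = log(400),
                      baseline_log_sd = 0.5)
  set.seed(101)
  folds <- stats::setNames(exp(rnorm(30, 0, 0.6)),
                           sample(simulate_gene_annotation(cfg)$gene, 30))
  d <- simulate_backcross(cfg, simulation_truth(cis = folds))
  f1 <- d$metadata$generation == "F1"
  het <- d$genotypes == 1L
  baf_f1 <- baf(d$votes, pool = TRUE, use = sweep(het, 2, f1, `&`))
  baf_n2 <- baf(d$votes, pool = TRUE, use = sweep(het, 2, !f1, `&`))
  ok <- !is.na(baf_f1) & !is.na(baf_n2)
  expect_gt(cor(baf_f1[ok], baf_n2[ok], method = "spearman"), 0.6)
})

test_that("developmental ASE finds monotone allele trends and honors floors", {
  somites <- rep(42:57, length.out = 32)
  genes <- c("trend", "flat")
  b6 <- matrix(25, 2, 32, dimnames = list(genes, paste0("e", 1:32)))
  cast <- b6
  # allele fraction strictly increasing with somite stage
  b6["trend", ] <- 100 * plogis((somites - 49.5) * 0.4)
  cast["trend", ] <- 100 - b6["trend", ]
  v <- allele_votes(b6 = b6, cast = cast)
  geno <- matrix(1L, 2, 32, dimnames = dimnames(b6))
  meta <- data.frame(somites = somites)
  res <- test_developmental_ase(v, geno, meta)
  expect_equal(res["trend", "rho"], 1)
  expect_true(res["trend", "significant"])
  expect_false(res["flat", "significant"])
  # too few distinct somite stages: untested
  meta2 <- data.frame(somites = rep(c(42, 43), 16))
  res2 <- test_developmental_ase(v, geno, meta2)
  expect_true(all(is.na(res2$p)))
})

test_that("developmental expression trends are recovered at q < 0.05", {
  cfg <- small_config(seed = 41)
  tr <- simulation_truth(somite_total = c(g01_0020 = 0.05))
  d <- simulate_backcross(cfg, tr)
  res <- test_developmental_expression(d$expression, d$metadata)
  expect_true(res["g01_0020", "significant"])
  expect_equal(sum(res$significant[res$gene != "g01_0020"]), 0)
})
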