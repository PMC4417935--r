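votes_from <- function(b6, cast) {
  allele_votes(b6 = b6, cast = cast)
}

test_that("preliminary calls apply the vote floor and the hom/het boundary", {
  b6 <- matrix(c(10, 52, 98, 19), nrow = 4,
               dimnames = list(paste0("g", 1:4), "e1"))
  cast <- matrix(c(9, 48, 2, 0), nrow = 4,
                 dimnames = list(paste0("g", 1:4), "e1"))
  pg <- preliminary_genotype(votes_from(b6, cast))
  expect_true(is.na(pg$call["g1", "e1"]))   # 19 informative votes
  expect_equal(pg$call["g2", "e1"], 1L)     # 52% B6: heterozygous
  expect_equal(pg$call["g3", "e1"], 0L)     # 98% B6: homozygous
  expect_true(is.na(pg$call["g4", "e1"]))   # 19 votes, all B6: still unknown
})

test_that("the 0.9 boundary separates the two genotype classes at 100 votes", {
  # direct binomial tails: a heterozygote (p = 0.5) essentially never
  # reaches 90 B6 votes of 100, and a homozygote (p = 0.998) essentially
  # never falls below
  p_het_cross <- pbinom(89, 100, 0.5, lower.tail = FALSE)
  p_hom_cross <- pbinom(89, 100, 0.998)
  expect_lt(p_het_cross, 1e-6)
  expect_lt(p_hom_cross, 1e-6)
})

test_that("Viterbi smoothing removes isolated miscalls and places breakpoints", {
  # isolated hom call inside a het block is smoothed away
  obs <- c(rep(1L, 10), 0L, rep(1L, 10))
  path <- aseqtl:::viterbi_genotypes(obs)
  expect_equal(path, rep(1L, 21))
  # two clean blocks produce exactly one state change at the junction
  obs2 <- c(rep(1L, 15), rep(0L, 15))
  path2 <- aseqtl:::viterbi_genotypes(obs2)
  expect_equal(path2, obs2)
  # unknown genes inherit the surrounding state
  obs3 <- c(1L, 1L, NA, NA, 1L)
  expect_equal(aseqtl:::viterbi_genotypes(obs3), rep(1L, 5))
  expect_true(all(is.na(aseqtl:::viterbi_genotypes(c(NA, NA, NA)))))
})

test_that("Viterbi equals exhaustive path enumeration on random instances", {
  set.seed(17)
  for (i in 1:150) {
    n <- sample(2:12, 1)
    obs <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    eps <- runif(1, 0.005, 0.2)
    tr <- 10^runif(1, -5, -1)
    path <- aseqtl:::viterbi_genotypes(obs, eps, tr)
    if (all(is.na(path))) {
      expect_true(all(is.na(obs)))
      next
    }
    expect_equal(path_loglik(path, obs, eps, tr),
                 oracle_best_path_loglik(obs, eps, tr), tolerance = 1e-9)
  }
})

test_that("the path scorer matches hand arithmetic", {
  ll <- path_loglik(c(1L, 1L, 0L), c(1L, NA, 0L), 0.02, 1e-3)
  expect_equal(ll, log(0.5) + log(0.98) + log(0.5) + log(0.98) +
                 log(1 - 1e-3) + log(1e-3))
})

test_that("low-coverage genes near breakpoints are masked, others keep calls", {
  ann <- data.frame(gene = paste0("g", 1:7), chrom = "chr1",
                    stringsAsFactors = FALSE)
  geno <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L), ncol = 1,
                 dimnames = list(ann$gene, "e1"))
  informative <- matrix(c(50, 50, 5, 8, 50, 4, 50), ncol = 1,
                        dimnames = list(ann$gene, "e1"))
  prelim <- list(informative = informative)
  bp <- data.frame(embryo = "e1", chrom = "chr1", gap = 3L)
  masked <- mask_near_breakpoints(geno, prelim, bp, ann)
  # between the flanking confident genes g2 and g5, low-coverage g3/g4 die
  expect_true(all(is.na(masked[c("g3", "g4"), "e1"])))
  # low coverage deep inside the hom block is untouched
  expect_equal(unname(masked["g6", "e1"]), 0L)
  expect_equal(unname(masked["g2", "e1"]), 1L)
  # a high-coverage gene at the breakpoint keeps its own call
  informative2 <- matrix(rep(50, 7), ncol = 1,
                         dimnames = list(ann$gene, "e1"))
  masked2 <- mask_near_breakpoints(geno, list(informative = informative2),
                                   bp, ann)
  expect_equal(masked2, geno)
})

test_that("marker regions merge identical genotype vectors and honor the budget", {
  ann <- data.frame(gene = paste0("g", 1:6), chrom = "chr1",
                    stringsAsFactors = FALSE)
  v1 <- c(1L, 1L, 0L)
  v2 <- c(1L, 1L, 1L)
  geno <- rbind(g1 = v1, g2 = v1, g3 = v1, g4 = v2, g5 = v2, g6 = v2)
  colnames(geno) <- paste0("e", 1:3)
  mr <- build_marker_regions(geno, ann, max_recombs = 0)
  expect_equal(nrow(mr$regions), 2)
  expect_equal(unname(mr$genotypes[1, ]), v1)
  expect_equal(unname(mr$genotypes[2, ]), v2)
  expect_equal(unname(mr$gene_region[c("g3", "g4")]),
               c("chr1_r001", "chr1_r002"))
  # a budget of one recombination merges the two blocks (one embryo differs
  # in the minority of the region's genes after merging under the consensus)
  mr1 <- build_marker_regions(geno, ann, max_recombs = 3)
  expect_equal(nrow(mr1$regions), 1)
})

test_that("region count never increases with a larger recombination budget", {
  set.seed(23)
  cfg <- small_config(seed = 23)
  sim <- simulate_n2_genotypes(cfg, 30)
  ann <- simulate_gene_annotation(cfg)
  counts <- vapply(c(0, 1, 2, 5, 10), function(b)
    nrow(build_marker_regions(sim$genotypes, ann, max_recombs = b)$regions),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("exact-mode region boundaries equal the union of true breakpoints", {
  cfg <- small_config(seed = 3)
  set.seed(cfg$seed)
  ann <- simulate_gene_annotation(cfg)
  sim <- simulate_n2_genotypes(cfg, 46, ann)
  mr <- build_marker_regions(sim$genotypes, ann, max_recombs = 0)
  expected <- nrow(unique(sim$breakpoints[, c("chrom", "gap")])) +
    length(unique(ann$chrom))
  expect_equal(nrow(mr$regions), expected)
})

test_that("consensus is the majority call, unknown only on genuine ties", {
  ann <- data.frame(gene = paste0("g", 1:2), chrom = "chr1",
                    stringsAsFactors = FALSE)
  # e1: calls disagree 1-1 -> unknown; e2 unanimous het; e3 single call kept
  geno <- rbind(g1 = c(1L, 1L, 1L), g2 = c(0L, 1L, NA))
  colnames(geno) <- paste0("e", 1:3)
  mr <- build_marker_regions(geno, ann, max_recombs = 2)
  expect_equal(nrow(mr$regions), 1)
  expect_true(is.na(mr$genotypes[1, "e1"]))
  expect_equal(unname(mr$genotypes[1, c("e2", "e3")]), c(1L, 1L))
})

test_that("the full genotyping stage recovers simulated genotypes", {
  cfg <- small_config(seed = 9, baseline_log_mean = log(200),
                      baseline_log_sd = 0.5)
  d <- simulate_backcross(cfg)
  gt <- genotype_embryos(d$votes, d$annotation)
  n2 <- d$metadata$generation == "N2"
  inferred <- gt$genotypes[, n2]
  truth <- d$genotypes[, n2]
  ok <- !is.na(inferred)
  expect_gt(mean(inferred[ok] == truth[ok]), 0.99)
  # F1 embryos must come out heterozygous everywhere they are called
  f1 <- gt$genotypes[, !n2]
  expect_true(all(f1[!is.na(f1)] == 1L))
})
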