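#' Simulation configuration for a synthetic backcross experiment
#'
#' Builds and validates the parameter set that defines a synthetic two-strain
#' (B6 x Cast) embryo experiment: 16 F1 hybrids from reciprocal crosses plus
#' 154 N2 embryos from the reciprocal backcross of (B6 x Cast)F1 to B6, with
#' recombination along 19 autosomes, overdispersed gene-level counts,
#' library-size and batch variation, and binomially sampled allele-specific
#' read votes. The defaults reproduce the design of the emulated study; the
#' genetic map length is a calibration chosen so that the realized number of
#' recombination-delimited marker regions is on the scale observed in real
#' backcross data (on the order of a thousand across 154 embryos).
#'
#' @param n_f1_per_direction F1 embryos per reciprocal cross direction.
#' @param n_n2_f1xb6 N2 embryos with an F1 mother (F1 x B6 cross).
#' @param n_n2_b6xf1 N2 embryos with a B6 mother (B6 x F1 cross).
#' @param n_autosomes number of autosomes simulated.
#' @param genes_per_chromosome genes placed on each autosome.
#' @param map_length_morgans genetic map length per autosome, in Morgans;
#'   the expected number of crossovers per transmitted F1 gamete.
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   per-gene baseline expression level (RPM scale, for a B6/B6 embryo).
#' @param dispersion negative-binomial overdispersion of counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param snp_read_fraction probability that a read from a gene covers at
#'   least one strain-distinguishing SNP (3'-biased protocols make this high).
#' @param library_log_mean,library_log_sd natural-log mean and sd of
#'   per-embryo library sizes (total mapped reads).
#' @param somite_range integer range of somite counts (developmental stage).
#' @param hom_vote_error per-vote probability that a homozygous B6/B6 embryo
#'   contributes a spurious Cast vote (sequencing/alignment error).
#' @param other_vote_rate per-vote probability of a call matching neither
#'   strain allele.
#' @param batch_sd log-normal sd of multiplicative per-(batch, gene)
#'   sequencing batch effects.
#' @param litter_size,batch_size embryos per litter and per sequencing batch.
#' @param seed integer seed fixing the whole dataset.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_f1_per_direction = 8L,
                              n_n2_f1xb6 = 65L,
                              n_n2_b6xf1 = 89L,
                              n_autosomes = 19L,
                              genes_per_chromosome = 105L,
                              map_length_morgans = 0.35,
                              baseline_log_mean = log(50),
                              baseline_log_sd = 1,
                              dispersion = 0.05,
                              snp_read_fraction = 0.3,
                              library_log_mean = log(1e6),
                              library_log_sd = 0.25,
                              somite_range = c(42L, 57L),
                              hom_vote_error = 0.002,
                              other_vote_rate = 0.01,
                              batch_sd = 0.1,
                              litter_size = 8L,
                              batch_size = 12L,
                              seed = 1L) {
  cfg <- list(
    n_f1_per_direction = as.integer(n_f1_per_direction),
    n_n2_f1xb6 = as.integer(n_n2_f1xb6),
    n_n2_b6xf1 = as.integer(n_n2_b6xf1),
    n_autosomes = as.integer(n_autosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    map_length_morgans = map_length_morgans,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    snp_read_fraction = snp_read_fraction,
    library_log_mean = library_log_mean,
    library_log_sd = library_log_sd,
    somite_range = as.integer(somite_range),
    hom_vote_error = hom_vote_error,
    other_vote_rate = other_vote_rate,
    batch_sd = batch_sd,
    litter_size = as.integer(litter_size),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$n_f1_per_direction >= 1, cfg$n_n2_f1xb6 >= 1, cfg$n_n2_b6xf1 >= 1,
    cfg$n_autosomes >= 1, cfg$genes_per_chromosome >= 1,
    cfg$map_length_morgans >= 0,
    cfg$dispersion >= 0,
    cfg$snp_read_fraction >= 0, cfg$snp_read_fraction <= 1,
    cfg$hom_vote_error >= 0, cfg$hom_vote_error <= 1,
    cfg$other_vote_rate >= 0, cfg$other_vote_rate <= 1,
    cfg$batch_sd >= 0,
    length(cfg$somite_range) == 2,
    cfg$somite_range[1] <= cfg$somite_range[2],
    cfg$litter_size >= 1, cfg$batch_size >= 1
  )
  invisible(cfg)
}

#' Ground-truth effect ledger for a simulation
#'
#' Records the effects planted in a synthetic dataset so that downstream
#' analyses can be scored by parameter recovery.
#'
#' @param cis named numeric vector: allelic fold change of the Cast allele
#'   relative to the B6 allele, per gene (1 = no cis effect; 0 = Cast silent).
#' @param maternal named numeric vector: fold change of total expression in
#'   embryos with a B6/B6 mother relative to embryos with an F1 mother.
#' @param imprinted data frame with columns `gene`, `silenced_origin`
#'   ("maternal" or "paternal") and `residual` (expression fraction retained
#'   by the silenced allele, in \[0, 1\]).
#' @param somite_total named numeric vector of log-slopes of total expression
#'   per somite.
#' @param somite_allele named numeric vector of logit-BAF slopes per somite
#'   (allele-differential developmental trends).
#' @param hotspot optional list `list(gene =, targets =)`: a trans-acting
#'   locus; `targets` is a named numeric vector of fold changes applied to
#'   target genes in embryos heterozygous at `gene`.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(cis = numeric(0),
                             maternal = numeric(0),
                             imprinted = NULL,
                             somite_total = numeric(0),
                             somite_allele = numeric(0),
                             hotspot = NULL) {
  if (is.null(imprinted)) {
    imprinted <- data.frame(gene = character(0), silenced_origin = character(0),
                            residual = numeric(0))
  }
  stopifnot(
    all(cis >= 0), all(maternal > 0),
    all(imprinted$silenced_origin %in% c("maternal", "paternal")),
    all(imprinted$residual >= 0 & imprinted$residual <= 1)
  )
  if (!is.null(hotspot)) {
    stopifnot(is.list(hotspot), !is.null(hotspot$gene),
              all(hotspot$targets > 0), !is.null(names(hotspot$targets)))
  }
  structure(list(cis = cis, maternal = maternal, imprinted = imprinted,
                 somite_total = somite_total, somite_allele = somite_allele,
                 hotspot = hotspot),
            class = "simulation_truth")
}

#' Gene annotation for a synthetic genome
#'
#' Genes are laid out uniformly along each autosome, with genomic coordinates
#' (for BED export) and genetic positions in Morgans (for recombination).
#'
#' @param config a [simulation_config()].
#' @return data frame with columns gene, chrom, start, end, strand,
#'   genetic_pos.
#' @export
simulate_gene_annotation <- function(config) {
  G <- config$genes_per_chromosome
  chroms <- paste0("chr", seq_len(config$n_autosomes))
  ann <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    idx <- seq_len(G)
    data.frame(
      gene = sprintf("g%02d_%04d", ci, idx),
      chrom = chroms[ci],
      start = (idx - 1L) * 20000L + 1000L,
      end = (idx - 1L) * 20000L + 6000L,
      strand = rep_len(c("+", "-"), G),
      genetic_pos = (idx - 0.5) / G * config$map_length_morgans,
      stringsAsFactors = FALSE
    )
  }))
  rownames(ann) <- ann$gene
  ann
}

#' Per-embryo metadata for a synthetic cross
#'
#' Assigns cross direction, maternal genotype class, litter, sequencing
#' batch, somite count, sex, and an Xist-like expression level consistent
#' with sex (used to exercise expression-based sex calling). F1 embryos come
#' from reciprocal B6 x Cast crosses; N2 embryos from reciprocal backcrosses
#' of (B6 x Cast)F1 with B6, so every N2 mother is either F1 (B6/Cast) or
#' B6/B6 and all N2 embryos carry B6 mitochondria.
#'
#' @param config a [simulation_config()].
#' @return data frame, one row per embryo, ordered F1 then N2.
#' @export
simulate_metadata <- function(config) {
  crosses <- c(rep("B6xCast", config$n_f1_per_direction),
               rep("CastxB6", config$n_f1_per_direction),
               rep("F1xB6", config$n_n2_f1xb6),
               rep("B6xF1", config$n_n2_b6xf1))
  generation <- ifelse(crosses %in% c("B6xCast", "CastxB6"), "F1", "N2")
  mother <- c(B6xCast = "B6", CastxB6 = "Cast", F1xB6 = "F1", B6xF1 = "B6")[crosses]
  n <- length(crosses)
  embryo <- sprintf("e%03d", seq_len(n))
  # litters nest within cross direction; batches are sequential pools
  litter <- unlist(lapply(unique(crosses), function(cr) {
    k <- sum(crosses == cr)
    paste0(cr, "_L", sprintf("%02d", ceiling(seq_len(k) / config$litter_size)))
  }))
  # sequencing pools multiplex embryos irrespective of cross direction:
  # assign embryos to batches at random within each generation
  batch <- character(n)
  for (gen in unique(generation)) {
    sel <- sample(which(generation == gen))
    batch[sel] <- paste0(substr(gen, 1, 2), "_batch",
                         sprintf("%02d", ceiling(seq_along(sel) / config$batch_size)))
  }
  somites <- sample(seq(config$somite_range[1], config$somite_range[2]), n,
                    replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  xist_rpm <- ifelse(sex == "F",
                     stats::rlnorm(n, log(300), 0.3),
                     stats::rlnorm(n, log(0.5), 0.5))
  data.frame(embryo = embryo, generation = generation, cross = crosses,
             mother = unname(mother), litter = litter, batch = batch,
             somites = somites, sex = sex, xist_rpm = xist_rpm,
             stringsAsFactors = FALSE)
}

#' Simulate N2 genotypes along recombinant chromosomes
#'
#' Each N2 embryo inherits one complete B6 genome from its B6 parent and one
#' recombinant F1 gamete. The gamete is a mosaic of B6 and Cast segments:
#' crossover count per chromosome is Poisson with mean equal to the map
#' length in Morgans, crossover positions are uniform, and there is no
#' interference. A gene is B6/Cast (heterozygous) where the gamete segment is
#' Cast and B6/B6 otherwise, so every gene is heterozygous with probability
#' 1/2 and Cast/Cast never occurs.
#'
#' @param config a [simulation_config()].
#' @param n_embryos number of N2 embryos to draw.
#' @param annotation gene annotation from [simulate_gene_annotation()];
#'   built from `config` when omitted.
#' @return list with `genotypes` (genes x embryos integer matrix, 0 = B6/B6,
#'   1 = B6/Cast) and `breakpoints` (data frame of recombination positions:
#'   embryo, chrom, gap = index of the gene immediately left of the
#'   breakpoint, counting only gaps where the genotype actually switches).
#' @export
simulate_n2_genotypes <- function(config, n_embryos,
                                  annotation = simulate_gene_annotation(config)) {
  validate_simulation_config(config)
  stopifnot(n_embryos >= 1)
  chroms <- unique(annotation$chrom)
  geno <- matrix(0L, nrow = nrow(annotation), ncol = n_embryos,
                 dimnames = list(annotation$gene, NULL))
  bp <- list()
  for (ch in chroms) {
    rows <- which(annotation$chrom == ch)
    gpos <- annotation$genetic_pos[rows]
    L <- config$map_length_morgans
    for (e in seq_len(n_embryos)) {
      nx <- stats::rpois(1, L)
      xpos <- sort(stats::runif(nx, 0, L))
      start_cast <- stats::rbinom(1, 1, 0.5)
      # allele at genetic position p flips at every crossover before p
      ncross <- findInterval(gpos, xpos)
      cast <- (start_cast + ncross) %% 2L
      geno[rows, e] <- as.integer(cast)
      sw <- which(diff(cast) != 0L)
      if (length(sw)) {
        bp[[length(bp) + 1L]] <- data.frame(embryo = e, chrom = ch, gap = sw)
      }
    }
  }
  breakpoints <- if (length(bp)) do.call(rbind, bp) else
    data.frame(embryo = integer(0), chrom = character(0), gap = integer(0))
  list(genotypes = geno, breakpoints = breakpoints)
}

# Relative expression weight of each allele for every (gene, embryo):
# B6/B6 baseline is weight 1 split 0.5/0.5 across the two (B6) alleles.
# Heterozygotes carry one B6 allele (0.5) and one Cast allele (0.5 x cis
# fold). Imprinting multiplies the silenced allele's weight by its residual
# fraction, with the silenced copy identified through the parental origin
# implied by the cross direction: the Cast allele is maternal in F1xB6 and
# CastxB6 crosses, paternal in B6xF1 and B6xCast crosses.
allele_weights <- function(truth, genotypes, metadata, annotation) {
  genes <- rownames(genotypes)
  n <- ncol(genotypes)
  b6w <- matrix(0.5, nrow = length(genes), ncol = n,
                dimnames = dimnames(genotypes))
  castw <- matrix(0.5, nrow = length(genes), ncol = n,
                  dimnames = dimnames(genotypes))
  het <- genotypes == 1L
  cis <- truth$cis[genes[genes %in% names(truth$cis)]]
  for (g in names(cis)) {
    castw[g, het[g, ]] <- 0.5 * cis[[g]]
  }
  cast_is_maternal <- metadata$cross %in% c("F1xB6", "CastxB6")
  if (nrow(truth$imprinted)) {
    for (i in seq_len(nrow(truth$imprinted))) {
      g <- truth$imprinted$gene[i]
      r <- truth$imprinted$residual[i]
      silence_maternal <- truth$imprinted$silenced_origin[i] == "maternal"
      sil_cast <- if (silence_maternal) cast_is_maternal else !cast_is_maternal
      ishet <- het[g, ]
      # heterozygous: silence whichever strain allele has the silenced origin
      castw[g, ishet & sil_cast] <- castw[g, ishet & sil_cast] * r
      b6w[g, ishet & !sil_cast] <- b6w[g, ishet & !sil_cast] * r
      # homozygous B6/B6: one of the two B6 copies is silenced either way
      b6w[g, !ishet] <- 0.5 + 0.5 * r
      castw[g, !ishet] <- 0
    }
  }
  list(b6 = b6w, cast = castw)
}

#' Simulate total expression counts
#'
#' Draws per-(gene, embryo) read counts from a negative binomial whose mean
#' is library_size x baseline RPM / 1e6, modulated by the planted cis,
#' imprinting, maternal, developmental-trend, trans-hotspot and batch
#' effects. With `dispersion = 0` counts are Poisson.
#'
#' @param truth a [simulation_truth()].
#' @param genotypes genes x embryos integer matrix (0 hom, 1 het) covering
#'   all embryos in `metadata` (F1 embryos are heterozygous everywhere).
#' @param metadata data frame from [simulate_metadata()].
#' @param config a [simulation_config()].
#' @param annotation gene annotation.
#' @return an [expression_matrix()] with the simulated library sizes; the
#'   per-gene baseline RPM is attached as attribute `baseline_rpm` and the
#'   allele weight matrices as attribute `weights`.
#' @export
simulate_expression <- function(truth, genotypes, metadata, config,
                                annotation = NULL) {
  stopifnot(ncol(genotypes) == nrow(metadata))
  genes <- rownames(genotypes)
  unknown <- setdiff(unlist(lapply(
    list(names(truth$cis), names(truth$maternal), truth$imprinted$gene,
         names(truth$somite_total), names(truth$somite_allele),
         truth$hotspot$gene, names(truth$hotspot$targets)), as.character)),
    genes)
  if (length(unknown)) {
    stop("truth ledger names genes absent from the genotype matrix: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(metadata)
  baseline <- stats::rlnorm(length(genes), config$baseline_log_mean,
                            config$baseline_log_sd)
  names(baseline) <- genes
  w <- allele_weights(truth, genotypes, metadata, annotation)
  mult <- w$b6 + w$cast
  if (length(truth$maternal)) {
    b6mom <- metadata$mother == "B6"
    for (g in names(truth$maternal)) {
      mult[g, b6mom] <- mult[g, b6mom] * truth$maternal[[g]]
    }
  }
  mid <- mean(config$somite_range)
  if (length(truth$somite_total)) {
    for (g in names(truth$somite_total)) {
      mult[g, ] <- mult[g, ] * exp(truth$somite_total[[g]] * (metadata$somites - mid))
    }
  }
  if (!is.null(truth$hotspot)) {
    carrier <- genotypes[truth$hotspot$gene, ] == 1L
    for (g in names(truth$hotspot$targets)) {
      mult[g, carrier] <- mult[g, carrier] * truth$hotspot$targets[[g]]
    }
  }
  if (config$batch_sd > 0) {
    batches <- unique(metadata$batch)
    bmat <- matrix(stats::rlnorm(length(genes) * length(batches),
                                 -config$batch_sd^2 / 2, config$batch_sd),
                   nrow = length(genes), dimnames = list(genes, batches))
    mult <- mult * bmat[, metadata$batch]
  }
  library_size <- round(stats::rlnorm(n, config$library_log_mean,
                                      config$library_log_sd))
  mu <- sweep(baseline * mult, 2, library_size / 1e6, `*`)
  counts <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow = length(genes), dimnames = list(genes, metadata$embryo))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu),
           nrow = length(genes), dimnames = list(genes, metadata$embryo))
  }
  expr <- expression_matrix(counts, stats::setNames(library_size, metadata$embryo))
  attr(expr, "baseline_rpm") <- baseline
  attr(expr, "weights") <- w
  expr
}

#' Simulate allele-specific read votes
#'
#' For each (gene, embryo), the number of SNP-covering reads is binomial in
#' the total count with probability `snp_read_fraction`; a small fraction of
#' votes match neither strain allele; the rest are B6 with the gene's B6
#' allele fraction. Heterozygous entries use the BAF implied by the planted
#' cis/imprinting/developmental effects; homozygous B6/B6 entries use
#' 1 - `hom_vote_error`, so the genotyper faces realistically mislabeled
#' votes.
#'
#' @inheritParams simulate_expression
#' @param expression the [expression_matrix()] from [simulate_expression()]
#'   (its `weights` attribute supplies the allele weights).
#' @return an [allele_votes()] table.
#' @export
simulate_allele_votes <- function(truth, genotypes, expression, metadata,
                                  config, annotation = NULL) {
  counts <- expression$counts
  stopifnot(identical(dim(counts), dim(genotypes)))
  w <- attr(expression, "weights")
  if (is.null(w)) w <- allele_weights(truth, genotypes, metadata, annotation)
  baf <- w$b6 / (w$b6 + w$cast)
  het <- genotypes == 1L
  baf[!het] <- 1 - config$hom_vote_error
  mid <- mean(config$somite_range)
  if (length(truth$somite_allele)) {
    for (g in names(truth$somite_allele)) {
      shift <- truth$somite_allele[[g]] * (metadata$somites - mid)
      baf[g, het[g, ]] <- stats::plogis(stats::qlogis(baf[g, het[g, ]]) +
                                          shift[het[g, ]])
    }
  }
  snp_reads <- matrix(stats::rbinom(length(counts), counts,
                                    config$snp_read_fraction),
                      nrow = nrow(counts), dimnames = dimnames(counts))
  other <- matrix(stats::rbinom(length(snp_reads), snp_reads,
                                config$other_vote_rate),
                  nrow = nrow(counts), dimnames = dimnames(counts))
  informative <- snp_reads - other
  b6 <- matrix(stats::rbinom(length(informative), informative, baf),
               nrow = nrow(counts), dimnames = dimnames(counts))
  allele_votes(b6 = b6, cast = informative - b6, other = other,
               snp_reads = snp_reads)
}

# Small SNP table over the synthetic genome, for read-level fixtures and
# format export: 1-4 SNPs per gene in the 3' end of the gene span.
simulate_snp_table <- function(config, annotation) {
  bases <- c("A", "C", "G", "T")
  per_gene <- stats::rbinom(nrow(annotation), 3, 0.6) + 1L
  idx <- rep(seq_len(nrow(annotation)), per_gene)
  off <- unlist(lapply(per_gene, function(k) sort(sample(3000:4999, k))))
  b6a <- sample(bases, length(idx), replace = TRUE)
  shift <- sample(1:3, length(idx), replace = TRUE)
  casta <- bases[(match(b6a, bases) + shift - 1L) %% 4L + 1L]
  data.frame(
    snp_id = sprintf("snp%05d", seq_along(idx)),
    chrom = annotation$chrom[idx],
    pos = annotation$start[idx] + off,
    b6_allele = b6a,
    cast_allele = casta,
    quality = sample(c("high", "low"), length(idx), TRUE, prob = c(0.9, 0.1)),
    indel_dist = sample(c(10L, 200L), length(idx), TRUE, prob = c(0.05, 0.95)),
    gene = annotation$gene[idx],
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic backcross dataset
#'
#' Runs the whole generator under a single seed: annotation, SNP table,
#' metadata, true genotypes (recombinant for N2, heterozygous everywhere for
#' F1), expression counts, and allele votes, together with the ground-truth
#' ledger. Identical `config` (including its seed) and `truth` give a
#' bit-identical dataset.
#'
#' @param config a [simulation_config()].
#' @param truth a [simulation_truth()]; defaults to an all-null ledger.
#' @return list of class `synthetic_backcross` with elements annotation,
#'   snp_table, metadata, genotypes, true_breakpoints, expression, votes,
#'   truth, config.
#' @export
simulate_backcross <- function(config = simulation_config(),
                               truth = simulation_truth()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  annotation <- simulate_gene_annotation(config)
  snp_table <- simulate_snp_table(config, annotation)
  metadata <- simulate_metadata(config)
  n_f1 <- 2L * config$n_f1_per_direction
  n_n2 <- config$n_n2_f1xb6 + config$n_n2_b6xf1
  sim <- simulate_n2_genotypes(config, n_n2, annotation)
  f1_geno <- matrix(1L, nrow = nrow(annotation), ncol = n_f1,
                    dimnames = list(annotation$gene, NULL))
  genotypes <- cbind(f1_geno, sim$genotypes)
  colnames(genotypes) <- metadata$embryo
  sim$breakpoints$embryo <- metadata$embryo[sim$breakpoints$embryo + n_f1]
  expression <- simulate_expression(truth, genotypes, metadata, config,
                                    annotation)
  votes <- simulate_allele_votes(truth, genotypes, expression, metadata,
                                 config, annotation)
  structure(list(annotation = annotation, snp_table = snp_table,
                 metadata = metadata, genotypes = genotypes,
                 true_breakpoints = sim$breakpoints, expression = expression,
                 votes = votes, truth = truth, config = config),
            class = "synthetic_backcross")
}

#' @export
print.synthetic_backcross <- function(x, ...) {
  cat("Synthetic backcross dataset\n")
  cat(sprintf("  %d genes on %d autosomes; %d embryos (%d F1, %d N2)\n",
              nrow(x$annotation), length(unique(x$annotation$chrom)),
              nrow(x$metadata), sum(x$metadata$generation == "F1"),
              sum(x$metadata$generation == "N2")))
  cat(sprintf("  planted effects: %d cis, %d maternal, %d imprinted, %s hotspot\n",
              length(x$truth$cis), length(x$truth$maternal),
              nrow(x$truth$imprinted),
              if (is.null(x$truth$hotspot)) "no" else "1"))
  invisible(x)
}
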