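#' Preliminary per-gene genotypes from allele votes
#'
#' In an N2 backcross only B6/B6 and B6/Cast genotypes occur, so each
#' (gene, embryo) is called from its B6 vote fraction: "unknown" if fewer
#' than `min_votes` SNP-covering informative votes were found, homozygous
#' if the B6 fraction is at least `hom_threshold`, heterozygous otherwise.
#' The 0.9 boundary cleanly separates the two genotype classes at the
#' 20-vote floor: a heterozygote (B6 fraction near 0.5) and a homozygote
#' (near 1 minus the per-vote error rate) each cross it with negligible
#' probability.
#'
#' @param votes an [allele_votes()] table.
#' @param min_votes minimum informative votes for a call.
#' @param hom_threshold B6 fraction at or above which the call is B6/B6.
#' @return list of class `preliminary_genotypes`: `call` (integer matrix,
#'   0 = B6/B6, 1 = B6/Cast, NA = unknown), `b6_fraction`, `informative`.
#' @export
preliminary_genotype <- function(votes, min_votes = 20, hom_threshold = 0.9) {
  informative <- votes$b6 + votes$cast
  frac <- votes$b6 / informative
  call <- ifelse(frac >= hom_threshold, 0L, 1L)
  call[informative < min_votes] <- NA_integer_
  structure(list(call = call, b6_fraction = frac, informative = informative,
                 min_votes = min_votes),
            class = "preliminary_genotypes")
}

# Viterbi decoding of the two-state (hom/het) genotype chain for one
# chromosome of one embryo. obs: 0 hom, 1 het, NA unknown. Emissions:
# a known call is emitted by the matching state with probability 1 - eps
# and by the other state with eps; unknown genes emit uniformly. The
# per-gene-step switch probability is `transition`. Returns the most
# probable state path (all NA when the chromosome has no known call).
viterbi_genotypes <- function(obs, epsilon = 0.02, transition = 1e-4) {
  n <- length(obs)
  if (all(is.na(obs))) return(rep(NA_integer_, n))
  le_match <- log(1 - epsilon)
  le_miss <- log(epsilon)
  lt_stay <- log(1 - transition)
  lt_switch <- log(transition)
  emit <- function(state, o) {
    ifelse(is.na(o), log(0.5), ifelse(o == state, le_match, le_miss))
  }
  e0 <- emit(0L, obs)
  e1 <- emit(1L, obs)
  delta <- matrix(NA_real_, nrow = 2, ncol = n)
  psi <- matrix(NA_integer_, nrow = 2, ncol = n)
  delta[, 1] <- c(log(0.5) + e0[1], log(0.5) + e1[1])
  for (i in 2:max(2, n)) {
    if (n == 1) break
    from0 <- delta[1, i - 1] + c(lt_stay, lt_switch)
    from1 <- delta[2, i - 1] + c(lt_switch, lt_stay)
    pick <- ifelse(from0 >= from1, 1L, 2L)
    delta[, i] <- pmax(from0, from1) + c(e0[i], e1[i])
    psi[, i] <- pick
  }
  path <- integer(n)
  path[n] <- which.max(delta[, n]) - 1L
  if (n > 1) {
    for (i in n:2) path[i - 1] <- psi[path[i] + 1L, i] - 1L
  }
  path
}

# total log-probability of a given state path (used by tests as well, via
# the exported wrapper below)
genotype_path_loglik <- function(path, obs, epsilon = 0.02,
                                 transition = 1e-4) {
  em <- ifelse(is.na(obs), log(0.5),
               ifelse(obs == path, log(1 - epsilon), log(epsilon)))
  tr <- 0
  if (length(path) > 1) {
    sw <- diff(path) != 0
    tr <- sum(ifelse(sw, log(transition), log(1 - transition)))
  }
  log(0.5) + sum(em) + tr
}

#' Smooth preliminary genotypes with a two-state HMM
#'
#' Runs Viterbi decoding per embryo and chromosome over the genes in
#' genomic order, penalizing transitions between the heterozygous and
#' homozygous states. Genes with unknown preliminary calls inherit the
#' decoded state of their neighborhood, and a recombination breakpoint is
#' recorded wherever the decoded state changes between adjacent genes.
#' Inter-gene distances are ignored (one transition step per gene).
#'
#' @param prelim a [preliminary_genotype()] result.
#' @param annotation gene annotation (`gene`, `chrom`) ordering the genes;
#'   genes are taken in annotation (genomic) order within each chromosome.
#' @param epsilon emission error: probability a known call contradicts the
#'   underlying state.
#' @param transition per-gene-step probability of switching state.
#' @return list with `genotypes` (integer matrix, 0/1/NA as in the input;
#'   NA only for chromosomes without any confident call) and `breakpoints`
#'   (data frame: embryo, chrom, gap = index within the chromosome of the
#'   gene immediately left of the state change).
#' @export
smooth_genotypes_hmm <- function(prelim, annotation, epsilon = 0.02,
                                 transition = 1e-4) {
  call <- prelim$call
  embryos <- colnames(call)
  out <- call
  bp <- list()
  for (ch in unique(annotation$chrom)) {
    genes <- annotation$gene[annotation$chrom == ch]
    genes <- genes[genes %in% rownames(call)]
    if (!length(genes)) next
    for (e in seq_along(embryos)) {
      path <- viterbi_genotypes(call[genes, e], epsilon, transition)
      out[genes, e] <- path
      if (!anyNA(path)) {
        sw <- which(diff(path) != 0L)
        if (length(sw)) {
          bp[[length(bp) + 1L]] <-
            data.frame(embryo = embryos[e], chrom = ch, gap = sw)
        }
      }
    }
  }
  breakpoints <- if (length(bp)) do.call(rbind, bp) else
    data.frame(embryo = character(0), chrom = character(0), gap = integer(0))
  rownames(breakpoints) <- NULL
  list(genotypes = out, breakpoints = breakpoints)
}

#' Mask low-coverage genotypes near recombination breakpoints
#'
#' The smoothed path places each breakpoint between two genes, but genes
#' with few informative votes near a breakpoint carry little evidence for
#' either side. For every breakpoint, the nearest flanking genes with at
#' least `low_votes_threshold` informative votes are located, and every
#' gene strictly between them with fewer votes is set to unknown. Genes
#' deep inside a uniform block keep their inferred state regardless of
#' coverage.
#'
#' @param genotypes smoothed genotype matrix from [smooth_genotypes_hmm()].
#' @param prelim the [preliminary_genotype()] result (for vote counts).
#' @param breakpoints breakpoint table from [smooth_genotypes_hmm()].
#' @param annotation gene annotation ordering genes within chromosomes.
#' @param low_votes_threshold votes below which a breakpoint-adjacent gene
#'   is considered unreliable.
#' @return the genotype matrix with masked entries set to NA.
#' @export
mask_near_breakpoints <- function(genotypes, prelim, breakpoints, annotation,
                                  low_votes_threshold = 20) {
  if (!nrow(breakpoints)) return(genotypes)
  out <- genotypes
  for (ch in unique(breakpoints$chrom)) {
    genes <- annotation$gene[annotation$chrom == ch]
    genes <- genes[genes %in% rownames(genotypes)]
    sub <- breakpoints[breakpoints$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      e <- sub$embryo[i]
      g <- sub$gap[i]
      conf <- prelim$informative[genes, e] >= low_votes_threshold
      left <- which(conf[seq_len(g)])
      left <- if (length(left)) max(left) else 0L
      right <- which(conf) # first confident gene at or right of g + 1
      right <- right[right >= g + 1L]
      right <- if (length(right)) min(right) else length(genes) + 1L
      if (left + 1L > right - 1L) next
      span <- seq(left + 1L, right - 1L)
      low <- span[!conf[span]]
      if (length(low)) out[genes[low], e] <- NA_integer_
    }
  }
  out
}

#' Consolidate adjacent genes into marker regions
#'
#' Scans each chromosome left to right, merging adjacent genes while the
#' total evidence for recombination inside the running region stays within
#' budget: the number of embryo genotype calls disagreeing with the
#' region's per-embryo majority, summed across the region, must not exceed
#' `max_recombs`. With `max_recombs = 0` (exact-identity mode) a region is
#' a maximal run of genes whose genotype vectors agree across all embryos
#' wherever both are known, so adjacent regions differ in at least one
#' embryo and region boundaries are exactly the union of per-embryo
#' breakpoints. The consensus genotype per (region, embryo) is the majority
#' call; where homozygous and heterozygous calls are close to equal
#' (difference of at most one, and neither unanimous) it is unknown.
#'
#' @param genotypes genes x embryos integer matrix (0/1/NA).
#' @param annotation gene annotation ordering genes within chromosomes.
#' @param max_recombs recombination budget per region (0 = exact identity).
#' @return list of class `marker_regions`: `regions` (data frame: region,
#'   chrom, first_gene, last_gene, n_genes), `genotypes` (regions x embryos
#'   consensus matrix), `gene_region` (named vector mapping every gene to
#'   its region).
#' @export
build_marker_regions <- function(genotypes, annotation, max_recombs = 0) {
  embryos <- colnames(genotypes) %||% paste0("embryo", seq_len(ncol(genotypes)))
  regions <- list()
  cons <- list()
  gene_region <- stats::setNames(rep(NA_character_, nrow(genotypes)),
                                 rownames(genotypes))
  consensus_call <- function(n0, n1) {
    known <- n0 + n1
    call <- ifelse(n0 > n1, 0L, 1L)
    tied <- abs(n0 - n1) <= 1 & pmin(n0, n1) > 0
    call[tied | known == 0] <- NA_integer_
    call
  }
  for (ch in unique(annotation$chrom)) {
    genes <- annotation$gene[annotation$chrom == ch]
    genes <- genes[genes %in% rownames(genotypes)]
    if (!length(genes)) next
    n0 <- n1 <- rep(0L, length(embryos))
    start <- 1L
    chrom_regions <- list()
    chrom_cons <- list()
    for (j in seq_along(genes)) {
      v <- genotypes[genes[j], ]
      a0 <- n0 + (!is.na(v) & v == 0L)
      a1 <- n1 + (!is.na(v) & v == 1L)
      if (j > start && sum(pmin(a0, a1)) > max_recombs) {
        chrom_regions[[length(chrom_regions) + 1L]] <- c(start, j - 1L)
        chrom_cons[[length(chrom_cons) + 1L]] <- consensus_call(n0, n1)
        n0 <- as.integer(!is.na(v) & v == 0L)
        n1 <- as.integer(!is.na(v) & v == 1L)
        start <- j
      } else {
        n0 <- a0
        n1 <- a1
      }
    }
    chrom_regions[[length(chrom_regions) + 1L]] <- c(start, length(genes))
    chrom_cons[[length(chrom_cons) + 1L]] <- consensus_call(n0, n1)
    for (k in seq_along(chrom_regions)) {
      span <- chrom_regions[[k]]
      id <- sprintf("%s_r%03d", ch, k)
      regions[[id]] <- data.frame(
        region = id, chrom = ch,
        first_gene = genes[span[1]], last_gene = genes[span[2]],
        n_genes = span[2] - span[1] + 1L, stringsAsFactors = FALSE)
      cons[[id]] <- chrom_cons[[k]]
      gene_region[genes[span[1]:span[2]]] <- id
    }
  }
  regions <- do.call(rbind, regions)
  rownames(regions) <- regions$region
  consensus <- do.call(rbind, cons)
  dimnames(consensus) <- list(regions$region, embryos)
  structure(list(regions = regions, genotypes = consensus,
                 gene_region = gene_region),
            class = "marker_regions")
}

#' @export
print.marker_regions <- function(x, ...) {
  cat(sprintf("marker_regions: %d regions over %d chromosomes, %d embryos\n",
              nrow(x$regions), length(unique(x$regions$chrom)),
              ncol(x$genotypes)))
  invisible(x)
}

#' Run the complete genotyping stage
#'
#' Preliminary calls, HMM smoothing, breakpoint masking, and marker-region
#' consolidation in one step.
#'
#' @inheritParams preliminary_genotype
#' @inheritParams smooth_genotypes_hmm
#' @inheritParams build_marker_regions
#' @param low_votes_threshold see [mask_near_breakpoints()].
#' @return list: `prelim`, `genotypes` (smoothed + masked), `breakpoints`,
#'   `markers` (a `marker_regions` object).
#' @export
genotype_embryos <- function(votes, annotation, min_votes = 20,
                             hom_threshold = 0.9, epsilon = 0.02,
                             transition = 1e-4, low_votes_threshold = 20,
                             max_recombs = 0) {
  prelim <- preliminary_genotype(votes, min_votes, hom_threshold)
  sm <- smooth_genotypes_hmm(prelim, annotation, epsilon, transition)
  masked <- mask_near_breakpoints(sm$genotypes, prelim, sm$breakpoints,
                                  annotation, low_votes_threshold)
  markers <- build_marker_regions(masked, annotation, max_recombs)
  list(prelim = prelim, genotypes = masked, breakpoints = sm$breakpoints,
       markers = markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
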