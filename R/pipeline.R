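#' Reporting arithmetic: proportion as a printed percentage
#'
#' value = numerator / denominator x 100, rounded half-up to `digits`
#' decimal places (half-up, not banker's rounding, so printed summaries
#' match conventional reporting).
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param digits decimal places of the printed percentage.
#' @return numeric percentage.
#' @export
summarize_proportion <- function(numerator, denominator, digits = 0) {
  if (denominator <= 0) stop("denominator must be positive")
  round_half_up(numerator / denominator * 100, digits)
}

#' Reporting arithmetic: change between two group means
#'
#' @param mean_a baseline group mean (must be positive).
#' @param mean_b comparison group mean.
#' @return list with `percent_change` ((b - a)/a x 100, rounded half-up to
#'   integer) and `fold_change` (larger mean over smaller).
#' @export
summarize_change <- function(mean_a, mean_b) {
  if (mean_a <= 0) stop("baseline mean must be positive")
  list(percent_change = round_half_up((mean_b - mean_a) / mean_a * 100, 0),
       fold_change = max(mean_a, mean_b) / min(mean_a, mean_b))
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Pipeline configuration
#'
#' A single document fixing every stage parameter of an end-to-end run, so
#' a run is fully specified by (config, seed). Can be round-tripped through
#' YAML with [read_pipeline_config()].
#'
#' @param sim a [simulation_config()] (synthetic-data mode).
#' @param truth a [simulation_truth()].
#' @param out_dir output directory; created if missing. `NULL` disables
#'   file output.
#' @param stages stages to run, in dependency order; any subset of
#'   `c("simulate", "quantify", "genotype", "ase", "imprinting", "dev_ase",
#'   "maternal", "eqtl", "report")`.
#' @param min_rpm expression floor for gene filtering (RPM).
#' @param genotype list of genotyping parameters (`min_votes`,
#'   `hom_threshold`, `epsilon`, `transition`, `low_votes_threshold`,
#'   `max_recombs`).
#' @param ase list of ASE parameters (`alpha`, `baf_window`,
#'   `min_embryos`).
#' @param maternal list with `alpha`.
#' @param eqtl list with `k_hidden_factors`, `n_permutations`,
#'   `q_threshold`, `min_per_class`, `hotspot_threshold`.
#' @param seed overrides `sim$seed` when not NULL.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            truth = simulation_truth(),
                            out_dir = NULL,
                            stages = c("simulate", "quantify", "genotype",
                                       "ase", "imprinting", "dev_ase",
                                       "maternal", "eqtl", "report"),
                            min_rpm = 5,
                            genotype = list(),
                            ase = list(),
                            maternal = list(),
                            eqtl = list(),
                            seed = NULL) {
  genotype <- utils::modifyList(list(min_votes = 20, hom_threshold = 0.9,
                                     epsilon = 0.02, transition = 1e-4,
                                     low_votes_threshold = 20,
                                     max_recombs = 0), genotype)
  ase <- utils::modifyList(list(alpha = 0.01, baf_window = c(0.45, 0.55),
                                min_embryos = 3), ase)
  maternal <- utils::modifyList(list(alpha = 0.01), maternal)
  eqtl <- utils::modifyList(list(k_hidden_factors = 5, n_permutations = 20,
                                 q_threshold = 0.01, min_per_class = 5,
                                 hotspot_threshold = 0.005), eqtl)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, truth = truth, out_dir = out_dir,
                 stages = stages, min_rpm = min_rpm, genotype = genotype,
                 ase = ase, maternal = maternal, eqtl = eqtl),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order on a synthetic dataset:
#' simulate, quantify (RPM + gene filters + sex calling), genotype (HMM +
#' marker regions), then the ASE, imprinting, developmental, maternal and
#' eQTL analyses, and finally a summary report. Every stage's outputs are
#' written as TSV under `config$out_dir` (when set) and a structured log
#' records parameters and counts. A failed stage stops the run with the
#' stage named; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with the per-stage objects and
#'   a `report` (see [pipeline_report()]).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- list(config = config)
  logrec <- list()
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logrec[[name]] <<- list(stage = name,
                            seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  dir_out <- config$out_dir
  if (!is.null(dir_out) && !dir.exists(dir_out)) {
    dir.create(dir_out, recursive = TRUE)
  }
  emit <- function(obj, fname, matrix_name = "gene") {
    if (is.null(dir_out)) return(invisible(NULL))
    path <- file.path(dir_out, fname)
    if (is.matrix(obj)) write_matrix_tsv(obj, path, matrix_name)
    else write_table_tsv(obj, path)
  }
  stages <- config$stages

  if ("simulate" %in% stages) {
    out$data <- t_stage("simulate", function()
      simulate_backcross(config$sim, config$truth))
    d <- out$data
    if (!is.null(dir_out)) {
      emit(d$metadata, "metadata.tsv")
      emit(d$expression$counts, "counts.tsv")
      emit(d$votes$b6, "votes_b6.tsv")
      emit(d$votes$cast, "votes_cast.tsv")
      write_snp_vcf(d$snp_table, file.path(dir_out, "snps.vcf"))
      write_gene_bed12(d$annotation, file.path(dir_out, "genes.bed"))
      write_truth_json(d$truth, file.path(dir_out, "truth.json"))
    }
  }
  d <- out$data
  if (is.null(d)) stop("pipeline stage 'simulate' must run first ",
                       "(no dataset in scope)")
  validate_mitochondrial_design(d$metadata)

  if ("quantify" %in% stages) {
    out$quantify <- t_stage("quantify", function() {
      keep <- apply_gene_filters(d$expression, gene_annotation = d$annotation,
                                 min_rpm = config$min_rpm,
                                 autosomes = unique(d$annotation$chrom))
      sex <- assign_sex(d$metadata$xist_rpm)
      list(gene_mask = keep, sex = sex)
    })
    emit(data.frame(gene = names(out$quantify$gene_mask),
                    keep = out$quantify$gene_mask), "gene_filters.tsv")
  }

  if ("genotype" %in% stages) {
    gp <- config$genotype
    out$genotyping <- t_stage("genotype", function()
      genotype_embryos(d$votes, d$annotation, gp$min_votes,
                       gp$hom_threshold, gp$epsilon, gp$transition,
                       gp$low_votes_threshold, gp$max_recombs))
    emit(out$genotyping$genotypes, "genotypes.tsv")
    emit(out$genotyping$markers$regions, "marker_regions.tsv")
    emit(out$genotyping$markers$genotypes, "marker_genotypes.tsv", "region")
    emit(out$genotyping$breakpoints, "breakpoints.tsv")
  }

  mask <- if (!is.null(out$quantify)) out$quantify$gene_mask else
    rep(TRUE, nrow(d$annotation))
  # allele-level tests pool embryos heterozygous at each gene: use the
  # inferred genotypes when the genotyping stage ran, else the true ones
  het_geno <- if (!is.null(out$genotyping)) out$genotyping$genotypes else
    d$genotypes

  if ("ase" %in% stages) {
    out$ase <- t_stage("ase", function()
      test_ase(d$votes, het_geno, d$expression$library_size,
               min_embryos = config$ase$min_embryos,
               alpha = config$ase$alpha,
               baf_window = config$ase$baf_window))
    emit(out$ase, "ase_results.tsv")
  }
  if ("imprinting" %in% stages) {
    out$imprinting <- t_stage("imprinting", function()
      test_imprinting(d$votes, het_geno, d$metadata,
                      alpha = config$ase$alpha))
    emit(out$imprinting, "imprinting_results.tsv")
  }
  if ("dev_ase" %in% stages) {
    out$dev_ase <- t_stage("dev_ase", function()
      test_developmental_ase(d$votes, het_geno, d$metadata))
    out$dev_expression <- t_stage("dev_expression", function()
      test_developmental_expression(d$expression, d$metadata,
                                    genes = names(which(mask))))
    emit(out$dev_ase, "developmental_ase.tsv")
    emit(out$dev_expression, "developmental_expression.tsv")
  }
  if ("maternal" %in% stages) {
    out$maternal <- t_stage("maternal", function()
      test_maternal_effect(d$expression, d$metadata,
                           genes = names(which(mask)),
                           alpha = config$maternal$alpha))
    emit(out$maternal, "maternal_effects.tsv")
  }
  if ("eqtl" %in% stages) {
    if (is.null(out$genotyping)) {
      stop("pipeline stage 'eqtl' requires stage 'genotype' ",
           "(no marker regions available)")
    }
    eq <- config$eqtl
    out$eqtl <- t_stage("eqtl", function() {
      n2 <- d$metadata$generation == "N2"
      norm <- normalize_expression(d$expression, d$metadata,
                                   k_hidden_factors = eq$k_hidden_factors,
                                   genes = names(which(mask)),
                                   embryos = d$metadata$embryo[n2])
      markers <- out$genotyping$markers
      markers$genotypes <- markers$genotypes[, d$metadata$embryo[n2],
                                             drop = FALSE]
      eqtl_fdr(norm, markers, d$annotation,
               n_permutations = eq$n_permutations, seed = config$sim$seed,
               q_threshold = eq$q_threshold,
               min_per_class = eq$min_per_class, keep_full = TRUE)
    })
    emit(as.data.frame(out$eqtl), "eqtl_results.tsv")
  }
  if ("report" %in% stages) {
    out$report <- pipeline_report(out)
    if (!is.null(dir_out)) {
      jsonlite::write_json(out$report, file.path(dir_out, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out$log <- logrec
  if (!is.null(dir_out)) {
    jsonlite::write_json(logrec, file.path(dir_out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(out) <- "pipeline_result"
  out
}

#' Summary report of a pipeline run
#'
#' Per-analysis tested/significant counts with derived percentages
#' (rounded half-up as printed).
#'
#' @param result a `pipeline_result` (possibly partial).
#' @return named list of counts and percentages.
#' @export
pipeline_report <- function(result) {
  rep <- list(seed = result$config$sim$seed)
  if (!is.null(result$quantify)) {
    rep$genes_total <- length(result$quantify$gene_mask)
    rep$genes_pass_filters <- sum(result$quantify$gene_mask)
  }
  if (!is.null(result$genotyping)) {
    rep$marker_regions <- nrow(result$genotyping$markers$regions)
  }
  add_counts <- function(rep, df, label) {
    tested <- sum(!is.na(df$p))
    sig <- sum(df$significant, na.rm = TRUE)
    rep[[paste0(label, "_tested")]] <- tested
    rep[[paste0(label, "_significant")]] <- sig
    if (tested > 0) {
      rep[[paste0(label, "_percent")]] <- summarize_proportion(sig, tested)
    }
    rep
  }
  if (!is.null(result$ase)) rep <- add_counts(rep, result$ase, "ase")
  if (!is.null(result$imprinting)) {
    rep <- add_counts(rep, result$imprinting, "imprinting")
  }
  if (!is.null(result$maternal)) {
    rep <- add_counts(rep, result$maternal, "maternal")
  }
  if (!is.null(result$dev_expression)) {
    rep <- add_counts(rep, result$dev_expression, "developmental_expression")
  }
  if (!is.null(result$eqtl)) {
    sig <- result$eqtl$significant
    rep$eqtl_significant <- sum(sig)
    rep$eqtl_cis <- sum(sig & result$eqtl$classification == "cis")
    rep$eqtl_trans <- sum(sig & result$eqtl$classification == "trans")
    if (rep$eqtl_significant > 0) {
      rep$eqtl_cis_percent <- summarize_proportion(rep$eqtl_cis,
                                                   rep$eqtl_significant)
    }
  }
  rep
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level blocks matching the arguments of
#'   [pipeline_config()] (`sim`, `stages`, `genotype`, `ase`, `maternal`,
#'   `eqtl`, `min_rpm`, `seed`).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, y$sim %||% list())
  pipeline_config(sim = sim,
                  out_dir = y$out_dir,
                  stages = y$stages %||% c("simulate", "quantify", "genotype",
                                           "ase", "imprinting", "dev_ase",
                                           "maternal", "eqtl", "report"),
                  min_rpm = y$min_rpm %||% 5,
                  genotype = y$genotype %||% list(),
                  ase = y$ase %||% list(),
                  maternal = y$maternal %||% list(),
                  eqtl = y$eqtl %||% list(),
                  seed = y$seed)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$sim$seed, ")\n", sep = "")
  if (!is.null(x$report)) {
    for (k in names(x$report)) cat(sprintf("  %s: %s\n", k, x$report[[k]]))
  }
  invisible(x)
}
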