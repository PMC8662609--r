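#' Full pipeline configuration
#'
#' Collects every analysis threshold in one auditable place: the
#' matched band (0.25-0.75 B6 contribution), the erosion cutoff implied
#' by its complement, the read-misclassification rate epsilon, the
#' informative-read floor, the attribution distance, peak-calling
#' parameters and the phenotype model settings.
#'
#' @param sim [sim_config()] for the synthetic dataset.
#' @param peak [peak_params()].
#' @param epsilon Read misclassification probability for
#'   [estimate_fraction()].
#' @param min_reads Informative-read floor for classification.
#' @param band Matched band (low, high), inclusive.
#' @param max_dist Attribution centre distance (bp).
#' @param pheno_groups Cohort design for [simulate_phenotypes()].
#' @param tau True synapsis threshold used by the phenotype simulator.
#' @param pseudo_count Sperm-count floor for azoospermic mice.
#' @param n_boot Bootstrap replicates for the cliff-edge interval.
#' @param seed Master seed; per-stage streams are derived from it.
#' @param out_dir Output directory for per-stage files and the report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            peak = peak_params(),
                            epsilon = 0.01,
                            min_reads = 5L,
                            band = c(0.25, 0.75),
                            max_dist = 500L,
                            pheno_groups = default_pheno_groups(),
                            tau = 0.5,
                            pseudo_count = 2,
                            n_boot = 200L,
                            seed = 1L,
                            out_dir = tempfile("hotspotsym_run_")) {
  cfg <- list(sim = sim, peak = peak, epsilon = epsilon,
              min_reads = as.integer(min_reads), band = as.numeric(band),
              max_dist = as.integer(max_dist), pheno_groups = pheno_groups,
              tau = tau, pseudo_count = pseudo_count,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns every violated invariant as data rather than failing on the
#' first; an empty character vector means the config is valid.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of error messages.
#' @export
validate_pipeline_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs[[length(errs) + 1L]] <<- msg
  errs <- c(errs, validate_sim_config(config$sim))
  chk(length(config$band) == 2L && config$band[1] < config$band[2],
      "band: low must be < high")
  chk(all(config$band >= 0 & config$band <= 1), "band values must be in [0,1]")
  chk(config$epsilon >= 0 && config$epsilon < 0.5,
      "epsilon must be in [0, 0.5)")
  chk(config$min_reads >= 1L, "min_reads must be >= 1")
  chk(config$max_dist >= 0L, "max_dist must be nonnegative")
  chk(config$peak$q_threshold > 0 && config$peak$q_threshold <= 1,
      "q_threshold must be in (0,1]")
  chk(config$tau >= 0 && config$tau <= 1, "tau must be in [0,1]")
  chk(config$pseudo_count > 0, "pseudo_count must be positive")
  chk(config$n_boot >= 0L, "n_boot must be nonnegative")
  errs
}

#' Run the whole analysis pipeline on a synthetic hybrid dataset
#'
#' simulate -> filter informative SNPs -> assign reads to homologs ->
#' call peaks -> attribute peaks to PRDM9 alleles -> estimate per-peak
#' homolog symmetry and per-allele matched-read proportions -> phenotype
#' statistics (group t-tests and the cliff-edge threshold fit).  Every
#' stage reads the files the previous stage wrote where a file format is
#' part of the contract (FASTA/VCF/SAM), so the run exercises the full
#' I/O path.  Identical config + seed gives an identical report.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report list (also written as `report.json`
#'   under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  errs <- validate_pipeline_config(config)
  if (length(errs))
    stop("config error: ", paste(errs, collapse = "; "))
  config$sim$seed <- config$seed
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  hap <- run_stage("simulate_haplotypes",
                   generate_haplotypes(config$sim, out_dir = od))
  hs <- run_stage("simulate_hotspots",
                  generate_hotspots(config$sim, out_dir = od))
  truth_reads <- run_stage("simulate_reads",
                           simulate_reads(hs, hap, config$sim, out_dir = od))

  sites <- run_stage("filter_snps",
                     load_informative_snps(file.path(od, "variants.vcf")))
  aln <- run_stage("load_alignments",
                   read_alignments(file.path(od, "reads.sam")))
  assignments <- run_stage("assign_reads", assign_reads(aln, sites))
  asn_summary <- assignment_summary(assignments)

  peaks <- run_stage("call_peaks",
                     call_peaks(aln, config$sim$chrom_length, config$peak,
                                config$sim$assay_type))
  peaks <- run_stage("attach_reads", attach_reads(peaks, assignments))

  map1 <- hs[hs$allele == "allele1", , drop = FALSE]
  map2 <- hs[hs$allele == "allele2", , drop = FALSE]
  attr_tab <- run_stage("attribute",
                        attribute_peaks(peaks, map1, map2, config$max_dist))
  dom <- run_stage("dominance",
                   dominance_summary(attr_tab, peaks$n_plus + peaks$n_minus))

  sym <- run_stage("symmetry",
                   hotspot_symmetry(peaks, config$epsilon, config$min_reads,
                                    config$band))
  matched <- lapply(c(allele1 = "allele1", allele2 = "allele2"), function(a) {
    tryCatch(matched_read_proportion(sym, attr_tab, a),
             warning = function(w) list(read_weighted = NA_real_,
                                        peak_weighted = NA_real_,
                                        n_peaks = 0L, n_reads = 0L))
  })

  pheno <- run_stage("simulate_phenotypes",
                     simulate_phenotypes(config$pheno_groups, tau = config$tau,
                                         seed = config$seed))
  pheno$synapsis_rate <- pheno$nuclei_synapsed / pheno$nuclei_total
  pheno$testis_norm <- normalize_testis(pheno$testis_weight,
                                        pheno$lean_body_weight)
  groups <- unique(pheno$group)
  ref_group <- groups[1L]
  tests <- lapply(setdiff(groups, ref_group), function(g) {
    a <- pheno[pheno$group == ref_group, ]
    b <- pheno[pheno$group == g, ]
    list(comparison = paste(ref_group, "vs", g),
         synapsis = group_ttest(a$synapsis_rate, b$synapsis_rate),
         testis = group_ttest(a$testis_norm, b$testis_norm),
         sperm = group_ttest(log10(pmax(a$sperm_count, config$pseudo_count)),
                             log10(pmax(b$sperm_count, config$pseudo_count))))
  })
  cliff <- run_stage("cliff_edge",
                     fit_cliff_edge(pheno, config$pseudo_count,
                                    config$n_boot, config$seed))
  utils::write.table(pheno, file.path(od, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_peaks_bed(peaks, file.path(od, "peaks.bed"))
  utils::write.table(merge(sym, attr_tab, by = "peak_id"),
                     file.path(od, "symmetry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- list(
    schema_version = "1.0",
    thresholds = list(band = config$band, epsilon = config$epsilon,
                      min_reads = config$min_reads,
                      max_dist = config$max_dist,
                      q_threshold = config$peak$q_threshold,
                      pseudo_count = config$pseudo_count,
                      tau_simulated = config$tau),
    seed = config$seed,
    n_reads_simulated = nrow(truth_reads),
    assignment_counts = as.list(asn_summary),
    n_peaks = nrow(peaks),
    class_counts = as.list(table(factor(sym$class,
      levels = c("matched", "eroded_B6_biased", "eroded_ALT_biased",
                 "unresolved")))),
    attribution_counts = as.list(table(factor(attr_tab$allele,
      levels = c("allele1", "allele2", "unattributed")))),
    dominance = dom,
    matched_proportions = matched,
    phenotype_tests = tests,
    cliff_edge = list(tau_hat = cliff$tau_hat,
                      ci_tau = cliff$ci_tau,
                      mean_below = cliff$mean_below,
                      mean_above = cliff$mean_above,
                      degenerate = cliff$degenerate))
  jsonlite::write_json(report, file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

#' Read or write a pipeline config as YAML
#'
#' Configs round-trip through serialization unchanged (up to numeric
#' representation); the sim and peak sub-configs keep their classes.
#'
#' @param config A [pipeline_config()] (for writing).
#' @param path YAML path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: the config list.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$pheno_groups <- as.list(x$pheno_groups)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim[setdiff(names(x$sim), character())])
  pg <- as.data.frame(x$pheno_groups, stringsAsFactors = FALSE)
  pipeline_config(sim = sim, peak = do.call(peak_params, x$peak),
                  epsilon = x$epsilon, min_reads = x$min_reads,
                  band = x$band, max_dist = x$max_dist,
                  pheno_groups = pg, tau = x$tau,
                  pseudo_count = x$pseudo_count, n_boot = x$n_boot,
                  seed = x$seed, out_dir = x$out_dir)
}
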