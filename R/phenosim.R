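#' Default phenotype cohort design
#'
#' Four genotype groups spanning the spectrum from sterile wild-type
#' hybrid to fertile parental control, with per-group true autosomal
#' synapsis probabilities straddling the sperm-production threshold.
#'
#' @param n_per_group Mice per group.
#' @return data.frame with `group`, `p_synapsis`, `n_mice`,
#'   `testis_mg_mean`, `testis_mg_sd`, `lean_g_mean`, `lean_g_sd`.
#' @export
default_pheno_groups <- function(n_per_group = 6L) {
  data.frame(
    group = c("wt_hybrid", "hum_hybrid", "cast_hybrid", "parental"),
    p_synapsis = c(0.25, 0.45, 0.55, 0.95),
    n_mice = as.integer(n_per_group),
    testis_mg_mean = c(45, 70, 95, 200),
    testis_mg_sd = c(6, 9, 10, 15),
    lean_g_mean = c(22, 22, 22, 24),
    lean_g_sd = c(1.5, 1.5, 1.5, 1.5),
    stringsAsFactors = FALSE)
}

#' Simulate per-mouse phenotype records
#'
#' Per mouse, `min_nuclei` (default 100, plus Poisson jitter) meiotic
#' nuclei are scored and the synapsed count
#' is Binomial(nuclei, group synapsis probability).  Sperm production is a
#' threshold process: groups whose true synapsis probability is below
#' `tau` draw from a near-zero law (Poisson, mean `sperm_low_mean`),
#' groups at or above it from a high-count log-normal law.  Testis and
#' lean body weights are Normal per group (truncated at small positive
#' floors).
#'
#' @param groups Group design as from [default_pheno_groups()].
#' @param tau True synapsis threshold for sperm production.
#' @param sperm_low_mean Mean of the near-zero sperm law (counts).
#' @param sperm_high_meanlog10,sperm_high_sdlog10 log10-scale parameters
#'   of the high-count law.
#' @param min_nuclei Minimum nuclei scored per mouse.
#' @param seed Integer seed.
#' @return data.frame of PhenotypeRecord rows: `mouse_id`, `group`,
#'   `nuclei_total`, `nuclei_synapsed`, `testis_weight` (mg),
#'   `lean_body_weight` (g), `sperm_count`.
#' @export
simulate_phenotypes <- function(groups = default_pheno_groups(),
                                tau = 0.5,
                                sperm_low_mean = 1,
                                sperm_high_meanlog10 = 6,
                                sperm_high_sdlog10 = 0.25,
                                min_nuclei = 100L,
                                seed = 1L) {
  if (any(groups$p_synapsis < 0 | groups$p_synapsis > 1))
    stop("invalid-config: p_synapsis must be in [0,1]")
  if (tau < 0 || tau > 1) stop("invalid-config: tau must be in [0,1]")
  set.seed(stage_seed(seed, "phenotypes"))
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    n <- groups$n_mice[g]
    nuclei <- min_nuclei + stats::rpois(n, 15)
    syn <- stats::rbinom(n, nuclei, groups$p_synapsis[g])
    sperm <- if (groups$p_synapsis[g] < tau) {
      stats::rpois(n, sperm_low_mean)
    } else {
      round(10^stats::rnorm(n, sperm_high_meanlog10, sperm_high_sdlog10))
    }
    testis <- pmax(stats::rnorm(n, groups$testis_mg_mean[g],
                                groups$testis_mg_sd[g]), 1)
    lean <- pmax(stats::rnorm(n, groups$lean_g_mean[g],
                              groups$lean_g_sd[g]), 5)
    data.frame(group = groups$group[g], nuclei_total = nuclei,
               nuclei_synapsed = syn, testis_weight = testis,
               lean_body_weight = lean, sperm_count = sperm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(mouse_id = sprintf("m%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}
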