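# Independent oracles and small shared fixtures, built in code.

# Grid-search maximiser of the misclassification-binomial likelihood:
# n_B6 ~ Binomial(n, eps + f (1 - 2 eps)).  Two-stage grid, final
# resolution 1e-8; independent of the closed-form estimator it checks.
grid_mle_fraction <- function(n_B6, n_ALT, eps) {
  n <- n_B6 + n_ALT
  loglik <- function(f) {
    g <- eps + f * (1 - 2 * eps)
    stats::dbinom(n_B6, n, g, log = TRUE)
  }
  coarse <- seq(0, 1, by = 1e-4)
  f0 <- coarse[which.max(loglik(coarse))]
  fine <- seq(max(0, f0 - 2e-4), min(1, f0 + 2e-4), by = 1e-8)
  fine[which.max(loglik(fine))]
}

# Small hybrid simulation shared across module tests.
small_sim_config <- function(seed = 11L, seq_error_rate = 0, ...) {
  sim_config(chrom_length = 2e5, n_snps = 2000, n_hotspots_per_allele = 10,
             erosion_prob = 0.5, read_depth = 40, background_per_kb = 0.5,
             seq_error_rate = seq_error_rate, seed = seed, ...)
}

simulate_small_hybrid <- function(cfg = small_sim_config()) {
  hap <- generate_haplotypes(cfg)
  hs <- generate_hotspots(cfg)
  reads <- simulate_reads(hs, hap, cfg)
  list(cfg = cfg, hap = hap, hs = hs, reads = reads)
}

# Hand-rolled VCF fixture writer for the variant-filter tests.
write_test_vcf <- function(records, path, sample = "STRAIN") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  writeLines(c(hdr, records), path)
  path
}

# Two-sided permutation test for a difference in means (enumeration by
# Monte Carlo at fixed seed); independent check of t-test direction.
perm_test_pvalue <- function(a, b, n_perm = 2000, seed = 42) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  stat <- replicate(n_perm, {
    i <- sample.int(length(pool), na)
    abs(mean(pool[i]) - mean(pool[-i]))
  })
  (1 + sum(stat >= obs)) / (n_perm + 1)
}
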