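test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_snps = 200, chrom_length = 100), "n_snps")
  expect_error(sim_config(erosion_prob = 1.5), "erosion_prob")
  expect_error(sim_config(seq_error_rate = -0.1), "seq_error_rate")
})

test_that("haplotype generation emits the configured variants", {
  cfg <- sim_config(chrom_length = 1e6, n_snps = 100,
                    n_hotspots_per_allele = 0, seed = 3)
  od <- withr::local_tempdir()
  hap <- generate_haplotypes(cfg, out_dir = od)
  expect_equal(nrow(hap$variants), 100L)
  expect_false(any(duplicated(hap$variants$pos0)))
  expect_true(all(hap$variants$ref != hap$variants$alt))
  # the ALT haplotype differs from the reference exactly at the variants
  p1 <- hap$variants$pos0 + 1L
  expect_equal(substring(hap$alt_seq, p1, p1), hap$variants$alt)
  expect_equal(substring(hap$ref_seq, p1, p1), hap$variants$ref)
  alt_chars <- strsplit(hap$alt_seq, "")[[1]]
  ref_chars <- strsplit(hap$ref_seq, "")[[1]]
  expect_equal(which(alt_chars != ref_chars), p1)
  # emitted VCF has exactly 100 SNP records at distinct 1-based positions
  vcf <- readLines(file.path(od, "variants.vcf"))
  rec <- vcf[!startsWith(vcf, "#")]
  expect_length(rec, 100L)
  fields <- do.call(rbind, strsplit(rec, "\t", fixed = TRUE))
  expect_true(all(nchar(fields[, 4]) == 1L & nchar(fields[, 5]) == 1L))
  expect_false(any(duplicated(fields[, 2])))
  expect_equal(as.integer(fields[, 2]), hap$variants$pos0 + 1L)
})

test_that("n_snps = 0 leaves the ALT haplotype identical to the reference", {
  cfg <- sim_config(chrom_length = 1e4, n_snps = 0,
                    n_hotspots_per_allele = 0, seed = 5)
  hap <- generate_haplotypes(cfg)
  expect_identical(hap$ref_seq, hap$alt_seq)
})

test_that("identical seeds give byte-identical FASTA/VCF/SAM outputs", {
  od1 <- withr::local_tempdir(); od2 <- withr::local_tempdir()
  for (od in c(od1, od2)) {
    cfg <- small_sim_config(seed = 21L)
    hap <- generate_haplotypes(cfg, out_dir = od)
    hs <- generate_hotspots(cfg)
    simulate_reads(hs, hap, cfg, out_dir = od)
  }
  for (f in c("reference.fa", "variants.vcf", "reads.sam",
              "truth_reads.tsv")) {
    expect_identical(readLines(file.path(od1, f)),
                     readLines(file.path(od2, f)), label = f)
  }
})

test_that("erosion states follow the configured probability", {
  cfg0 <- sim_config(chrom_length = 1e6, n_snps = 0,
                     n_hotspots_per_allele = 50, erosion_prob = 0, seed = 9)
  expect_true(all(generate_hotspots(cfg0)$eroded_on == "none"))

  cfg1 <- sim_config(chrom_length = 1e6, n_snps = 0, min_spacing = 100,
                     n_hotspots_per_allele = 200, erosion_prob = 1,
                     erosion_factor = 0, seed = 9)
  hs1 <- generate_hotspots(cfg1)
  a1 <- hs1[hs1$allele == "allele1", ]
  a2 <- hs1[hs1$allele == "allele2", ]
  expect_true(all(a1$eroded_on == "B6") && all(a1$heat_homB6 == 0))
  expect_true(all(a2$eroded_on == "ALT") && all(a2$heat_homALT == 0))

  # erosion_prob = 0.8: eroded fraction within the binomial 99.9% CI
  cfg8 <- sim_config(chrom_length = 2e6, n_snps = 0, min_spacing = 100,
                     n_hotspots_per_allele = 500, erosion_prob = 0.8,
                     seed = 13)
  hs8 <- generate_hotspots(cfg8)
  frac <- mean(hs8$eroded_on != "none")
  ci <- wilson_interval(800, 1000, conf_level = 0.999)
  expect_gt(frac, ci$low)
  expect_lt(frac, ci$high)
})

test_that("eroded hotspots lose heat on the allele's own background", {
  cfg <- sim_config(chrom_length = 1e6, n_snps = 0,
                    n_hotspots_per_allele = 100, erosion_prob = 0.5,
                    erosion_factor = 0.05, seed = 2)
  hs <- generate_hotspots(cfg)
  er <- hs[hs$eroded_on != "none", ]
  expect_true(all(er$eroded_on == ifelse(er$allele == "allele1",
                                         "B6", "ALT")))
  f <- true_b6_fraction(er)
  expect_true(all(abs(f - ifelse(er$eroded_on == "B6",
                                 0.05 / 1.05, 1 / 1.05)) < 1e-12))
  expect_false(any(duplicated(hs$center)))
})

test_that("eroded-hotspot count is monotone in erosion_prob at fixed seed", {
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    cfg <- sim_config(chrom_length = 1e6, n_snps = 0,
                      n_hotspots_per_allele = 100, erosion_prob = p,
                      seed = 4)
    sum(generate_hotspots(cfg)$eroded_on != "none")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("read simulation conserves reads and respects the error model", {
  od <- withr::local_tempdir()
  cfg <- small_sim_config()
  hap <- generate_haplotypes(cfg)
  hs <- generate_hotspots(cfg)
  reads <- simulate_reads(hs, hap, cfg, out_dir = od)
  s <- list(cfg = cfg, hap = hap, hs = hs, reads = reads)
  expect_true(all(s$reads$end - s$reads$start == s$cfg$read_length))
  expect_false(any(duplicated(s$reads$read_id)))
  # conservation: every emitted read appears exactly once in the truth TSV
  truth <- read.delim(file.path(od, "truth_reads.tsv"))
  expect_setequal(truth$read_id, s$reads$read_id)
  expect_equal(nrow(truth), nrow(s$reads))
  sam <- readLines(file.path(od, "reads.sam"))
  expect_equal(sum(!startsWith(sam, "@")), nrow(s$reads))

  # zero error: every read matches its homolog of origin at all SNPs
  hit <- s$reads$hotspot_id != "background"
  for (i in which(hit)[1:50]) {
    src <- if (s$reads$true_homolog[i] == "B6") s$hap$ref_seq else s$hap$alt_seq
    expect_identical(s$reads$seq[i],
                     substr(src, s$reads$start[i] + 1, s$reads$end[i]))
  }
})

test_that("zero heat and zero background yields an empty read set", {
  cfg <- sim_config(chrom_length = 1e4, n_snps = 10,
                    n_hotspots_per_allele = 2, read_depth = 0,
                    background_per_kb = 0, seed = 6)
  hap <- generate_haplotypes(cfg)
  hs <- generate_hotspots(cfg)
  expect_warning(rd <- simulate_reads(hs, hap, cfg), "no reads")
  expect_equal(nrow(rd), 0L)
})

test_that("balanced heats give a balanced homolog of origin", {
  cfg <- sim_config(chrom_length = 5e5, n_snps = 0,
                    n_hotspots_per_allele = 25, erosion_prob = 0,
                    read_depth = 100, background_per_kb = 0, seed = 8)
  hap <- generate_haplotypes(cfg)
  hs <- generate_hotspots(cfg)
  rd <- simulate_reads(hs, hap, cfg)
  expect_gt(nrow(rd), 5000)
  p <- mean(rd$true_homolog == "B6")
  ci <- wilson_interval(round(nrow(rd) / 2), nrow(rd), conf_level = 0.999)
  expect_gt(p, ci$low)
  expect_lt(p, ci$high)
})

test_that("phenotype simulation honours group laws and the threshold", {
  g1 <- data.frame(group = "g", p_synapsis = 1, n_mice = 5L,
                   testis_mg_mean = 100, testis_mg_sd = 5,
                   lean_g_mean = 20, lean_g_sd = 1)
  ph1 <- simulate_phenotypes(g1, seed = 3)
  expect_true(all(ph1$nuclei_synapsed == ph1$nuclei_total))
  expect_true(all(ph1$nuclei_total >= 50))

  g2 <- g1; g2$p_synapsis <- 0.2; g2$n_mice <- 20L
  ph2 <- simulate_phenotypes(g2, tau = 0.5, seed = 3)
  expect_true(all(ph2$sperm_count < 100))  # near-zero law only

  g3 <- g1; g3$p_synapsis <- 0.9; g3$n_mice <- 10L
  ph3 <- simulate_phenotypes(g3, seed = 7)
  rate <- mean(ph3$nuclei_synapsed / ph3$nuclei_total)
  se <- sqrt(0.9 * 0.1 / mean(ph3$nuclei_total)) / sqrt(10)
  expect_lt(abs(rate - 0.9), 3 * se)

  g4 <- g1; g4$p_synapsis <- 1.2
  expect_error(simulate_phenotypes(g4), "invalid-config")
})
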