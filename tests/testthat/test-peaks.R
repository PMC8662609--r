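test_that("pure background produces (almost) no peaks", {
  cfg <- sim_config(chrom_length = 1e6, n_snps = 0,
                    n_hotspots_per_allele = 0, background_per_kb = 5,
                    seed = 51)
  hap <- generate_haplotypes(cfg)
  hs <- generate_hotspots(cfg)
  rd <- simulate_reads(hs, hap, cfg)
  pk <- call_peaks(rd, cfg$chrom_length)
  expect_lte(nrow(pk), 2L)  # BH false-positive budget at q = 0.01
})

test_that("a single planted hotspot is recovered at its centre", {
  cfg <- sim_config(chrom_length = 2e5, n_snps = 0,
                    n_hotspots_per_allele = 0, background_per_kb = 0.5,
                    seed = 52)
  hap <- generate_haplotypes(cfg)
  hs <- data.frame(id = "hs1", chrom = cfg$chrom, center = 1e5L,
                   allele = "allele1", heat_homB6 = 2, heat_homALT = 2,
                   eroded_on = "none", stringsAsFactors = FALSE)
  rd <- simulate_reads(hs, hap, cfg)  # depth 50 x heat 4 = 200 reads
  pk <- call_peaks(rd, cfg$chrom_length)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$start <= 1e5 && 1e5 < pk$end)
  expect_lt(abs(pk$center - 1e5), 250)
  expect_gt(pk$enrichment, 1)
  expect_gte(pk$n_plus + pk$n_minus, 5)
})

test_that("hotspots 10 kb apart stay distinct at merge_dist 1 kb", {
  cfg <- sim_config(chrom_length = 1e5, n_snps = 0,
                    n_hotspots_per_allele = 0, background_per_kb = 0,
                    seed = 53)
  hap <- generate_haplotypes(cfg)
  hs <- data.frame(id = c("a", "b"), chrom = cfg$chrom,
                   center = c(4e4L, 5e4L), allele = "allele1",
                   heat_homB6 = 2, heat_homALT = 2, eroded_on = "none",
                   stringsAsFactors = FALSE)
  rd <- simulate_reads(hs, hap, cfg)
  pk <- call_peaks(rd, cfg$chrom_length,
                   peak_params(merge_dist = 1000L))
  expect_equal(nrow(pk), 2L)
})

test_that("the peak count is monotone non-increasing in the q-threshold", {
  s <- simulate_small_hybrid()
  n <- vapply(c(0.1, 0.01, 0.001, 1e-6), function(q) {
    nrow(call_peaks(s$reads, s$cfg$chrom_length,
                    peak_params(q_threshold = q)))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("the peak set is invariant to read order", {
  s <- simulate_small_hybrid()
  pk1 <- call_peaks(s$reads, s$cfg$chrom_length)
  set.seed(1)
  shuffled <- s$reads[sample.int(nrow(s$reads)), , drop = FALSE]
  pk2 <- call_peaks(shuffled, s$cfg$chrom_length)
  expect_equal(pk1, pk2)
})

test_that("unsorted multi-chromosome input is rejected", {
  r <- data.frame(read_id = c("a", "b"), chrom = c("chr1", "chr2"),
                  start = c(0L, 0L), end = c(50L, 50L),
                  strand = "+", seq = strrep("A", 50),
                  stringsAsFactors = FALSE)
  expect_error(call_peaks(r, 1e4), "single chromosome")
})

test_that("attach_reads counts midpoints with half-open semantics", {
  pk <- data.frame(id = "p1", chrom = "chr1", start = 100L, end = 200L,
                   center = 150L, n_plus = 0L, n_minus = 0L,
                   enrichment = 2, p_value = 0, q_value = 0,
                   stringsAsFactors = FALSE)
  # alignment midpoint of [s, s+50) is s + 25
  mk <- function(id, s, call) data.frame(
    read_id = id, chrom = "chr1", start = s, end = s + 50L, strand = "+",
    n_informative = 1L, votes_B6 = as.integer(call == "B6"),
    votes_ALT = as.integer(call == "ALT"), call = call,
    stringsAsFactors = FALSE)
  asn <- rbind(mk("at_start", 75L, "B6"),      # midpoint 100 -> in
               mk("at_end", 175L, "ALT"),      # midpoint 200 -> out
               mk("inside", 120L, "ALT"),      # midpoint 145 -> in
               mk("before", 0L, "B6"))         # midpoint 25  -> out
  out <- attach_reads(pk, asn)
  expect_equal(out$n_B6, 1L)
  expect_equal(out$n_ALT, 1L)
  expect_equal(out$n_ambiguous, 0L)
  # a peak with no overlapping reads has all-zero counts
  pk2 <- pk; pk2$start <- 5000L; pk2$end <- 5100L; pk2$center <- 5050L
  out2 <- attach_reads(pk2, asn)
  expect_equal(out2$n_B6 + out2$n_ALT + out2$n_ambiguous +
                 out2$n_uninformative, 0L)
})

test_that("per-peak homolog counts agree with an oracle recount", {
  s <- simulate_small_hybrid()
  asn <- assign_reads(s$reads, s$hap$variants)
  pk <- attach_reads(call_peaks(s$reads, s$cfg$chrom_length), asn)
  mids <- (asn$start + asn$end) %/% 2L
  for (i in seq_len(nrow(pk))) {
    inpk <- mids >= pk$start[i] & mids < pk$end[i]
    expect_equal(pk$n_B6[i] + pk$n_ALT[i],
                 sum(asn$call[inpk] %in% c("B6", "ALT")))
  }
})

test_that("H3K4me3 assay centres peaks without strand geometry", {
  cfg <- sim_config(chrom_length = 2e5, n_snps = 0,
                    n_hotspots_per_allele = 0, background_per_kb = 0.2,
                    assay_type = "h3k4me3", seed = 54)
  hap <- generate_haplotypes(cfg)
  hs <- data.frame(id = "hs1", chrom = cfg$chrom, center = 1e5L,
                   allele = "allele1", heat_homB6 = 3, heat_homALT = 3,
                   eroded_on = "none", stringsAsFactors = FALSE)
  rd <- simulate_reads(hs, hap, cfg)
  pk <- call_peaks(rd, cfg$chrom_length, assay_type = "h3k4me3")
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$center - 1e5), 250)
})
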