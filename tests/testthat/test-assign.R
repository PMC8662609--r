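# Hand-built reads over two informative SNPs at pos0 10 (A>G) and 20 (C>T).
two_snp_sites <- data.frame(chrom = "chr1", pos0 = c(10L, 20L),
                            ref = c("A", "C"), alt = c("G", "T"),
                            stringsAsFactors = FALSE)

mk_read <- function(id, start, seq, strand = "+") {
  data.frame(read_id = id, chrom = "chr1", start = start,
             end = start + nchar(seq), strand = strand, seq = seq,
             stringsAsFactors = FALSE)
}

# 30-base template; positions 10 and 20 (0-based) set per test
template <- function(b10, b20) {
  s <- strrep("A", 30)
  substr(s, 11, 11) <- b10
  substr(s, 21, 21) <- b20
  s
}

test_that("votes and calls follow the majority rule", {
  reads <- rbind(
    mk_read("alt_both", 0, template("G", "T")),   # both alt -> ALT (0,2)
    mk_read("tie", 0, template("A", "T")),        # one each -> ambiguous
    mk_read("no_snp", 100, strrep("A", 30)),      # no SNP -> uninformative
    mk_read("b6_both", 0, template("A", "C")),    # both ref -> B6 (2,0)
    mk_read("abstain", 0, template("C", "G")))    # neither allele -> ambiguous
  asn <- assign_reads(reads, two_snp_sites)
  expect_equal(asn$call,
               c("ALT", "ambiguous", "uninformative", "B6", "ambiguous"))
  expect_equal(asn$votes_B6, c(0L, 1L, 0L, 2L, 0L))
  expect_equal(asn$votes_ALT, c(2L, 1L, 0L, 0L, 0L))
  expect_equal(asn$n_informative, c(2L, 2L, 0L, 2L, 2L))
  expect_true(all(asn$votes_B6 + asn$votes_ALT <= asn$n_informative))
  expect_true(all((asn$call == "uninformative") == (asn$n_informative == 0)))
})

test_that("low-quality bases abstain", {
  r <- mk_read("q", 0, template("G", "T"))
  r$qual <- paste0(strrep("I", 10), "#", strrep("I", 19))  # Q2 at SNP 1
  asn <- assign_reads(r, two_snp_sites, min_base_qual = 20)
  expect_equal(asn$n_informative, 1L)
  expect_equal(asn$votes_ALT, 1L)
  expect_equal(asn$call, "ALT")
})

test_that("empty input and chromosome mismatches are handled", {
  empty <- mk_read("x", 0, "AAAA")[0, ]
  asn <- assign_reads(empty, two_snp_sites)
  expect_equal(nrow(asn), 0L)
  expect_equal(unname(assignment_summary(asn)), rep(0L, 5))
  bad <- mk_read("x", 0, strrep("A", 30))
  bad$chrom <- "chrX"
  expect_error(assign_reads(bad, two_snp_sites), "mismatch")
})

test_that("call categories partition the reads", {
  s <- simulate_small_hybrid()
  asn <- assign_reads(s$reads, s$hap$variants)
  cnt <- assignment_summary(asn)
  expect_equal(sum(cnt[c("B6", "ALT", "ambiguous", "uninformative")]),
               unname(cnt["total"]))
  expect_equal(unname(cnt["total"]), nrow(s$reads))
})

test_that("error-free reads are always assigned to their true homolog", {
  s <- simulate_small_hybrid()  # seq_error_rate = 0
  asn <- assign_reads(s$reads, s$hap$variants)
  called <- asn$call %in% c("B6", "ALT")
  expect_gt(sum(called), 200)
  expect_equal(asn$call[called], s$reads$true_homolog[called])
  expect_equal(sum(asn$call == "ambiguous"), 0L)
})

test_that("assignment accuracy decreases with the sequencing error rate", {
  acc <- vapply(c(0, 0.01, 0.05), function(eps) {
    s <- simulate_small_hybrid(small_sim_config(seed = 31L,
                                                seq_error_rate = eps))
    asn <- assign_reads(s$reads, s$hap$variants)
    called <- asn$call %in% c("B6", "ALT")
    mean(asn$call[called] == s$reads$true_homolog[called])
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 0))
})

test_that("single-SNP flip and abstention rates match the error model", {
  # an error at the SNP hits the other allele w.p. eps/3 (homolog flip)
  # and a non-allele base w.p. 2 eps/3 (abstention -> ambiguous)
  eps <- 0.06
  cfg <- sim_config(chrom_length = 5e5, n_snps = 2000, min_spacing = 500,
                    n_hotspots_per_allele = 40, erosion_prob = 0,
                    read_depth = 150, background_per_kb = 0,
                    seq_error_rate = eps, seed = 41)
  hap <- generate_haplotypes(cfg)
  hs <- generate_hotspots(cfg)
  rd <- simulate_reads(hs, hap, cfg)
  asn <- assign_reads(rd, hap$variants)
  one <- asn$n_informative == 1L
  expect_gt(sum(one), 2000)
  flip <- asn$call[one] %in% c("B6", "ALT") &
    asn$call[one] != rd$true_homolog[one]
  abst <- asn$call[one] == "ambiguous"
  n <- sum(one)
  ci_flip <- wilson_interval(round(n * eps / 3), n, conf_level = 0.999)
  ci_abst <- wilson_interval(round(n * 2 * eps / 3), n, conf_level = 0.999)
  expect_gt(mean(flip), ci_flip$low)
  expect_lt(mean(flip), ci_flip$high)
  expect_gt(mean(abst), ci_abst$low)
  expect_lt(mean(abst), ci_abst$high)
})

test_that("SAM round-trip preserves coordinates, strand and sequence", {
  s <- simulate_small_hybrid()
  od <- withr::local_tempdir()
  write_sam(s$reads, s$cfg$chrom, s$cfg$chrom_length,
            file.path(od, "r.sam"))
  aln <- read_alignments(file.path(od, "r.sam"))
  expect_equal(nrow(aln), nrow(s$reads))
  m <- match(s$reads$read_id, aln$read_id)
  expect_false(anyNA(m))
  expect_equal(aln$start[m], s$reads$start)
  expect_equal(aln$end[m], s$reads$end)
  expect_equal(aln$strand[m], s$reads$strand)
  expect_equal(aln$seq[m], s$reads$seq)
  expect_equal(attr(aln, "n_skipped"), 0L)
})
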