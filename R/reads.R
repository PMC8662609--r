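#' Simulate aligned single-end reads from hotspots
#'
#' Per hotspot and homolog, the read count is Poisson(`read_depth` x heat
#' on that homolog).  For the SSDS assay, plus-strand reads sit upstream of
#' the hotspot centre and minus-strand reads downstream, displaced by
#' Normal(`frag_offset_mean`, `frag_offset_sd`) — the strand-asymmetric
#' geometry of resected DSB ends.  For H3K4me3, placement is symmetric
#' about the centre.  Uniform background reads are added.  Each read's
#' sequence is copied from the haplotype of its homolog of origin
#' (forward-strand orientation, as in an alignment record) with per-base
#' error `seq_error_rate`; an erroneous base becomes one of the other
#' three bases uniformly.
#'
#' @param hotspots Output of [generate_hotspots()].
#' @param haplotypes Output of [generate_haplotypes()].
#' @param config A [sim_config()].
#' @param out_dir Optional; when given, writes `reads.sam` and
#'   `truth_reads.tsv` there.
#' @return data.frame with `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `true_homolog` ("B6"/"ALT"), `hotspot_id`
#'   ("background" for background reads), `seq`.
#' @export
simulate_reads <- function(hotspots, haplotypes, config, out_dir = NULL) {
  set.seed(stage_seed(config$seed, "reads"))
  L <- as.integer(config$chrom_length)
  rl <- config$read_length
  nh <- nrow(hotspots)

  counts_b6 <- if (nh) stats::rpois(nh, config$read_depth * hotspots$heat_homB6) else integer()
  counts_alt <- if (nh) stats::rpois(nh, config$read_depth * hotspots$heat_homALT) else integer()
  hs_idx <- c(rep(seq_len(nh), counts_b6), rep(seq_len(nh), counts_alt))
  homolog <- c(rep("B6", sum(counts_b6)), rep("ALT", sum(counts_alt)))
  n_sig <- length(hs_idx)

  n_bg <- stats::rpois(1L, config$background_per_kb * L / 1000)
  n_tot <- n_sig + n_bg
  if (n_tot == 0L) {
    warning("no reads simulated: zero total heat and zero background")
    reads <- data.frame(read_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), true_homolog = character(),
                        hotspot_id = character(), seq = character(),
                        stringsAsFactors = FALSE)
    if (!is.null(out_dir)) write_reads(reads, config, out_dir)
    return(reads)
  }

  strand <- sample(c("+", "-"), n_tot, replace = TRUE)
  mid <- numeric(n_tot)
  if (n_sig) {
    center <- hotspots$center[hs_idx]
    off <- stats::rnorm(n_sig, config$frag_offset_mean, config$frag_offset_sd)
    if (config$assay_type == "ssds") {
      sgn <- ifelse(strand[seq_len(n_sig)] == "+", -1, 1)
      mid[seq_len(n_sig)] <- center + sgn * off
    } else {
      mid[seq_len(n_sig)] <- center +
        stats::rnorm(n_sig, 0, config$frag_offset_mean)
    }
  }
  if (n_bg > 0L) {
    mid[n_sig + seq_len(n_bg)] <- stats::runif(n_bg, rl / 2, L - rl / 2)
  }
  start <- pmin(pmax(as.integer(round(mid - rl / 2)), 0L), L - rl)
  homolog <- c(homolog, sample(c("B6", "ALT"), n_bg, replace = TRUE))
  hotspot_id <- c(if (n_sig) hotspots$id[hs_idx] else character(),
                  rep("background", n_bg))

  seqs <- ifelse(homolog == "B6",
                 substring(haplotypes$ref_seq, start + 1L, start + rl),
                 substring(haplotypes$alt_seq, start + 1L, start + rl))
  seqs <- mutate_bases(seqs, config$seq_error_rate, rl)

  reads <- data.frame(
    read_id = sprintf("read%07d", seq_len(n_tot)),
    chrom = config$chrom, start = start, end = start + rl,
    strand = strand, true_homolog = homolog, hotspot_id = hotspot_id,
    seq = seqs, stringsAsFactors = FALSE)
  reads <- reads[order(reads$start, reads$read_id), , drop = FALSE]
  rownames(reads) <- NULL
  if (!is.null(out_dir)) write_reads(reads, config, out_dir)
  reads
}

# Apply per-base substitution errors to a character vector of equal-length
# sequences.  Each erroneous base is replaced by one of the other three.
mutate_bases <- function(seqs, eps, rl) {
  if (eps <= 0 || !length(seqs)) return(seqs)
  n <- length(seqs)
  n_err_per_read <- stats::rbinom(n, rl, eps)
  hit <- which(n_err_per_read > 0L)
  if (!length(hit)) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(rl, n_err_per_read[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

# Write reads.sam (coordinate-sorted) + truth_reads.tsv under out_dir.
write_reads <- function(reads, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sam(reads, config$chrom, config$chrom_length,
            file.path(out_dir, "reads.sam"))
  utils::write.table(
    reads[, c("read_id", "chrom", "start", "end", "strand",
              "true_homolog", "hotspot_id")],
    file.path(out_dir, "truth_reads.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Write simulated reads as a SAM file
#'
#' Coordinate-sorted, single-end alignments; strand is encoded in FLAG bit
#' 0x10, base qualities are uniform Q40.
#'
#' @param reads Read table from [simulate_reads()].
#' @param chrom,chrom_length Reference name and length for the header.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom, chrom_length, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_length)))
  if (nrow(reads)) {
    reads <- reads[order(reads$start, reads$read_id), , drop = FALSE]
    rl <- reads$end - reads$start
    body <- paste(reads$read_id,
                  ifelse(reads$strand == "-", 16L, 0L),
                  reads$chrom, reads$start + 1L, 60L,
                  paste0(rl, "M"), "*", 0L, 0L,
                  reads$seq, strrep("I", rl), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read aligned single-end reads from SAM/BAM
#'
#' SAM input is converted with [Rsamtools::asBam()] first.  Reads flagged
#' unmapped, secondary, supplementary or duplicate are dropped and counted.
#'
#' @param path A `.sam` or `.bam` file.
#' @return data.frame with `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `seq`, `qual`, plus an attribute
#'   `n_skipped` (unusable alignment records).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "seq", "qual")))[[1L]]
  bad <- bitwAnd(b$flag, 0x4 + 0x100 + 0x400 + 0x800) != 0L | is.na(b$pos)
  keep <- !bad
  df <- data.frame(
    read_id = b$qname[keep],
    chrom = as.character(b$rname[keep]),
    start = b$pos[keep] - 1L,
    end = b$pos[keep] - 1L + b$qwidth[keep],
    strand = ifelse(bitwAnd(b$flag[keep], 0x10) != 0L, "-", "+"),
    seq = as.character(b$seq[keep]),
    qual = as.character(b$qual[keep]),
    stringsAsFactors = FALSE)
  attr(df, "n_skipped") <- sum(bad)
  df
}
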