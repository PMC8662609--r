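#' Assign aligned reads to their homolog of origin
#'
#' For every informative SNP a read overlaps, the read base votes "B6"
#' when it equals the reference allele and "ALT" when it equals the
#' alternative allele; bases matching neither, or below the base-quality
#' threshold, abstain.  The read-level call is the vote majority:
#' `B6`/`ALT` on a strict majority, `ambiguous` on a tie or when every
#' readable base abstained, `uninformative` when the read overlaps no
#' informative SNP with a readable base.
#'
#' @param reads data.frame with `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `seq`, and optionally `qual` (ASCII
#'   Phred+33); e.g. from [simulate_reads()] or [read_alignments()].
#' @param sites Informative sites from [load_informative_snps()].
#' @param min_base_qual Bases below this Phred quality abstain (only
#'   applied when a `qual` column is present).
#' @return data.frame of ReadAssignment rows: `read_id`, `chrom`, `start`,
#'   `end`, `strand`, `n_informative`, `votes_B6`, `votes_ALT`, `call`.
#' @export
assign_reads <- function(reads, sites, min_base_qual = 20L) {
  if (nrow(reads)) {
    miss <- setdiff(unique(reads$chrom), unique(sites$chrom))
    if (length(miss) && nrow(sites))
      stop("chromosome name mismatch: reads on [",
           paste(miss, collapse = ", "), "] absent from variant sites [",
           paste(unique(sites$chrom), collapse = ", "), "]")
  }
  n <- nrow(reads)
  votes_b6 <- votes_alt <- n_inf <- integer(n)
  if (n && nrow(sites)) {
    rg <- GenomicRanges::GRanges(reads$chrom,
                                 IRanges::IRanges(reads$start + 1L, reads$end))
    sg <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos0 + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(rg, sg)
    ri <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    if (length(ri)) {
      off <- sites$pos0[si] - reads$start[ri] + 1L
      base <- substring(reads$seq[ri], off, off)
      readable <- rep(TRUE, length(ri))
      if (!is.null(reads$qual)) {
        q <- utf8ToInt(paste(substring(reads$qual[ri], off, off),
                             collapse = "")) - 33L
        readable <- q >= min_base_qual
      }
      vb6 <- readable & base == sites$ref[si]
      valt <- readable & base == sites$alt[si]
      n_inf <- tab_by(ri, readable, n)
      votes_b6 <- tab_by(ri, vb6, n)
      votes_alt <- tab_by(ri, valt, n)
    }
  }
  call <- rep("uninformative", n)
  call[n_inf > 0L] <- "ambiguous"
  call[votes_b6 > votes_alt] <- "B6"
  call[votes_alt > votes_b6] <- "ALT"
  data.frame(read_id = reads$read_id, chrom = reads$chrom,
             start = reads$start, end = reads$end, strand = reads$strand,
             n_informative = n_inf, votes_B6 = votes_b6,
             votes_ALT = votes_alt, call = call, stringsAsFactors = FALSE)
}

# Count TRUEs of `flag` per read index 1..n.
tab_by <- function(idx, flag, n) {
  out <- integer(n)
  t <- rowsum(as.integer(flag), idx)
  out[as.integer(rownames(t))] <- as.integer(t[, 1L])
  out
}

#' Summarise read-assignment calls
#'
#' @param assignments Output of [assign_reads()].
#' @return Named integer vector over the four call categories plus
#'   `total`; the categories partition the usable reads.
#' @export
assignment_summary <- function(assignments) {
  lv <- c("B6", "ALT", "ambiguous", "uninformative")
  counts <- table(factor(assignments$call, levels = lv))
  out <- c(as.integer(counts), nrow(assignments))
  names(out) <- c(lv, "total")
  out
}
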