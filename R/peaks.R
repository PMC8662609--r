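#' Default peak-calling parameters
#'
#' @param window_size Test window (bp).
#' @param step Window step (bp).
#' @param background_window Local background window (bp) centred on each
#'   test window.
#' @param min_reads Minimum reads in a window for it to be reportable.
#' @param q_threshold Benjamini-Hochberg q-value cutoff.
#' @param merge_dist Significant windows closer than this are merged (bp).
#' @return Named list of parameters.
#' @export
peak_params <- function(window_size = 1000L, step = 100L,
                        background_window = 10000L, min_reads = 5L,
                        q_threshold = 0.01, merge_dist = 1000L) {
  list(window_size = as.integer(window_size), step = as.integer(step),
       background_window = as.integer(background_window),
       min_reads = as.integer(min_reads), q_threshold = q_threshold,
       merge_dist = as.integer(merge_dist))
}

#' Call hotspot peaks from strand-resolved read coverage
#'
#' Sliding-window Poisson enrichment test of the window read count
#' against max(local background rate, chromosome-wide rate), with
#' Benjamini-Hochberg correction across all tested windows.  Overlapping
#' or near-adjacent significant windows are merged into peaks.  The peak
#' centre is estimated from the strand geometry: for SSDS, the midpoint
#' between the plus-strand and minus-strand count-weighted mean read
#' midpoints (the two strands flank the DSB site); for H3K4me3, the
#' count-weighted mean of all read midpoints.
#'
#' @param reads Read table (`chrom`, `start`, `end`, `strand`), e.g. from
#'   [simulate_reads()] or [read_alignments()]; one chromosome at a time.
#' @param chrom_length Chromosome length in bases.
#' @param params [peak_params()].
#' @param assay_type `"ssds"` or `"h3k4me3"`.
#' @return data.frame of CalledPeak rows: `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `center`, `n_plus`, `n_minus`, `enrichment`,
#'   `p_value`, `q_value`.  No reads gives an empty peak list.
#' @export
call_peaks <- function(reads, chrom_length,
                       params = peak_params(),
                       assay_type = c("ssds", "h3k4me3")) {
  assay_type <- match.arg(assay_type)
  empty <- data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(), center = integer(),
                      n_plus = integer(), n_minus = integer(),
                      enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  if (length(unique(reads$chrom)) > 1L)
    stop("call_peaks expects reads from a single chromosome")
  if (is.unsorted(reads$start))
    reads <- reads[order(reads$start), , drop = FALSE]
  chrom <- reads$chrom[1L]
  L <- as.integer(chrom_length)
  mids <- read_midpoint(reads)

  w <- params$window_size
  starts <- seq.int(0L, max(L - w, 0L), by = params$step)
  mi <- IRanges::IRanges(mids + 1L, width = 1L)
  win <- IRanges::IRanges(starts + 1L, width = w)
  k <- IRanges::countOverlaps(win, mi)
  bgw <- IRanges::IRanges(pmax(starts + 1L - (params$background_window - w) %/% 2L, 1L),
                          width = params$background_window)
  kbg <- IRanges::countOverlaps(bgw, mi)
  rate_global <- length(mids) / L
  lambda <- pmax(kbg / params$background_window, rate_global) * w
  p <- stats::ppois(k - 1L, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q <= params$q_threshold & k >= params$min_reads
  if (!any(sig)) return(empty)

  merged <- IRanges::reduce(win[sig], min.gapwidth = params$merge_dist + 1L)
  ps <- IRanges::start(merged) - 1L
  pe <- IRanges::end(merged)
  # per-peak stats from reads whose midpoint falls in [start, end)
  res <- lapply(seq_along(ps), function(i) {
    inpk <- mids >= ps[i] & mids < pe[i]
    m <- mids[inpk]
    str_plus <- reads$strand[inpk] == "+"
    np <- sum(str_plus); nm <- sum(!str_plus)
    if (assay_type == "ssds" && np > 0L && nm > 0L) {
      center <- as.integer(round((mean(m[str_plus]) + mean(m[!str_plus])) / 2))
    } else {
      center <- as.integer(round(mean(m)))
    }
    center <- min(max(center, ps[i]), pe[i] - 1L)
    wsel <- sig & starts >= ps[i] - params$merge_dist & starts < pe[i]
    data.frame(start = ps[i], end = pe[i], center = center,
               n_plus = np, n_minus = nm,
               enrichment = (np + nm) / (pe[i] - ps[i]) / rate_global,
               p_value = min(p[wsel]), q_value = min(q[wsel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(id = sprintf("peak%04d", seq_len(nrow(out))),
               chrom = chrom, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Alignment midpoint of a 0-based half-open read interval.
read_midpoint <- function(reads) {
  as.integer((reads$start + reads$end) %/% 2L)
}

#' Attach homolog-assignment counts to called peaks
#'
#' Counts, per peak, the reads of each assignment category whose
#' alignment midpoint falls inside the half-open peak interval
#' `[start, end)`.
#'
#' @param peaks Output of [call_peaks()].
#' @param assignments Output of [assign_reads()].
#' @return `peaks` with added columns `n_B6`, `n_ALT`, `n_ambiguous`,
#'   `n_uninformative`.
#' @export
attach_reads <- function(peaks, assignments) {
  lv <- c("B6", "ALT", "ambiguous", "uninformative")
  cnt <- matrix(0L, nrow(peaks), 4L, dimnames = list(NULL, lv))
  if (nrow(peaks) && nrow(assignments)) {
    mids <- read_midpoint(assignments)
    pg <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
    mg <- GenomicRanges::GRanges(assignments$chrom,
                                 IRanges::IRanges(mids + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(pg, mg)
    pi <- S4Vectors::queryHits(ov)
    ai <- S4Vectors::subjectHits(ov)
    if (length(pi)) {
      tt <- table(factor(pi, levels = seq_len(nrow(peaks))),
                  factor(assignments$call[ai], levels = lv))
      cnt <- matrix(as.integer(tt), nrow(peaks), 4L,
                    dimnames = list(NULL, lv))
    }
  }
  peaks$n_B6 <- cnt[, "B6"]
  peaks$n_ALT <- cnt[, "ALT"]
  peaks$n_ambiguous <- cnt[, "ambiguous"]
  peaks$n_uninformative <- cnt[, "uninformative"]
  peaks
}

#' Write peaks as BED6+ (score = -log10 q, centre in column 7)
#'
#' @param peaks Output of [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  sc <- round(pmin(-log10(pmax(peaks$q_value, 1e-300)), 1000), 3)
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$id, sc, ".",
                    peaks$center)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
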