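#' Erosion probability that yields a target matched-read proportion
#'
#' Under the generator's erosion model, a non-eroded hotspot has equal
#' heat h on both homologs (2h of signal, all "matched") while an eroded
#' hotspot keeps h on one homolog and `factor * h` on the other
#' ((1 + factor) h of signal, "eroded" class).  With erosion probability
#' p independent of heat, the expected read-weighted matched proportion
#' is `2 (1 - p) / (2 (1 - p) + (1 + factor) p)`; this inverts that map.
#'
#' @param matched Target matched-read proportion in (0, 1].
#' @param factor Erosion factor (residual heat on the eroded homolog).
#' @return Erosion probability p in [0, 1).
#' @export
erosion_for_matched <- function(matched, factor = 0.05) {
  stopifnot(matched > 0, matched <= 1)
  2 * (1 - matched) / (2 * (1 - matched) + matched * (1 + factor))
}

#' Simulation configs for the two hybrid regimes
#'
#' `"eroded"` emulates the wild-type interspecies hybrid, where heavy
#' reciprocal erosion leaves only ~15% of DSB signal at matched
#' positions for each allele.  `"denovo"` emulates a hybrid whose first
#' allele has been replaced by an engineered (de novo) allele: its
#' binding sites are largely intact on both homologs, modelled as a
#' much-reduced residual erosion probability placing its true matched
#' read proportion at ~60% (the second allele keeps wild-type erosion).
#'
#' @param regime `"eroded"` or `"denovo"`.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
regime_config <- function(regime = c("eroded", "denovo"), seed = 1L) {
  regime <- match.arg(regime)
  p_wt <- erosion_for_matched(0.15)
  p_dn <- erosion_for_matched(0.60)
  sim_config(
    chrom_length = 2e7, n_snps = 2e5, n_hotspots_per_allele = 200,
    erosion_prob = if (regime == "eroded") c(p_wt, p_wt) else c(p_dn, p_wt),
    erosion_factor = 0.05, heat_meanlog = 0, heat_sdlog = 0.75,
    read_depth = 80, background_per_kb = 0.2,
    seq_error_rate = 0.001, assay_type = "ssds", seed = seed)
}

#' True matched-read proportion realised in a simulation
#'
#' The oracle counterpart of [matched_read_proportion()]: using the
#' simulator's truth (hotspot heats and read origins), the proportion of
#' hotspot reads of one allele that came from hotspots whose *true* B6
#' fraction lies inside the matched band.
#'
#' @param truth_reads Read table from [simulate_reads()].
#' @param hotspots Truth table from [generate_hotspots()].
#' @param allele `"allele1"` or `"allele2"`.
#' @param band Matched band.
#' @return List with `read_weighted`, `peak_weighted`, `n_reads`.
#' @export
truth_matched_read_proportion <- function(truth_reads, hotspots, allele,
                                          band = c(0.25, 0.75)) {
  f <- true_b6_fraction(hotspots)
  matched <- f >= band[1] & f <= band[2]
  hs <- hotspots[hotspots$allele == allele, , drop = FALSE]
  m <- matched[hotspots$allele == allele]
  counts <- table(factor(truth_reads$hotspot_id, levels = hs$id))
  n <- as.numeric(counts)
  list(read_weighted = sum(n[m]) / sum(n),
       peak_weighted = mean(m), n_reads = sum(n))
}
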