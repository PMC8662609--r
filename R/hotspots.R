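#' Generate truth hotspots for two PRDM9 alleles
#'
#' Each allele activates its own hotspots, with heavy-tailed (log-normal)
#' intensities.  With probability `erosion_prob[k]` a hotspot of allele k
#' has its binding site eroded on the homolog carrying that allele's own
#' genetic background (allele 1 erodes on the B6 homolog, allele 2 on the
#' ALT homolog): its heat on that homolog is multiplied by
#' `erosion_factor`.  A de novo allele whose motifs are intact on both
#' homologs corresponds to `erosion_prob` near 0 for that allele.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional; when given, writes `truth_hotspots.tsv` and a
#'   0-based half-open `truth_hotspots.bed`.
#' @return data.frame with one row per hotspot: `id`, `chrom`, `center`
#'   (0-based), `allele` ("allele1"/"allele2"), `heat_homB6`,
#'   `heat_homALT`, `eroded_on` ("none"/"B6"/"ALT").
#' @export
generate_hotspots <- function(config, out_dir = NULL) {
  errs <- validate_sim_config(config)
  if (length(errs)) stop("invalid sim_config: ", paste(errs, collapse = "; "))
  set.seed(stage_seed(config$seed, "hotspots"))
  n <- config$n_hotspots_per_allele
  total <- 2L * n
  if (total == 0L) {
    return(data.frame(id = character(), chrom = character(),
                      center = integer(), allele = character(),
                      heat_homB6 = numeric(), heat_homALT = numeric(),
                      eroded_on = character(), stringsAsFactors = FALSE))
  }
  # unique centres, kept clear of the chromosome ends and at least
  # min_spacing apart (hotspots are discrete, well-separated loci):
  # uniform draw conditioned on the spacing via the gap transform
  margin <- min(1000L, floor(config$chrom_length / 10))
  lo <- margin
  hi <- as.integer(config$chrom_length) - margin
  spacing <- min(config$min_spacing, floor((hi - lo) / max(total, 1L)))
  u <- sort(stats::runif(total, 0, hi - lo - (total - 1L) * spacing))
  centers <- as.integer(round(lo + u + (seq_len(total) - 1L) * spacing))
  allele <- sample(rep(c("allele1", "allele2"), each = n))
  heat <- stats::rlnorm(total, config$heat_meanlog, config$heat_sdlog)
  own_bg <- ifelse(allele == "allele1", "B6", "ALT")
  p_erode <- ifelse(allele == "allele1",
                    config$erosion_prob[1L], config$erosion_prob[2L])
  eroded <- stats::runif(total) < p_erode
  hb6 <- ifelse(eroded & own_bg == "B6", heat * config$erosion_factor, heat)
  halt <- ifelse(eroded & own_bg == "ALT", heat * config$erosion_factor, heat)
  hs <- data.frame(
    id = sprintf("hs%04d", seq_len(total)),
    chrom = config$chrom, center = centers, allele = allele,
    heat_homB6 = hb6, heat_homALT = halt,
    eroded_on = ifelse(eroded, own_bg, "none"),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(hs, file.path(out_dir, "truth_hotspots.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    half <- 500L
    bed <- data.frame(hs$chrom, pmax(hs$center - half, 0L),
                      pmin(hs$center + half, as.integer(config$chrom_length)),
                      hs$id, 0L, ".")
    utils::write.table(bed, file.path(out_dir, "truth_hotspots.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  hs
}

#' True B6-homolog fraction of each truth hotspot
#'
#' @param hotspots Output of [generate_hotspots()].
#' @return Numeric vector `heat_homB6 / (heat_homB6 + heat_homALT)`.
#' @export
true_b6_fraction <- function(hotspots) {
  hotspots$heat_homB6 / (hotspots$heat_homB6 + hotspots$heat_homALT)
}
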