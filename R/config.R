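#' Simulation configuration for a synthetic hybrid dataset
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object.  The generator emulates an F1 hybrid between two inbred mouse
#' strains: a reference ("B6") haplotype and an alternative ("ALT", e.g.
#' SPRET- or STUS-like) haplotype differing at biallelic SNPs, plus two
#' PRDM9 alleles each activating its own set of hotspots.  Hotspots of an
#' allele may be eroded on the homolog carrying that allele's own genetic
#' background, reproducing the asymmetric-binding situation of hybrids.
#'
#' @param chrom_length Chromosome length in bases.
#' @param chrom Chromosome name used in all emitted files.
#' @param n_snps Number of strain-distinguishing biallelic SNPs.
#' @param n_hotspots_per_allele Hotspots activated by each PRDM9 allele.
#' @param min_spacing Minimum distance between hotspot centres in bases
#'   (shrunk automatically when the chromosome cannot accommodate it).
#' @param erosion_prob Probability that a hotspot's binding site has been
#'   eroded on the homolog matching its allele's own background.  Scalar or
#'   length-2 vector (allele1, allele2); a de novo (engineered) allele is
#'   modelled by a low value for that allele.
#' @param erosion_factor Multiplicative heat reduction on the eroded
#'   homolog (0 = complete loss).
#' @param heat_meanlog,heat_sdlog Log-normal parameters of the per-hotspot
#'   intensity ("heat") law; heavy-tailed, as binding affinities span a
#'   wide spectrum from strong to weak.
#' @param read_depth Expected reads per unit heat per homolog.
#' @param read_length Read length in bases (single-end).
#' @param frag_offset_mean,frag_offset_sd Strand-specific displacement, in
#'   bases, of read midpoints from the hotspot centre (SSDS geometry:
#'   plus-strand reads upstream, minus-strand downstream).
#' @param seq_error_rate Per-base sequencing error probability (epsilon);
#'   an erroneous base is replaced by one of the other three uniformly.
#' @param background_per_kb Expected uniform background reads per kilobase.
#' @param assay_type `"ssds"` (strand-offset read geometry) or
#'   `"h3k4me3"` (symmetric geometry).
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_length = 1e6,
                       chrom = "chr1",
                       n_snps = 10000,
                       n_hotspots_per_allele = 50,
                       min_spacing = 5000,
                       erosion_prob = 0.5,
                       erosion_factor = 0.05,
                       heat_meanlog = 0,
                       heat_sdlog = 0.75,
                       read_depth = 50,
                       read_length = 50,
                       frag_offset_mean = 100,
                       frag_offset_sd = 30,
                       seq_error_rate = 0.001,
                       background_per_kb = 0.5,
                       assay_type = c("ssds", "h3k4me3"),
                       seed = 1L) {
  assay_type <- match.arg(assay_type)
  cfg <- list(
    chrom_length = as.numeric(chrom_length), chrom = chrom,
    n_snps = as.integer(n_snps),
    n_hotspots_per_allele = as.integer(n_hotspots_per_allele),
    min_spacing = as.numeric(min_spacing),
    erosion_prob = rep_len(as.numeric(erosion_prob), 2L),
    erosion_factor = as.numeric(erosion_factor),
    heat_meanlog = as.numeric(heat_meanlog),
    heat_sdlog = as.numeric(heat_sdlog),
    read_depth = as.numeric(read_depth),
    read_length = as.integer(read_length),
    frag_offset_mean = as.numeric(frag_offset_mean),
    frag_offset_sd = as.numeric(frag_offset_sd),
    seq_error_rate = as.numeric(seq_error_rate),
    background_per_kb = as.numeric(background_per_kb),
    assay_type = assay_type,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  errs <- validate_sim_config(cfg)
  if (length(errs)) stop("invalid sim_config: ", paste(errs, collapse = "; "))
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` list.
#' @return Character vector of violated invariants (empty when valid).
#' @export
validate_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs[[length(errs) + 1L]] <<- msg
  chk(cfg$chrom_length >= 1, "chrom_length must be positive")
  chk(cfg$n_snps >= 0, "n_snps must be nonnegative")
  chk(cfg$n_snps <= cfg$chrom_length, "n_snps exceeds chrom_length")
  chk(cfg$n_hotspots_per_allele >= 0, "n_hotspots_per_allele must be nonnegative")
  chk(cfg$min_spacing >= 0, "min_spacing must be nonnegative")
  chk(all(cfg$erosion_prob >= 0 & cfg$erosion_prob <= 1),
      "erosion_prob must be in [0,1]")
  chk(cfg$erosion_factor >= 0 && cfg$erosion_factor <= 1,
      "erosion_factor must be in [0,1]")
  chk(cfg$read_depth >= 0, "read_depth must be nonnegative")
  chk(cfg$read_length >= 1, "read_length must be positive")
  chk(cfg$read_length <= cfg$chrom_length, "read_length exceeds chrom_length")
  chk(cfg$seq_error_rate >= 0 && cfg$seq_error_rate <= 1,
      "seq_error_rate must be in [0,1]")
  chk(cfg$background_per_kb >= 0, "background_per_kb must be nonnegative")
  chk(cfg$frag_offset_sd >= 0, "frag_offset_sd must be nonnegative")
  errs
}

# Deterministic per-stage seed derived from the master seed, so stages can
# be rerun in isolation with identical random streams.  Kept below 2^31.
stage_seed <- function(seed, stage) {
  offs <- c(haplotypes = 1L, hotspots = 2L, reads = 3L, phenotypes = 4L,
            background = 5L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 97L + offs[[stage]] * 1009L) %% .Machine$integer.max)
}
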