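#' Load strain-distinguishing informative SNPs from a VCF
#'
#' Applies the informative-site filter used for homolog assignment in
#' hybrids: keep only records that are single-nucleotide, biallelic,
#' passed all upstream quality filters (FILTER == "PASS"), and are called
#' homozygous for the alternative allele in the non-reference strain.
#' Heterozygous, missing-genotype, indel and multiallelic records are
#' dropped (a third allele cannot be attributed to either homolog).
#'
#' @param vcf_path Path to a VCF (v4.2, plain or bgzipped).
#' @param sample Genotype column to judge homozygosity from; default the
#'   first sample.  A VCF with no genotype columns keeps PASS SNPs (sites
#'   assumed pre-filtered to homozygous calls).
#' @return data.frame of VariantSite rows sorted by (chrom, pos0):
#'   `chrom`, `pos0` (0-based), `ref`, `alt`.  Empty result raises a
#'   warning, not an error.
#' @export
load_informative_snps <- function(vcf_path, sample = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record VCF gives a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    warning("no informative SNPs found in ", vcf_path)
    return(data.frame(chrom = character(), pos0 = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !is.na(fix$FILTER) & fix$FILTER == "PASS"
  gt <- v@gt
  if (!is.null(gt) && ncol(gt) >= 2L) {
    samples <- colnames(gt)[-1L]
    if (is.null(sample)) sample <- samples[1L]
    if (!sample %in% samples)
      stop("sample '", sample, "' not present in VCF (has: ",
           paste(samples, collapse = ", "), ")")
    gtfield <- vcfR::extract.gt(v, element = "GT")[, sample]
    hom_alt <- !is.na(gtfield) & gsub("\\|", "/", gtfield) %in% c("1/1", "1")
    keep <- keep & hom_alt
  }
  out <- data.frame(chrom = fix$CHROM[keep],
                    pos0 = as.integer(fix$POS[keep]) - 1L,
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no informative SNPs found in ", vcf_path)
  out
}

#' Write informative sites as a BED file (0-based half-open)
#'
#' @param sites data.frame from [load_informative_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$pos0, sites$pos0 + 1L,
                    paste0(sites$ref, ">", sites$alt))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
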