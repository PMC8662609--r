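#' Generate the two parental haplotypes of a hybrid chromosome
#'
#' Draws a random reference chromosome and `n_snps` biallelic substitution
#' sites at distinct positions that define the alternative (non-reference
#' strain) haplotype, emulating published strain variant calls.  All sites
#' are emitted as homozygous-ALT, PASS records, as the informative-site
#' filter downstream expects.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `reference.fa`
#'   and `variants.vcf` there.
#' @return List with `ref_seq` and `alt_seq` (character, length-1 strings),
#'   and `variants`: data.frame with `chrom`, `pos0` (0-based), `ref`,
#'   `alt`.  VCF output is 1-based.
#' @export
generate_haplotypes <- function(config, out_dir = NULL) {
  errs <- validate_sim_config(config)
  if (length(errs)) stop("invalid sim_config: ", paste(errs, collapse = "; "))
  set.seed(stage_seed(config$seed, "haplotypes"))
  bases <- c("A", "C", "G", "T")
  L <- as.integer(config$chrom_length)
  ref_vec <- sample(bases, L, replace = TRUE)
  if (config$n_snps > 0) {
    pos0 <- sort(sample.int(L, config$n_snps, replace = FALSE)) - 1L
    ref_b <- ref_vec[pos0 + 1L]
    # alt base: uniform among the three non-reference bases
    alt_b <- vapply(ref_b, function(b) sample(setdiff(bases, b), 1L), "")
    variants <- data.frame(chrom = config$chrom, pos0 = pos0,
                           ref = ref_b, alt = unname(alt_b),
                           stringsAsFactors = FALSE)
  } else {
    variants <- data.frame(chrom = character(), pos0 = integer(),
                           ref = character(), alt = character(),
                           stringsAsFactors = FALSE)
  }
  alt_vec <- ref_vec
  if (nrow(variants)) alt_vec[variants$pos0 + 1L] <- variants$alt
  hap <- list(ref_seq = paste(ref_vec, collapse = ""),
              alt_seq = paste(alt_vec, collapse = ""),
              chrom = config$chrom, variants = variants)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ss <- Biostrings::DNAStringSet(hap$ref_seq)
    names(ss) <- config$chrom
    Biostrings::writeXStringSet(ss, file.path(out_dir, "reference.fa"))
    write_variants_vcf(variants, file.path(out_dir, "variants.vcf"),
                       sample_name = "ALT_strain")
  }
  hap
}

#' Write strain variants as a minimal VCF v4.2
#'
#' One homozygous-ALT genotype column for the non-reference strain; FILTER
#' is PASS for every record (the generator emulates already-filtered calls).
#'
#' @param variants data.frame with `chrom`, `pos0`, `ref`, `alt`.
#' @param path Output path.
#' @param sample_name Genotype column name.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, sample_name = "ALT_strain") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hotspotsym-simulator",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  if (nrow(variants)) {
    rec <- paste(variants$chrom, variants$pos0 + 1L, ".", variants$ref,
                 variants$alt, ".", "PASS", ".", "GT", "1/1", sep = "\t")
  } else rec <- character()
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# Base at 0-based positions of a haplotype string (vectorised).
hap_base <- function(seq, pos0) {
  substring(seq, pos0 + 1L, pos0 + 1L)
}
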