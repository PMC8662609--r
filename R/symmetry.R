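#' Estimate the B6-homolog read fraction with misclassification correction
#'
#' Models each informative read as carrying the wrong homolog label with
#' probability `epsilon` (sequencing/assignment error), so the observed
#' B6 proportion has expectation `epsilon + f (1 - 2 epsilon)` where `f`
#' is the true B6 fraction.  The maximum-likelihood estimate is
#' `clamp((p_obs - epsilon) / (1 - 2 epsilon), 0, 1)`; the 95% interval
#' is the Wilson interval on `p_obs` mapped through the same
#' transformation and clamped.
#'
#' @param n_B6,n_ALT Informative read counts (vectors allowed).
#' @param epsilon Misclassification probability, `0 <= epsilon < 0.5`.
#' @param conf_level Confidence level of the interval.
#' @return data.frame with `f_hat`, `ci_low`, `ci_high`.
#' @export
estimate_fraction <- function(n_B6, n_ALT, epsilon = 0, conf_level = 0.95) {
  if (any(epsilon < 0) || any(epsilon >= 0.5))
    stop("epsilon must be in [0, 0.5)")
  n <- n_B6 + n_ALT
  if (any(n < 1)) stop("n_B6 + n_ALT must be >= 1")
  p_obs <- n_B6 / n
  unmap <- function(p) pmin(pmax((p - epsilon) / (1 - 2 * epsilon), 0), 1)
  ci <- wilson_interval(n_B6, n, conf_level)
  data.frame(f_hat = unmap(p_obs),
             ci_low = unmap(ci$low), ci_high = unmap(ci$high))
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes; @param n Trials; @param conf_level Level.
#' @return data.frame with `low`, `high` (vectorised).
#' @export
wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(low = pmax(center - half, 0), high = pmin(center + half, 1))
}

#' Classify hotspots as matched or eroded from their B6 fraction
#'
#' A hotspot is "matched" when both homologs contribute appreciably —
#' operationally, an estimated B6 fraction between 0.25 and 0.75
#' (inclusive).  Erosion is a stronger-than-75% skew toward one homolog:
#' `f_hat > 0.75` means the ALT-homolog copy is eroded (reads come from
#' B6), `f_hat < 0.25` the converse.  Peaks with fewer informative reads
#' than `min_reads` are "unresolved".
#'
#' @param f_hat Estimated B6 fractions.
#' @param n_informative Informative read counts (`n_B6 + n_ALT`).
#' @param min_reads Minimum informative reads to attempt classification.
#' @param band Matched band endpoints (inclusive).
#' @return Character vector over {matched, eroded_B6_biased,
#'   eroded_ALT_biased, unresolved}.
#' @export
classify_hotspot <- function(f_hat, n_informative, min_reads = 5L,
                             band = c(0.25, 0.75)) {
  stopifnot(band[1] < band[2])
  cls <- ifelse(n_informative < min_reads, "unresolved",
         ifelse(f_hat > band[2], "eroded_B6_biased",
         ifelse(f_hat < band[1], "eroded_ALT_biased", "matched")))
  cls
}

#' Per-peak homolog symmetry table
#'
#' Combines [estimate_fraction()] and [classify_hotspot()] over a peak
#' table carrying homolog read counts (from [attach_reads()]).
#' Ambiguous and uninformative reads are excluded throughout.
#'
#' @param peaks Peaks with `id`, `n_B6`, `n_ALT` columns.
#' @param epsilon Read misclassification probability.
#' @param min_reads Minimum informative reads for a resolved class.
#' @param band Matched band.
#' @return data.frame of HotspotSymmetry rows: `peak_id`, `n_B6`,
#'   `n_ALT`, `f_hat`, `ci_low`, `ci_high`, `class`; `f_hat` is `NA` for
#'   unresolved peaks with zero informative reads.
#' @export
hotspot_symmetry <- function(peaks, epsilon = 0.01, min_reads = 5L,
                             band = c(0.25, 0.75)) {
  n <- peaks$n_B6 + peaks$n_ALT
  est <- data.frame(f_hat = rep(NA_real_, nrow(peaks)),
                    ci_low = NA_real_, ci_high = NA_real_)
  pos <- n >= 1L
  if (any(pos))
    est[pos, ] <- estimate_fraction(peaks$n_B6[pos], peaks$n_ALT[pos], epsilon)
  cls <- rep("unresolved", nrow(peaks))
  cls[pos] <- classify_hotspot(est$f_hat[pos], n[pos], min_reads, band)
  out <- data.frame(peak_id = peaks$id, n_B6 = peaks$n_B6,
                    n_ALT = peaks$n_ALT,
                    f_hat = est$f_hat, ci_low = est$ci_low,
                    ci_high = est$ci_high, class = cls,
                    stringsAsFactors = FALSE)
  # total strand-resolved read count, for signal-weighted summaries
  if (!is.null(peaks$n_plus) && !is.null(peaks$n_minus))
    out$n_total <- peaks$n_plus + peaks$n_minus
  out
}

#' Proportion of reads (and peaks) at matched hotspots for one allele
#'
#' Over the resolved peaks attributed to the given allele: the sum of
#' informative reads at matched peaks divided by the sum of informative
#' reads at all such peaks (read-weighted), and the analogous proportion
#' of peaks (peak-weighted).
#'
#' @param symmetries Output of [hotspot_symmetry()].
#' @param attributions Output of [attribute_peaks()].
#' @param allele `"allele1"` or `"allele2"`.
#' @return List with `read_weighted` (weights = informative reads),
#'   `total_read_weighted` (weights = all strand-resolved peak reads;
#'   `NA` when `symmetries` lacks an `n_total` column), `peak_weighted`,
#'   `n_peaks`, `n_reads`.  All proportions are `NA` (with a warning)
#'   when the allele has no resolved attributed peaks.
#' @export
matched_read_proportion <- function(symmetries, attributions, allele) {
  sym <- merge(symmetries, attributions, by = "peak_id")
  sel <- sym$allele == allele & sym$class != "unresolved"
  if (!any(sel)) {
    warning("no resolved peaks attributed to ", allele)
    return(list(read_weighted = NA_real_, total_read_weighted = NA_real_,
                peak_weighted = NA_real_, n_peaks = 0L, n_reads = 0L))
  }
  s <- sym[sel, , drop = FALSE]
  reads <- s$n_B6 + s$n_ALT
  matched <- s$class == "matched"
  tot <- if (!is.null(s$n_total)) {
    sum(s$n_total[matched]) / sum(s$n_total)
  } else NA_real_
  list(read_weighted = sum(reads[matched]) / sum(reads),
       total_read_weighted = tot,
       peak_weighted = mean(matched),
       n_peaks = nrow(s), n_reads = sum(reads))
}
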