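#' Attribute hybrid peaks to the PRDM9 allele activating them
#'
#' Compares each hybrid peak centre with single-allele reference hotspot
#' maps.  A peak is attributed to an allele iff its centre lies within
#' `max_dist` of a centre in that allele's map and not within `max_dist`
#' of any centre in the other map; peaks near both maps or neither are
#' left unattributed (conservative ambiguity rule).
#'
#' @param peaks Peaks with `id` and `center` columns.
#' @param map1,map2 Reference maps: data.frames (or vectors) of hotspot
#'   centres for allele 1 and allele 2; a data.frame uses its `center`
#'   column.
#' @param max_dist Maximum centre-to-centre distance in bases.
#' @return data.frame of AlleleAttribution rows: `peak_id`, `allele`
#'   ("allele1"/"allele2"/"unattributed").
#' @export
attribute_peaks <- function(peaks, map1, map2, max_dist = 500L) {
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids")
  c1 <- map_centers(map1)
  c2 <- map_centers(map2)
  d1 <- nearest_dist(peaks$center, c1)
  d2 <- nearest_dist(peaks$center, c2)
  near1 <- d1 <= max_dist
  near2 <- d2 <= max_dist
  allele <- rep("unattributed", nrow(peaks))
  allele[near1 & !near2] <- "allele1"
  allele[near2 & !near1] <- "allele2"
  data.frame(peak_id = peaks$id, allele = allele, stringsAsFactors = FALSE)
}

map_centers <- function(map) {
  if (is.data.frame(map)) as.numeric(map$center) else as.numeric(map)
}

# Distance from each x to the nearest value in `centers` (Inf when empty).
nearest_dist <- function(x, centers) {
  if (!length(centers)) return(rep(Inf, length(x)))
  centers <- sort(centers)
  i <- findInterval(x, centers)
  lo <- centers[pmax(i, 1L)]
  hi <- centers[pmin(i + 1L, length(centers))]
  pmin(abs(x - lo), abs(x - hi))
}

#' Summarise allele dominance over attributed peaks
#'
#' Reports the share of hotspots controlled by each allele, both as a
#' proportion of peaks and weighted by per-peak read totals — the
#' peak-count and signal views of dominance.
#'
#' @param attributions Output of [attribute_peaks()].
#' @param read_totals Per-peak read totals aligned with `attributions`
#'   rows (e.g. `n_plus + n_minus`).
#' @return data.frame with rows allele1/allele2/unattributed and columns
#'   `n_peaks`, `prop_peaks`, `n_reads`, `prop_reads`; each proportion
#'   column sums to 1.  Empty input gives an empty summary with a warning.
#' @export
dominance_summary <- function(attributions, read_totals) {
  lv <- c("allele1", "allele2", "unattributed")
  if (nrow(attributions) == 0L) {
    warning("no peaks to summarise")
    return(data.frame(allele = lv, n_peaks = 0L, prop_peaks = NA_real_,
                      n_reads = 0, prop_reads = NA_real_,
                      stringsAsFactors = FALSE))
  }
  stopifnot(length(read_totals) == nrow(attributions))
  f <- factor(attributions$allele, levels = lv)
  n_peaks <- as.integer(table(f))
  n_reads <- as.numeric(tapply(read_totals, f, sum, default = 0))
  data.frame(allele = lv, n_peaks = n_peaks,
             prop_peaks = n_peaks / sum(n_peaks),
             n_reads = n_reads,
             prop_reads = if (sum(n_reads) > 0) n_reads / sum(n_reads)
                          else rep(NA_real_, 3L),
             stringsAsFactors = FALSE)
}
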