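# Sequencing-library accounting arithmetic: duplicate rates, downsampling
# fractions to a fixed uniquely-aligned target, the peak-caller read
# extension midpoint, and qPCR amplification-cycle selection.

#' Percent of unique, non-duplicated reads
#'
#' `round(after_dedup / (2 * read_pairs) * 100)`, half-up, as printed in
#' library QC tables. The denominator is total reads (two per pair); the
#' numerator is uniquely aligned reads surviving duplicate removal.
#'
#' @param read_pairs sequenced read pairs (> 0).
#' @param after_dedup uniquely aligned reads after deduplication.
#' @return integer percentage (vectorized).
#' @examples
#' percent_unique_nondup(5728173, 6775525)  # 59
#' @export
percent_unique_nondup <- function(read_pairs, after_dedup) {
  if (any(read_pairs <= 0)) .fail("read_pairs must be > 0")
  if (any(after_dedup < 0)) .fail("after_dedup must be >= 0")
  as.integer(round_half_up(after_dedup / (2 * read_pairs) * 100))
}

#' Percent of reads to keep when downsampling to a fixed target
#'
#' `min(100, round(target / after_dedup * 100))`, half-up. Libraries with
#' fewer deduplicated reads than the target are kept whole (100). The
#' default target of 3.8 million uniquely aligned reads puts all libraries
#' of a benchmark at equal depth before peak calling.
#'
#' @param after_dedup uniquely aligned reads after deduplication (> 0).
#' @param target downsampling target in reads.
#' @return integer percentage (vectorized), capped at 100.
#' @examples
#' downsample_fraction(6775525)  # 56
#' @export
downsample_fraction <- function(after_dedup, target = 3.8e6) {
  if (any(after_dedup <= 0)) .fail("after_dedup must be > 0")
  if (any(target <= 0)) .fail("target must be > 0")
  as.integer(pmin(100, round_half_up(target / after_dedup * 100)))
}

#' Augment a library-accounting table with derived percentages
#'
#' Adds `pct_unique_nondup` ([percent_unique_nondup()]) and `pct_to_keep`
#' ([downsample_fraction()]) columns to a table with columns `read_pairs`
#' and `after_dedup` (a `uniquely_aligned` column, when present, is checked
#' against the `after_dedup <= uniquely_aligned` invariant).
#'
#' @param libs data frame of per-library counts.
#' @param target downsampling target in reads.
#' @return the augmented data frame.
#' @export
library_stats <- function(libs, target = 3.8e6) {
  stopifnot(is.data.frame(libs))
  need <- c("read_pairs", "after_dedup")
  if (!all(need %in% names(libs))) {
    .fail("library table needs columns: ", paste(need, collapse = ", "))
  }
  if ("uniquely_aligned" %in% names(libs) &&
      any(libs$after_dedup > libs$uniquely_aligned)) {
    .fail("after_dedup exceeds uniquely_aligned")
  }
  libs$pct_unique_nondup <- percent_unique_nondup(libs$read_pairs,
                                                  libs$after_dedup)
  libs$pct_to_keep <- downsample_fraction(libs$after_dedup, target)
  libs
}

#' Midpoint of a read-extension range
#'
#' Peak callers that accept a single read extension length rather than a
#' range are given the midpoint of the observed fragment-size range:
#' `min + (max - min) / 2`.
#'
#' @param min_frag,max_frag fragment-size range in bp (`min_frag <=
#'   max_frag`).
#' @return midpoint in bp.
#' @examples
#' extension_midpoint(200, 2000)  # 1100
#' @export
extension_midpoint <- function(min_frag, max_frag) {
  if (any(min_frag > max_frag)) .fail("min_frag > max_frag")
  min_frag + (max_frag - min_frag) / 2
}

#' Library amplification cycle number from a qPCR curve
#'
#' Selects the number of PCR cycles for library amplification from a qPCR
#' amplification curve, picking a cycle during the exponential phase so the
#' library is neither under- nor over-amplified. Two readings of the
#' "one third" rule are provided:
#' \describe{
#'   \item{`"plateau"` (default)}{the smallest measured cycle whose
#'     fluorescence reaches one third of the plateau fluorescence. The
#'     plateau is estimated as the mean fluorescence over the trailing
#'     cycles whose slope has fallen below `plateau_tol` of the maximum
#'     slope.}
#'   \item{`"slope"`}{the first cycle reached by a per-cycle slope of at
#'     least one third of the maximum slope.}
#' }
#' Both are invariant to uniform scaling of the fluorescence. A curve that
#' never flattens (no trailing slope below `plateau_tol` of the maximum,
#' or no rise at all) is rejected.
#'
#' @param cycles strictly increasing integer cycle numbers (>= 5 points).
#' @param fluorescence non-negative fluorescence readings, same length.
#' @param method `"plateau"` or `"slope"` (see above).
#' @param plateau_tol slope fraction below which the curve counts as flat.
#' @return the selected cycle number (integer).
#' @export
amplification_cycles <- function(cycles, fluorescence,
                                 method = c("plateau", "slope"),
                                 plateau_tol = 0.05) {
  method <- match.arg(method)
  if (length(cycles) < 5L) .fail("qPCR curve needs at least 5 points")
  if (length(cycles) != length(fluorescence)) {
    .fail("cycles and fluorescence differ in length")
  }
  if (any(diff(cycles) <= 0)) .fail("cycles must be strictly increasing")
  if (any(fluorescence < 0)) .fail("fluorescence must be non-negative")
  slopes <- diff(fluorescence) / diff(cycles)
  mx <- max(slopes)
  if (mx <= 0) .fail("no plateau detected: curve never rises")
  flat <- slopes < plateau_tol * mx
  if (!flat[length(flat)]) {
    .fail("no plateau detected: curve still rising at the last cycle")
  }
  if (method == "slope") {
    i <- which(slopes >= mx / 3)[1L]
    return(as.integer(cycles[i + 1L]))
  }
  last_steep <- max(which(!flat))          # guaranteed non-empty: mx slope
  plateau_level <- mean(fluorescence[(last_steep + 1L):length(fluorescence)])
  i <- which(fluorescence >= plateau_level / 3)[1L]
  if (is.na(i)) .fail("fluorescence never reaches a third of the plateau")
  as.integer(cycles[i])
}
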