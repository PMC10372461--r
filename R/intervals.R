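# Interval algebra: merge-with-gap, complement, fractional-overlap
# intersection. All operations assume (and verify) sorted input and run in
# O(n log n) via grouped cummax / findInterval lookups.

#' Merge peaks separated by at most a given gap
#'
#' Two intervals on the same chromosome are merged when the uncovered
#' distance between them (`next start - previous end`) is at most `gap`
#' base pairs; overlapping or touching intervals always merge. The default
#' of 150 bp is the length of DNA wrapped in one nucleosome: gaps between
#' called peaks shorter than a nucleosome are not biologically meaningful.
#' `gap = 0` normalizes a peak set (merges overlapping/touching intervals
#' only). A distance of exactly `gap` merges.
#'
#' @param peaks a sorted [peak_set()].
#' @param gap maximum uncovered distance in bp (>= 0) across which to merge.
#' @return a sorted, non-overlapping [peak_set()]; the count never exceeds
#'   the input count. Merging is idempotent.
#' @examples
#' gl <- genome_layout("c1", 1000)
#' p <- peak_set("c1", c(100, 350), c(200, 400), layout = gl)
#' as.data.frame(merge_adjacent(p, gap = 150))  # one interval [100, 400)
#' @export
merge_adjacent <- function(peaks, gap = 150) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!is.numeric(gap) || length(gap) != 1L || is.na(gap) || gap < 0) {
    .fail("gap must be a single non-negative number")
  }
  if (!is_sorted_peaks(peaks)) .fail("merge_adjacent requires sorted input")
  df <- peaks$intervals
  n <- nrow(df)
  if (n < 2L) return(peaks)
  out <- lapply(split(df[c("start", "end")], factor(df$chrom, unique(df$chrom))),
                function(d) {
    cm <- cummax(d$end)
    newgrp <- c(TRUE, d$start[-1L] - cm[-nrow(d)] > gap)
    g <- cumsum(newgrp)
    data.frame(start = d$start[newgrp],
               end = as.numeric(tapply(d$end, g, max)))
  })
  chrom <- rep(unique(df$chrom), vapply(out, nrow, 0L))
  merged <- do.call(rbind, out)
  peak_set(chrom, merged$start, merged$end, label = peaks$label,
           layout = peaks$genome)
}

#' Complement of a peak set
#'
#' Per chromosome, the maximal intervals of `[0, length)` not covered by any
#' peak (the regions-without-peaks used to count true negatives).
#' Chromosomes with no peaks contribute one full-length interval. Input is
#' normalized internally with `merge_adjacent(gap = 0)`.
#'
#' @param peaks a [peak_set()].
#' @param layout a [genome_layout()]; defaults to the layout stored in
#'   `peaks`.
#' @return a [peak_set()] of uncovered regions. For any `X`,
#'   `total_bp(normalized X) + total_bp(complement(X))` equals the genome
#'   size, and `complement(complement(X))` equals the normalized `X`.
#' @export
complement_peaks <- function(peaks, layout = peaks$genome) {
  stopifnot(inherits(peaks, "peak_set"))
  if (is.null(layout)) .fail("complement requires a genome layout")
  stopifnot(inherits(layout, "genome_layout"))
  norm <- merge_adjacent(peaks, 0)
  df <- norm$intervals
  chroms <- character()
  starts <- numeric()
  ends <- numeric()
  for (i in seq_len(nrow(layout))) {
    nm <- layout$name[i]
    len <- layout$length[i]
    d <- df[df$chrom == nm, , drop = FALSE]
    s <- c(0, d$end)
    e <- c(d$start, len)
    keep <- s < e
    chroms <- c(chroms, rep(nm, sum(keep)))
    starts <- c(starts, s[keep])
    ends <- c(ends, e[keep])
  }
  peak_set(chroms, starts, ends,
           label = paste0("complement(", peaks$label, ")"), layout = layout)
}

# Base pairs of [qs, qe) covered by a merged (disjoint, sorted) interval set
# given as vectors rs/re on ONE chromosome. Vectorized over queries.
covered_in_chrom <- function(qs, qe, rs, re) {
  if (length(rs) == 0L) return(numeric(length(qs)))
  cw <- cumsum(re - rs)
  before <- function(x) {
    j <- findInterval(x, rs)
    out <- numeric(length(x))
    hit <- j > 0L
    out[hit] <- cw[j[hit]] - pmax(0, re[j[hit]] - x[hit])
    out
  }
  before(qe) - before(qs)
}

# covered bp per query interval against a normalized reference, all
# chromosomes; q and r are interval data.frames
covered_bp <- function(q, r) {
  out <- numeric(nrow(q))
  for (nm in unique(q$chrom)) {
    qi <- which(q$chrom == nm)
    ri <- r$chrom == nm
    out[qi] <- covered_in_chrom(q$start[qi], q$end[qi],
                                r$start[ri], r$end[ri])
  }
  out
}

#' Split a query peak set into reference hits and misses by overlap fraction
#'
#' A query interval is a *hit* when the total base pairs it shares with the
#' reference set (coverage union across all reference intervals) is at least
#' `min_fraction` of its own length; each query interval is counted once no
#' matter how many reference intervals it touches. The default 0.20
#' reproduces a BEDTools `intersect -f 0.20` call; an overlap of exactly
#' `min_fraction` counts as a hit.
#'
#' @param query,reference sorted [peak_set()]s.
#' @param min_fraction required overlap as a fraction of the query
#'   interval's length, in (0, 1].
#' @param reciprocal when `TRUE`, a hit additionally requires a single
#'   reference interval whose pairwise overlap is also at least
#'   `min_fraction` of that reference interval's length (BEDTools `-r`).
#' @return a list with sorted [peak_set()]s `hits` and `misses`;
#'   their union is the query set and they are disjoint.
#' @export
intersect_fraction <- function(query, reference, min_fraction = 0.20,
                               reciprocal = FALSE) {
  stopifnot(inherits(query, "peak_set"), inherits(reference, "peak_set"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      is.na(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    .fail("min_fraction must be in (0, 1]")
  }
  if (!is_sorted_peaks(query) || !is_sorted_peaks(reference)) {
    .fail("intersect_fraction requires sorted input")
  }
  q <- query$intervals
  rmerged <- merge_adjacent(reference, 0)$intervals
  width <- q$end - q$start
  cov <- covered_bp(q, rmerged)
  hit <- cov + 1e-9 >= min_fraction * width
  if (reciprocal && any(hit)) {
    rraw <- reference$intervals
    for (i in which(hit)) {
      ri <- which(rraw$chrom == q$chrom[i] & rraw$start < q$end[i] &
                    rraw$end > q$start[i])
      ok <- FALSE
      for (j in ri) {
        ov <- min(q$end[i], rraw$end[j]) - max(q$start[i], rraw$start[j])
        if (ov + 1e-9 >= min_fraction * width[i] &&
            ov + 1e-9 >= min_fraction * (rraw$end[j] - rraw$start[j])) {
          ok <- TRUE
          break
        }
      }
      hit[i] <- ok
    }
  }
  mk <- function(idx, suffix) {
    peak_set(q$chrom[idx], q$start[idx], q$end[idx],
             label = paste0(query$label, suffix), layout = query$genome)
  }
  list(hits = mk(hit, " hits"), misses = mk(!hit, " misses"))
}
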