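# Interval-level confusion matrix against a reference peak set, the derived
# sensitivity/specificity/PPV, and the optimal input amount located as the
# intersection of the two curves on a log cell-number axis.

#' Interval-level confusion counts against a reference peak set
#'
#' Counts true/false positives and true negatives for a query peak call
#' benchmarked against a trusted reference call:
#' \itemize{
#'   \item TP: query intervals overlapping the reference at >=
#'     `min_fraction` of their own length (see [intersect_fraction()]);
#'   \item FP: the remaining query intervals (so TP + FP = query count);
#'   \item TN: intervals of `complement(reference)` overlapping
#'     `complement(query)` at the same fraction of their own length.
#' }
#' The positives denominator used for sensitivity is the *reference* peak
#' count. Note the deliberate asymmetry: TP is counted on the query side, so
#' sensitivity can exceed 1 when a query fragments reference peaks; set
#' `tp_side = "reference"` to count TP on the reference side instead
#' (guaranteeing sensitivity <= 1).
#'
#' Both inputs are expected to be merged already (the benchmark merges peaks
#' closer than a nucleosome first, see [merge_adjacent()]); they are
#' normalized internally with `gap = 0`, which leaves merged sets unchanged.
#'
#' @param query,reference [peak_set()]s for the condition under test and the
#'   trusted reference.
#' @param layout a [genome_layout()] (needed for the complements).
#' @param min_fraction required overlap fraction, default 0.20.
#' @param tp_side side on which true positives are counted; `"query"` is the
#'   benchmark's published arithmetic.
#' @return an object of class `confusion_counts` with fields `query_peaks`,
#'   `reference_peaks`, `true_positives`, `false_positives`,
#'   `true_negatives`.
#' @export
confusion_counts <- function(query, reference, layout = query$genome,
                             min_fraction = 0.20,
                             tp_side = c("query", "reference")) {
  stopifnot(inherits(query, "peak_set"), inherits(reference, "peak_set"))
  tp_side <- match.arg(tp_side)
  if (is.null(layout)) .fail("confusion_counts requires a genome layout")
  if (n_peaks(reference) == 0L) {
    .fail("no positives defined: reference peak set is empty")
  }
  qn <- merge_adjacent(query, 0)
  rn <- merge_adjacent(reference, 0)
  split_q <- intersect_fraction(qn, rn, min_fraction)
  fp <- n_peaks(split_q$misses)
  tp <- if (tp_side == "query") {
    n_peaks(split_q$hits)
  } else {
    n_peaks(intersect_fraction(rn, qn, min_fraction)$hits)
  }
  cq <- complement_peaks(qn, layout)
  cr <- complement_peaks(rn, layout)
  tn <- n_peaks(intersect_fraction(cr, cq, min_fraction)$hits)
  out <- structure(
    list(query_peaks = n_peaks(qn), reference_peaks = n_peaks(rn),
         true_positives = tp, false_positives = fp, true_negatives = tn,
         min_fraction = min_fraction, tp_side = tp_side,
         query_label = qn$label, reference_label = rn$label),
    class = "confusion_counts"
  )
  if (tp_side == "query" &&
      out$true_positives + out$false_positives != out$query_peaks) {
    .fail("internal error: TP + FP != query peak count")  # invariant
  }
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(paste0("confusion counts ('%s' vs reference '%s', f = %g):\n",
                     "  query peaks %d | reference peaks %d | TP %d | FP %d | TN %d\n"),
              x$query_label, x$reference_label, x$min_fraction,
              x$query_peaks, x$reference_peaks, x$true_positives,
              x$false_positives, x$true_negatives))
  invisible(x)
}

#' Sensitivity, specificity and PPV from confusion counts
#'
#' `sensitivity = TP / reference peaks`, `specificity = TN / (TN + FP)`,
#' `PPV = TP / (TP + FP)`. Full precision is retained; the print method
#' rounds to 2 decimals (half-up), the convention of published benchmark
#' tables. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param counts a [confusion_counts()] object, or a list with fields
#'   `true_positives`, `false_positives`, `true_negatives`,
#'   `reference_peaks`.
#' @return an object of class `concordance_metrics` with fields
#'   `sensitivity`, `specificity`, `ppv`.
#' @export
concordance_metrics <- function(counts) {
  tp <- counts$true_positives
  fp <- counts$false_positives
  tn <- counts$true_negatives
  ref <- counts$reference_peaks
  stopifnot(is.numeric(tp), is.numeric(fp), is.numeric(tn), is.numeric(ref))
  if (any(c(tp, fp, tn, ref) < 0)) .fail("confusion counts must be >= 0")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(sensitivity = div(tp, ref),
         specificity = div(tn, tn + fp),
         ppv = div(tp, tp + fp)),
    class = "concordance_metrics"
  )
}

#' @export
print.concordance_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", round_half_up(v, 2))
  cat("sensitivity ", fmt(x$sensitivity), "  specificity ", fmt(x$specificity),
      "  PPV ", fmt(x$ppv), "\n", sep = "")
  invisible(x)
}

#' Benchmark one or more query peak sets against a reference
#'
#' Convenience wrapper producing one row per condition in the published
#' benchmark-table format: peaks are merged with [merge_adjacent()], the
#' confusion matrix is built with [confusion_counts()], and the metrics are
#' rounded to two decimals (half-up). The reference's self-comparison row is
#' included first (it should read sensitivity = specificity = 1.00).
#'
#' @param queries a named list of [peak_set()]s, one per condition.
#' @param reference the reference [peak_set()].
#' @param layout a [genome_layout()].
#' @param cells optional numeric vector of input cell numbers, one per query
#'   condition (appears as a column and feeds [optimum_cell_number()]).
#' @param gap merge distance in bp applied to every set first.
#' @param min_fraction overlap fraction for [confusion_counts()].
#' @param self_row include the reference-vs-reference row.
#' @return a data frame with columns `sample`, (optional `cells`),
#'   `Peaks (positives)`, `true positives`, `false positives`,
#'   `true negatives`, `sensitivity`, `specificity`, `PPV`. Unrounded
#'   metrics are attached as attribute `"metrics"`.
#' @export
concordance_table <- function(queries, reference, layout,
                              cells = NULL, gap = 150, min_fraction = 0.20,
                              self_row = TRUE) {
  if (inherits(queries, "peak_set")) queries <- list(queries)
  if (is.null(names(queries))) {
    names(queries) <- vapply(queries, function(p) p$label, "")
  }
  if (!is.null(cells) && length(cells) != length(queries)) {
    .fail("cells must have one entry per query condition")
  }
  refm <- merge_adjacent(reference, gap)
  rows <- list()
  full <- list()
  add_row <- function(sample, cc, cell) {
    m <- concordance_metrics(cc)
    full[[sample]] <<- m
    rows[[length(rows) + 1L]] <<- data.frame(
      sample = sample,
      cells = if (is.null(cells)) NA_real_ else cell,
      `Peaks (positives)` = cc$query_peaks,
      `true positives` = cc$true_positives,
      `false positives` = cc$false_positives,
      `true negatives` = cc$true_negatives,
      sensitivity = round_half_up(m$sensitivity, 2),
      specificity = round_half_up(m$specificity, 2),
      PPV = round_half_up(m$ppv, 2),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  if (self_row) {
    add_row(refm$label, confusion_counts(refm, refm, layout, min_fraction),
            NA_real_)
  }
  for (i in seq_along(queries)) {
    qm <- merge_adjacent(queries[[i]], gap)
    add_row(names(queries)[i], confusion_counts(qm, refm, layout, min_fraction),
            if (is.null(cells)) NA_real_ else cells[i])
  }
  out <- do.call(rbind, rows)
  if (is.null(cells)) out$cells <- NULL
  attr(out, "metrics") <- full
  out
}

# linear interpolation helpers on d(x) = sensitivity - specificity
.seg_region <- function(x1, x2, d1, d2, tol) {
  # sub-interval of [x1, x2] where |d| <= tol; NULL when empty
  if (d1 == d2) {
    if (abs(d1) <= tol) return(c(x1, x2)) else return(NULL)
  }
  m <- (d2 - d1) / (x2 - x1)
  xa <- x1 + (-tol - d1) / m
  xb <- x1 + (tol - d1) / m
  lo <- max(x1, min(xa, xb))
  hi <- min(x2, max(xa, xb))
  if (lo > hi) NULL else c(lo, hi)
}

#' Locate the optimal cell number as the sensitivity/specificity crossing
#'
#' Benchmarks of input titrations trade sensitivity (rises with more cells)
#' against specificity (falls as extra peaks appear); the intersection of
#' the two curves as a function of the optimization parameter is
#' conventionally taken as the optimum. Both curves are interpolated
#' piecewise-linearly in `log10(cells)` (cell numbers span several orders
#' of magnitude). The crossing is solved within the highest segment that
#' contains a sign change of `sensitivity - specificity`; the plateau is the
#' maximal connected range around the crossing where the two curves differ
#' by at most `tolerance`, reported rounded to 2 significant figures.
#'
#' @param series a data frame with numeric columns `cells` (strictly
#'   increasing, >= 2 rows), `sensitivity` and `specificity`.
#' @param tolerance maximum |sensitivity - specificity| defining the
#'   plateau.
#' @return an object of class `optimum_estimate` with fields
#'   `crossing_cells` (NA when the curves never cross), `plateau`
#'   (`c(low, high)` in cells, NA when no crossing) and `tolerance`.
#'   When present, `plateau[1] <= crossing_cells <= plateau[2]`.
#' @examples
#' s <- data.frame(cells = c(1e3, 1e4, 1e6),
#'                 sensitivity = c(0.39, 0.78, 0.94),
#'                 specificity = c(0.90, 0.90, 0.88))
#' optimum_cell_number(s)
#' @export
optimum_cell_number <- function(series, tolerance = 0.02) {
  stopifnot(is.data.frame(series))
  need <- c("cells", "sensitivity", "specificity")
  if (!all(need %in% names(series))) {
    .fail("series needs columns: ", paste(need, collapse = ", "))
  }
  series <- series[order(series$cells), , drop = FALSE]
  n <- nrow(series)
  if (n < 2L) .fail("optimum finding needs at least 2 points")
  if (any(diff(series$cells) <= 0)) .fail("cells must be strictly increasing")
  if (any(!is.finite(series$sensitivity)) || any(!is.finite(series$specificity))) {
    .fail("sensitivity/specificity must be finite")
  }
  x <- log10(series$cells)
  d <- series$sensitivity - series$specificity
  none <- structure(list(crossing_cells = NA_real_, plateau = NULL,
                         tolerance = tolerance, log10_crossing = NA_real_),
                    class = "optimum_estimate")
  if (all(d == 0)) {
    # degenerate: curves identical; crossing at the smallest cell number
    return(structure(list(crossing_cells = series$cells[1L],
                          plateau = c(low = signif(series$cells[1L], 2),
                                      high = signif(series$cells[n], 2)),
                          tolerance = tolerance, log10_crossing = x[1L]),
                     class = "optimum_estimate"))
  }
  segs <- which((d[-n] <= 0 & d[-1L] >= 0) | (d[-n] >= 0 & d[-1L] <= 0))
  if (length(segs) == 0L) return(none)
  i <- max(segs)
  x_star <- if (d[i + 1L] == d[i]) x[i] else {
    x[i] - d[i] * (x[i + 1L] - x[i]) / (d[i + 1L] - d[i])
  }
  # plateau: connected component of {|d| <= tol} containing the crossing
  reg <- .seg_region(x[i], x[i + 1L], d[i], d[i + 1L], tolerance)
  lo <- reg[1L]
  hi <- reg[2L]
  eps <- 1e-9
  k <- i - 1L
  while (k >= 1L && lo <= x[k + 1L] + eps) {
    r <- .seg_region(x[k], x[k + 1L], d[k], d[k + 1L], tolerance)
    if (is.null(r) || r[2L] < x[k + 1L] - eps) break
    lo <- r[1L]
    if (lo > x[k] + eps) break
    k <- k - 1L
  }
  k <- i + 1L
  while (k <= n - 1L && hi >= x[k] - eps) {
    r <- .seg_region(x[k], x[k + 1L], d[k], d[k + 1L], tolerance)
    if (is.null(r) || r[1L] > x[k] + eps) break
    hi <- r[2L]
    if (hi < x[k + 1L] - eps) break
    k <- k + 1L
  }
  structure(
    list(crossing_cells = 10^x_star,
         plateau = c(low = signif(10^lo, 2), high = signif(10^hi, 2)),
         tolerance = tolerance, log10_crossing = x_star),
    class = "optimum_estimate"
  )
}

#' @export
print.optimum_estimate <- function(x, ...) {
  if (is.na(x$crossing_cells)) {
    cat("no sensitivity/specificity crossing\n")
  } else {
    cat(sprintf("crossing at %s cells (plateau %s - %s at |sens - spec| <= %g)\n",
                format(signif(x$crossing_cells, 3), big.mark = ","),
                format(x$plateau[1L], big.mark = ",", scientific = FALSE),
                format(x$plateau[2L], big.mark = ",", scientific = FALSE),
                x$tolerance))
  }
  invisible(x)
}
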