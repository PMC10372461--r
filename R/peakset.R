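# PeakSet: sorted, validated genomic intervals for one condition.
# Coordinates are 0-based half-open throughout (BED convention).

#' Construct a peak set
#'
#' A peak set is a collection of genomic intervals (peaks) for one
#' condition, kept sorted by (chromosome rank, start, end). Coordinates are
#' 0-based half-open as in BED: a peak `[start, end)` covers `end - start`
#' base pairs. Zero-length intervals are rejected.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval bounds (start < end).
#' @param label condition label carried through to outputs (e.g. "C1 merged").
#' @param layout optional [genome_layout()]; when supplied, chromosome names
#'   and bounds are validated against it and its order is used for sorting.
#' @return an object of class `peak_set`.
#' @examples
#' gl <- genome_layout("c1", 1000)
#' peak_set("c1", c(100, 400), c(200, 500), label = "demo", layout = gl)
#' @export
peak_set <- function(chrom = character(), start = numeric(), end = numeric(),
                     label = "", layout = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n) {
    .fail("chrom, start, end must have equal length")
  }
  if (n > 0L) {
    if (!all(is_wholenumber(start)) || !all(is_wholenumber(end))) {
      .fail("interval bounds must be integers")
    }
    if (any(start < 0)) .fail("negative start coordinate")
    bad <- which(start >= end)
    if (length(bad)) {
      .fail("start >= end for interval ", chrom[bad[1L]], ":",
            start[bad[1L]], "-", end[bad[1L]])
    }
  }
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "genome_layout"))
    r <- chrom_rank(chrom, layout)
    if (anyNA(r)) {
      .fail("unknown chromosome '", chrom[which(is.na(r))[1L]],
            "' not in genome layout")
    }
    too_far <- which(end > layout$length[r])
    if (length(too_far)) {
      i <- too_far[1L]
      .fail("interval ", chrom[i], ":", start[i], "-", end[i],
            " exceeds chromosome length ", layout$length[r[i]])
    }
    o <- order(r, start, end)
  } else {
    o <- order(chrom, start, end)
  }
  structure(
    list(
      intervals = data.frame(chrom = chrom[o], start = start[o], end = end[o],
                             stringsAsFactors = FALSE),
      label = as.character(label)[1L],
      genome = layout
    ),
    class = "peak_set"
  )
}

#' Number of peaks in a peak set
#' @param peaks a [peak_set()].
#' @return integer count.
#' @export
n_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  nrow(peaks$intervals)
}

#' Total base pairs in a peak set
#'
#' Sum of interval widths. Overlapping intervals are counted once only if
#' the set has been normalized (see [merge_adjacent()] with `gap = 0`).
#'
#' @param peaks a [peak_set()].
#' @return base pairs.
#' @export
total_bp <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  sum(peaks$intervals$end - peaks$intervals$start)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak set", if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
      ": ", n_peaks(x), " interval(s), ",
      format(total_bp(x), big.mark = ","), " bp\n", sep = "")
  if (n_peaks(x) > 0L) {
    print(utils::head(x$intervals, 6L), row.names = FALSE)
    if (n_peaks(x) > 6L) cat("...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.peak_set <- function(x, ...) x$intervals

# TRUE when intervals are sorted by (chrom rank, start, end)
is_sorted_peaks <- function(peaks) {
  df <- peaks$intervals
  if (nrow(df) < 2L) return(TRUE)
  r <- if (!is.null(peaks$genome)) chrom_rank(df$chrom, peaks$genome)
       else match(df$chrom, unique(df$chrom))
  key_prev <- seq_len(nrow(df) - 1L)
  ok_chrom <- r[key_prev] <= r[key_prev + 1L]
  same <- r[key_prev] == r[key_prev + 1L]
  ok_start <- !same | df$start[key_prev] <= df$start[key_prev + 1L]
  all(ok_chrom & ok_start)
}

bed_skip_pattern <- "^(#|track([ \t]|$)|browser([ \t]|$))"

#' Read a BED file of peaks
#'
#' Reads BED3+ (tab- or space-separated); columns beyond the third are
#' ignored. Lines starting with `#`, `track` or `browser` are skipped. A
#' header comment of the form `# label: <text>` written by [write_bed()]
#' restores the condition label. Intervals are validated against the layout
#' and returned sorted.
#'
#' @param path path to a BED file.
#' @param layout a [genome_layout()] defining the coordinate universe.
#' @param label condition label; defaults to the label stored in the file
#'   header, or the file name.
#' @return a sorted, validated [peak_set()].
#' @export
read_bed <- function(path, layout, label = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!file.exists(path)) .fail("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  file_label <- sub("^#[ \t]*label:[ \t]*", "",
                    grep("^#[ \t]*label:", lines, value = TRUE))
  skip <- grepl(bed_skip_pattern, lines) | grepl("^\\s*$", lines)
  body <- lines[!skip]
  lineno <- which(!skip)
  if (is.null(label)) {
    label <- if (length(file_label)) file_label[1L] else basename(path)
  }
  if (length(body) == 0L) {
    return(peak_set(label = label, layout = layout))
  }
  parts <- strsplit(body, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1L]
    .fail(path, " line ", lineno[i], ": fewer than 3 BED columns")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    .fail(path, " line ", lineno[bad[1L]], ": non-numeric coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    .fail(path, " line ", lineno[bad[1L]], ": start >= end")
  }
  r <- chrom_rank(chrom, layout)
  if (anyNA(r)) {
    i <- which(is.na(r))[1L]
    .fail(path, " line ", lineno[i], ": unknown chromosome '", chrom[i], "'")
  }
  bad <- which(start < 0 | end > layout$length[r])
  if (length(bad)) {
    .fail(path, " line ", lineno[bad[1L]], ": interval outside chromosome")
  }
  peak_set(chrom, start, end, label = label, layout = layout)
}

#' Write a peak set as BED3
#'
#' Writes a sorted peak set as plain BED3 with the condition label in a
#' track-less comment header, so that a write/read cycle restores an
#' identical peak set.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  df <- peaks$intervals
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# label: ", peaks$label), con)
  if (nrow(df) > 0L) {
    writeLines(sprintf("%s\t%s\t%s", df$chrom,
                       format(df$start, scientific = FALSE, trim = TRUE),
                       format(df$end, scientific = FALSE, trim = TRUE)),
               con)
  }
  invisible(path)
}

#' Read a gene annotation (BED6)
#'
#' Minimal strand-aware gene model reader: BED with at least 3 columns;
#' column 4 (name) and column 6 (strand) are used when present. Genes with
#' no strand column default to `+`.
#'
#' @param path path to a BED6 (or BED3/BED4) file.
#' @param layout a [genome_layout()].
#' @return a data frame with columns `chrom`, `start`, `end`, `strand`, `id`.
#' @export
read_genes <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!file.exists(path)) .fail("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  skip <- grepl(bed_skip_pattern, lines) | grepl("^\\s*$", lines)
  body <- lines[!skip]
  lineno <- which(!skip)
  if (length(body) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), id = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    .fail(path, " line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 columns")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  id <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))], ""),
               sprintf("gene%05d", seq_along(parts)))
  strand <- ifelse(nf >= 6L, vapply(parts, function(p) p[min(6L, length(p))], ""),
                   "+")
  if (any(is.na(start) | is.na(end) | start >= end)) {
    .fail(path, ": malformed gene coordinates")
  }
  if (!all(strand %in% c("+", "-"))) {
    .fail(path, ": strand must be '+' or '-'")
  }
  r <- chrom_rank(chrom, layout)
  if (anyNA(r)) {
    .fail(path, ": unknown chromosome '", chrom[which(is.na(r))[1L]], "'")
  }
  if (any(start < 0 | end > layout$length[r])) {
    .fail(path, ": gene outside chromosome bounds")
  }
  o <- order(r, start, end)
  data.frame(chrom = chrom[o], start = start[o], end = end[o],
             strand = strand[o], id = id[o], stringsAsFactors = FALSE)
}

#' Write a gene annotation as BED6
#'
#' @param genes gene data frame as returned by [read_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s\t0\t%s", genes$chrom,
                     format(genes$start, scientific = FALSE, trim = TRUE),
                     format(genes$end, scientific = FALSE, trim = TRUE),
                     genes$id, genes$strand),
             path)
  invisible(path)
}
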