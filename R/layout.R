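# GenomeLayout: the ordered chromosome universe all coordinates live in.

#' Construct a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths that
#' defines the coordinate universe for every peak set. The order given here
#' is canonical: all peak sets are sorted by it and all outputs follow it.
#'
#' @param name character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in base pairs (> 0).
#' @return an object of class `genome_layout` (a data frame with columns
#'   `name` and `length`).
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(name, length) {
  name <- as.character(name)
  if (length(name) == 0L) .fail("no chromosomes")
  if (anyNA(name) || any(name == "")) .fail("chromosome names must be non-empty")
  if (anyDuplicated(name)) {
    .fail("duplicate chromosome name: ", name[duplicated(name)][1L])
  }
  if (length(name) != base::length(length)) {
    .fail("name and length differ in length")
  }
  if (!all(is_wholenumber(length)) || any(length <= 0)) {
    .fail("chromosome lengths must be positive integers")
  }
  structure(
    data.frame(name = name, length = as.numeric(length),
               stringsAsFactors = FALSE),
    class = c("genome_layout", "data.frame")
  )
}

#' Read a chrom.sizes file
#'
#' Parses the two-column tab-separated `chrom.sizes` format
#' (name, length). File order is preserved and becomes the canonical
#' chromosome order.
#'
#' @param path path to a chrom.sizes file.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) .fail("no chromosomes in ", path)
  parts <- strsplit(lines, "[ \t]+")
  nm <- character(length(parts))
  ln <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L) {
      .fail(path, " line ", lineno[i], ": expected two columns (name, length)")
    }
    val <- suppressWarnings(as.numeric(p[2L]))
    if (is.na(val) || !is_wholenumber(val) || val <= 0) {
      .fail(path, " line ", lineno[i], ": non-positive or non-integer length '",
            p[2L], "'")
    }
    nm[i] <- p[1L]
    ln[i] <- val
  }
  if (anyDuplicated(nm)) {
    bad <- nm[duplicated(nm)][1L]
    .fail(path, " line ", lineno[match(TRUE, duplicated(nm))],
          ": duplicate chromosome name '", bad, "'")
  }
  genome_layout(nm, ln)
}

#' Total genome size
#'
#' @param layout a [genome_layout()].
#' @return total length in base pairs.
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$length)
}

# rank of chromosomes in canonical order; NA for unknown names
chrom_rank <- function(chrom, layout) match(chrom, layout$name)

chrom_length <- function(chrom, layout) layout$length[chrom_rank(chrom, layout)]

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome layout:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a chrom.sizes file
#'
#' @param layout a [genome_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  writeLines(sprintf("%s\t%s", layout$name,
                     format(layout$length, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
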