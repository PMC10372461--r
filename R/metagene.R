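# Scaled metagene log(observed/expected) enrichment profiles, rank-sum
# comparison of profiles and RPKM summaries, and binned read-count
# correlation between libraries.

#' Sliding bin grid over a genome
#'
#' Half-open windows of `bin_size` bp tiled every `step_size` bp (default:
#' half a bin, the convention of HMM-based chromatin segmenters whose bin
#' size matches the peak caller's read extension length). Windows are
#' clipped at chromosome ends.
#'
#' @param layout a [genome_layout()].
#' @param bin_size window width in bp.
#' @param step_size distance between window starts in bp; default half the
#'   bin size.
#' @return an object of class `bin_grid`: a list with the window data frame
#'   (`bins`), `bin_size`, `step_size` and the layout.
#' @export
bin_grid <- function(layout, bin_size = 1000, step_size = bin_size / 2) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is_wholenumber(bin_size) || bin_size < 1) .fail("bin_size must be >= 1")
  if (!is_wholenumber(step_size) || step_size < 1 || step_size > bin_size) {
    .fail("step_size must be in [1, bin_size]")
  }
  per <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    s <- seq(0, max(0, len - 1), by = step_size)
    s <- s[s < len]
    data.frame(chrom = layout$name[i], start = s, end = pmin(s + bin_size, len),
               stringsAsFactors = FALSE)
  })
  structure(list(bins = do.call(rbind, per), bin_size = bin_size,
                 step_size = step_size, genome = layout),
            class = "bin_grid")
}

#' Per-bin read counts for one or more libraries
#'
#' @param grid a [bin_grid()].
#' @param counts numeric matrix (bins x libraries) or vector of
#'   non-negative counts aligned to `grid$bins`.
#' @param labels library labels (defaults to column names or `lib1`, ...).
#' @return an object of class `binned_counts`.
#' @export
binned_counts <- function(grid, counts, labels = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(grid$bins)) {
    .fail("counts rows (", nrow(counts), ") != number of bins (",
          nrow(grid$bins), ")")
  }
  if (any(counts < 0) || anyNA(counts)) .fail("counts must be non-negative")
  if (is.null(labels)) {
    labels <- colnames(counts)
    if (is.null(labels)) labels <- sprintf("lib%d", seq_len(ncol(counts)))
  }
  colnames(counts) <- labels
  structure(list(grid = grid, counts = counts, labels = labels),
            class = "binned_counts")
}

# per-bp signal value and cumulative sums for one chromosome of a
# binned_counts column; overlapping bins are averaged per bp
.chrom_signal_cums <- function(bins, counts, len) {
  num <- numeric(len + 1L)
  den <- numeric(len + 1L)
  w <- bins$end - bins$start
  # difference-array accumulation of count/width and of multiplicity
  for (i in seq_len(nrow(bins))) {
    num[bins$start[i] + 1L] <- num[bins$start[i] + 1L] + counts[i] / w[i]
    num[bins$end[i] + 1L] <- num[bins$end[i] + 1L] - counts[i] / w[i]
    den[bins$start[i] + 1L] <- den[bins$start[i] + 1L] + 1
    den[bins$end[i] + 1L] <- den[bins$end[i] + 1L] - 1
  }
  num <- cumsum(num)[seq_len(len)]
  den <- cumsum(den)[seq_len(len)]
  val <- ifelse(den > 0, num / den, 0)
  list(cs_val = c(0, cumsum(val)), cs_def = c(0, cumsum(den > 0)),
       total_val = sum(val), total_def = sum(den > 0))
}

# window boundaries for one metagene position across all genes (vectorized).
# Positions: flank_bins upstream, body_bins scaled gene-body, flank_bins
# downstream; minus-strand genes are mirrored so the axis reads TSS -> TES.
.metagene_windows <- function(genes, pos, flank, body_bins, flank_bins) {
  plus <- genes$strand == "+"
  len <- genes$end - genes$start
  f <- flank_bins
  b <- body_bins
  if (pos <= f) {                      # upstream flank, far to near
    a0 <- floor(flank * (f - pos + 1) / f)
    a1 <- floor(flank * (f - pos) / f)
    ws <- ifelse(plus, genes$start - a0, genes$end + a1)
    we <- ifelse(plus, genes$start - a1, genes$end + a0)
  } else if (pos <= f + b) {           # scaled gene body
    k <- pos - f
    lo <- floor(len * (k - 1) / b)
    hi <- floor(len * k / b)
    ws <- ifelse(plus, genes$start + lo, genes$end - hi)
    we <- ifelse(plus, genes$start + hi, genes$end - lo)
  } else {                             # downstream flank, near to far
    k <- pos - f - b
    a0 <- floor(flank * (k - 1) / f)
    a1 <- floor(flank * k / f)
    ws <- ifelse(plus, genes$end + a0, genes$start - a1)
    we <- ifelse(plus, genes$end + a1, genes$start - a0)
  }
  data.frame(chrom = genes$chrom, start = ws, end = we,
             stringsAsFactors = FALSE)
}

#' Scaled metagene enrichment profile
#'
#' Computes a log(observed/expected) occupancy profile over a scaled gene
#' model: `flank_bins` windows across an upstream flank of `flank` bp, then
#' `body_bins` windows dividing each gene body (TSS to TES) into equal
#' parts, then `flank_bins` downstream windows. Minus-strand genes are
#' mirrored so the axis always reads upstream -> TSS -> TES -> downstream.
#'
#' For a [peak_set()] signal, the observed value at a position is the
#' fraction of genes whose window overlaps a peak by at least 1 bp and the
#' expected value is the fraction of the genome covered by peaks. For a
#' [binned_counts()] signal, observed is the mean per-base signal across
#' gene windows and expected is the genome-wide mean per-base signal.
#' Enrichment is the natural log of observed/expected; positions with
#' observed = 0 are reported as `NA` (missing), never `-Inf`. Windows
#' clipped away entirely at chromosome ends do not contribute.
#'
#' @param signal a [peak_set()] or a [binned_counts()] object.
#' @param genes gene data frame (`chrom`, `start`, `end`, `strand`, `id`);
#'   genes shorter than `body_bins` bp are dropped with a message.
#' @param layout a [genome_layout()].
#' @param flank flank length in bp on each side.
#' @param body_bins number of scaled windows across the gene body.
#' @param flank_bins number of windows across each flank.
#' @param library for `binned_counts` signal, the library column (index or
#'   label) to profile.
#' @return an object of class `metagene_profile`: a list with `profile`
#'   (data frame of `position`, `region`, `observed`, `expected`,
#'   `enrichment`), `n_genes` used, `n_dropped`, and the geometry
#'   parameters.
#' @export
occupancy_profile <- function(signal, genes, layout, flank = 5000,
                              body_bins = 50, flank_bins = 25, library = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.data.frame(genes) || nrow(genes) == 0L) {
    .fail("empty gene list")
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(genes)))
  short <- (genes$end - genes$start) < body_bins
  if (any(short)) {
    message(sum(short), " gene(s) shorter than ", body_bins, " bp dropped")
    genes <- genes[!short, , drop = FALSE]
  }
  if (nrow(genes) == 0L) .fail("no genes left after length filtering")
  npos <- 2L * flank_bins + body_bins
  positions <- c(sprintf("u%02d", flank_bins:1),
                 sprintf("b%02d", seq_len(body_bins)),
                 sprintf("d%02d", seq_len(flank_bins)))
  region <- c(rep("upstream", flank_bins), rep("body", body_bins),
              rep("downstream", flank_bins))

  if (inherits(signal, "peak_set")) {
    merged <- merge_adjacent(signal, 0)$intervals
    expected <- sum(merged$end - merged$start) / genome_size(layout)
    window_obs <- function(win) {
      # clip at chromosome ends; drop windows with no remaining width
      lenc <- chrom_length(win$chrom, layout)
      s <- pmax(0, win$start)
      e <- pmin(lenc, win$end)
      ok <- s < e
      if (!any(ok)) return(NA_real_)
      cov <- covered_bp(data.frame(chrom = win$chrom[ok], start = s[ok],
                                   end = e[ok], stringsAsFactors = FALSE),
                        merged)
      mean(cov > 0)
    }
  } else if (inherits(signal, "binned_counts")) {
    cnt <- signal$counts[, library]
    bins <- signal$grid$bins
    cums <- list()
    tot_val <- 0
    tot_def <- 0
    for (i in seq_len(nrow(layout))) {
      nm <- layout$name[i]
      cc <- .chrom_signal_cums(bins[bins$chrom == nm, , drop = FALSE],
                               cnt[bins$chrom == nm], layout$length[i])
      cums[[nm]] <- cc
      tot_val <- tot_val + cc$total_val
      tot_def <- tot_def + cc$total_def
    }
    expected <- if (tot_def > 0) tot_val / tot_def else 0
    window_obs <- function(win) {
      lenc <- chrom_length(win$chrom, layout)
      s <- pmax(0, win$start)
      e <- pmin(lenc, win$end)
      ok <- s < e
      if (!any(ok)) return(NA_real_)
      vals <- numeric(sum(ok))
      idx <- which(ok)
      for (j in seq_along(idx)) {
        cc <- cums[[win$chrom[idx[j]]]]
        a <- s[idx[j]]
        bnd <- e[idx[j]]
        ndef <- cc$cs_def[bnd + 1L] - cc$cs_def[a + 1L]
        vals[j] <- if (ndef > 0) {
          (cc$cs_val[bnd + 1L] - cc$cs_val[a + 1L]) / ndef
        } else 0
      }
      mean(vals)
    }
  } else {
    .fail("signal must be a peak_set or binned_counts")
  }

  observed <- vapply(seq_len(npos), function(p) {
    window_obs(.metagene_windows(genes, p, flank, body_bins, flank_bins))
  }, 0)
  enrichment <- ifelse(!is.na(observed) & observed > 0 & expected > 0,
                       log(observed / expected), NA_real_)
  structure(
    list(profile = data.frame(position = positions, region = region,
                              observed = observed, expected = expected,
                              enrichment = enrichment,
                              stringsAsFactors = FALSE),
         n_genes = nrow(genes), n_dropped = sum(short),
         flank = flank, body_bins = body_bins, flank_bins = flank_bins,
         tss_index = flank_bins + 1L, tes_index = flank_bins + body_bins),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  fin <- sum(is.finite(x$profile$enrichment))
  cat(sprintf(paste0("metagene profile: %d genes, %d positions ",
                     "(%d finite), flank %d bp, %d body bins\n"),
              x$n_genes, nrow(x$profile), fin, x$flank, x$body_bins))
  invisible(x)
}

# shared rank-sum core; exact when small and tie-free (stats::wilcox.test
# default), otherwise normal approximation with tie correction
.rank_sum <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          n = c(length(a), length(b)),
                          note = "fewer than 3 finite values on one side"),
                     class = "rank_sum_result"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = c(length(a), length(b)), note = NULL),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  if (is.na(x$p_value)) {
    cat("rank-sum: undefined (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf("rank-sum W = %g, p = %.4g (n = %d vs %d)\n",
                x$statistic, x$p_value, x$n[1L], x$n[2L]))
  }
  invisible(x)
}

#' Compare two metagene profiles with a rank-sum test
#'
#' Two-sided unpaired Wilcoxon rank-sum test on the vectors of
#' log(observed/expected) values; missing positions are dropped. Identical
#' profiles give p = 1.
#'
#' @param a,b [occupancy_profile()] results.
#' @return a `rank_sum_result` with fields `statistic` and `p_value`
#'   (`NA` and flagged when fewer than 3 finite values remain on a side).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "metagene_profile"), inherits(b, "metagene_profile"))
  .rank_sum(a$profile$enrichment, b$profile$enrichment)
}

#' Compare two RPKM vectors with a rank-sum test
#'
#' @param a,b numeric RPKM vectors (e.g. `rpkm_summary(...)$rpkm`).
#' @return a `rank_sum_result`; see [compare_profiles()].
#' @export
compare_rpkm <- function(a, b) {
  if (is.list(a) && !is.null(a$rpkm)) a <- a$rpkm
  if (is.list(b) && !is.null(b$rpkm)) b <- b$rpkm
  .rank_sum(as.numeric(a), as.numeric(b))
}

#' Per-bin RPKM and its mean for one library
#'
#' `RPKM = count * 1e9 / (bin width in bp * total counts in the library)`
#' (reads per kilobase per million mapped reads). The actual, possibly
#' end-clipped, width of each bin is used.
#'
#' @param counts a [binned_counts()] object.
#' @param library library column (index or label).
#' @return a list with `rpkm` (per-bin vector), `mean`, and `library`.
#' @export
rpkm_summary <- function(counts, library = 1L) {
  stopifnot(inherits(counts, "binned_counts"))
  v <- counts$counts[, library]
  total <- sum(v)
  if (total <= 0) .fail("zero total counts in library")
  w <- counts$grid$bins$end - counts$grid$bins$start
  rpkm <- v * 1e9 / (w * total)
  list(rpkm = rpkm, mean = mean(rpkm),
       library = colnames(counts$counts)[library])
}

#' Pairwise Pearson correlation of binned read counts
#'
#' @param counts a [binned_counts()] object with at least 2 libraries.
#' @return a symmetric correlation matrix with unit diagonal. Libraries
#'   with zero variance get `NA` off-diagonal entries and are listed in the
#'   `"flagged"` attribute.
#' @export
count_correlation <- function(counts) {
  stopifnot(inherits(counts, "binned_counts"))
  m <- counts$counts
  if (ncol(m) < 2L) .fail("count correlation needs at least 2 libraries")
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(r) <- 1
  sds <- apply(m, 2L, stats::sd)
  attr(r, "flagged") <- colnames(m)[sds == 0]
  r
}
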