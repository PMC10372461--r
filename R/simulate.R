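# Synthetic-data generators with known ground truth: genome + gene
# annotation, reference peaks at TSSs, degraded query peaks (planted recall,
# boundary jitter, fragmentation, background false peaks), and binned
# Poisson read counts. Every generator is a pure function of
# (configuration, seed); a single global seed feeds a named per-stage
# substream so stages can be regenerated independently.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data world. Defaults emulate the kind
#' of dataset the benchmark runs on: a genome of a few Mb over several
#' chromosomes, thousands of genes of which roughly half carry a reference
#' peak at the TSS, peak widths anchored on a 300-1500 bp chromatin
#' fragment range (normal, mean 900, sd 300, truncated at 50 bp), and
#' query degradation through planted recall, boundary jitter, peak
#' splitting by sub-nucleosomal gaps and uniform background false peaks.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (all equal).
#' @param n_genes total genes placed without overlap.
#' @param gene_length_mean,gene_length_sd gene length model in bp
#'   (normal, truncated at 300 bp).
#' @param p_tss_peak probability a gene carries a reference peak at its TSS.
#' @param peak_width_mean,peak_width_sd peak width model in bp (normal,
#'   truncated at 50 bp).
#' @param planted_recall probability a reference peak is recovered in the
#'   query set.
#' @param background_rate false peaks per Mb, placed off the reference.
#' @param jitter_sd sd in bp of the normal jitter applied to each retained
#'   peak boundary.
#' @param split_prob probability a retained peak is fragmented in two.
#' @param split_gap gap in bp between the two fragments (<= 150 so merging
#'   at a nucleosome length re-fuses them).
#' @param depth total reads for binned-count simulation.
#' @param enrichment fold enrichment of in-peak over background bins.
#' @param seed integer master seed; all stages derive substreams from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4, chrom_length = 2.5e6, n_genes = 4000,
                       gene_length_mean = 1500, gene_length_sd = 400,
                       p_tss_peak = 0.5,
                       peak_width_mean = 900, peak_width_sd = 300,
                       planted_recall = 0.8, background_rate = 5,
                       jitter_sd = 50, split_prob = 0.1, split_gap = 150,
                       depth = 3.8e6, enrichment = 10, seed = 1) {
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length,
              n_genes = n_genes, gene_length_mean = gene_length_mean,
              gene_length_sd = gene_length_sd, p_tss_peak = p_tss_peak,
              peak_width_mean = peak_width_mean,
              peak_width_sd = peak_width_sd,
              planted_recall = planted_recall,
              background_rate = background_rate, jitter_sd = jitter_sd,
              split_prob = split_prob, split_gap = split_gap, depth = depth,
              enrichment = enrichment, seed = seed)
  probs <- c("p_tss_peak", "planted_recall", "split_prob")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) .fail(p, " must be in [0, 1]")
  }
  pos <- c("n_chrom", "chrom_length", "gene_length_mean", "gene_length_sd",
           "peak_width_mean", "peak_width_sd")
  for (p in pos) if (cfg[[p]] <= 0) .fail(p, " must be > 0")
  nonneg <- c("n_genes", "background_rate", "jitter_sd", "split_gap", "depth")
  for (p in nonneg) if (cfg[[p]] < 0) .fail(p, " must be >= 0")
  if (!is_wholenumber(cfg$seed)) .fail("seed must be an integer")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome layout and non-overlapping gene annotation
#'
#' Chromosomes `chr1..chrN` of equal length; genes are allotted to
#' chromosomes proportionally and placed uniformly without overlap (uniform
#' order statistics over the free space), with both strands represented.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with `layout` (a [genome_layout()]) and `genes` (a gene
#'   data frame as in [read_genes()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- genome_layout(sprintf("chr%d", seq_len(config$n_chrom)),
                          rep(config$chrom_length, config$n_chrom))
  n <- config$n_genes
  if (n == 0L) {
    return(list(layout = layout,
                genes = data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), strand = character(),
                                   id = character(), stringsAsFactors = FALSE)))
  }
  # proportional allotment with largest remainders
  share <- layout$length / sum(layout$length) * n
  k <- floor(share)
  rem <- n - sum(k)
  if (rem > 0) {
    k[order(share - k, decreasing = TRUE)[seq_len(rem)]] <-
      k[order(share - k, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  genes <- with_seed(stage_seed(config$seed, "genome"), {
    per <- lapply(seq_len(nrow(layout)), function(i) {
      ki <- k[i]
      if (ki == 0) return(NULL)
      len <- layout$length[i]
      lens <- NULL
      for (try in seq_len(20L)) {
        cand <- pmax(300, round(stats::rnorm(ki, config$gene_length_mean,
                                             config$gene_length_sd)))
        if (sum(cand) <= len) {
          lens <- cand
          break
        }
      }
      if (is.null(lens)) {
        .fail("cannot place ", ki, " genes on a ", len,
              " bp chromosome without overlap")
      }
      slack <- len - sum(lens)
      u <- sort(stats::runif(ki, 0, slack))
      starts <- floor(u) + cumsum(c(0, lens[-ki]))
      data.frame(chrom = layout$name[i], start = starts, end = starts + lens,
                 strand = sample(c("+", "-"), ki, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  genes$id <- sprintf("gene%05d", seq_len(nrow(genes)))
  list(layout = layout, genes = genes)
}

#' Simulate reference peaks at gene TSSs
#'
#' Each gene carries a TSS-centred peak with probability
#' `config$p_tss_peak`; widths are drawn from the configured normal model
#' (truncated at 50 bp) and peaks are clipped at chromosome ends and to a
#' per-gene territory (bounded by the midpoints of the intergenic gaps,
#' with a 1 bp guard), so the reference is always a disjoint interval set
#' -- as a peak caller's output is -- and planted recall has an
#' unambiguous ground truth. With `p_tss_peak = 1` there is exactly one
#' peak per gene. Deterministic given `config$seed`.
#'
#' @param genes gene data frame (see [simulate_genome()]).
#' @param layout a [genome_layout()].
#' @param config a [sim_config()].
#' @return a [peak_set()] labelled `"reference"`.
#' @export
simulate_reference_peaks <- function(genes, layout, config) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  if (nrow(genes) == 0L || config$p_tss_peak == 0) {
    return(peak_set(label = "reference", layout = layout))
  }
  # disjoint per-gene territories: midpoints of the intergenic gaps
  lo <- numeric(nrow(genes))
  hi <- numeric(nrow(genes))
  for (nm in unique(genes$chrom)) {
    idx <- which(genes$chrom == nm)
    gs <- genes$start[idx]
    ge <- genes$end[idx]
    len <- chrom_length(nm, layout)
    lo[idx] <- floor((c(0, ge[-length(idx)]) + gs) / 2)
    hi[idx] <- floor((ge + c(gs[-1L], len)) / 2)
  }
  with_seed(stage_seed(config$seed, "reference"), {
    has <- stats::runif(nrow(genes)) < config$p_tss_peak
    g <- genes[has, , drop = FALSE]
    if (nrow(g) == 0L) {
      peak_set(label = "reference", layout = layout)
    } else {
      w <- pmax(50, round(stats::rnorm(nrow(g), config$peak_width_mean,
                                       config$peak_width_sd)))
      tss <- ifelse(g$strand == "+", g$start, g$end)
      lenc <- chrom_length(g$chrom, layout)
      # clip to the chromosome and to the gene territory (1 bp guard so
      # neighbouring peaks never touch and gap-0 merging keeps them apart)
      s <- pmax(0, lo[has], tss - floor(w / 2))
      e <- pmin(lenc, hi[has] - 1, tss + ceiling(w / 2))
      keep <- s < e
      peak_set(g$chrom[keep], s[keep], e[keep], label = "reference",
               layout = layout)
    }
  })
}

#' Simulate a degraded query peak set from a reference
#'
#' Models what a peak call on a smaller input looks like relative to the
#' reference call: each reference peak is retained with probability
#' `planted_recall`; retained peaks get normal boundary jitter
#' (`jitter_sd`), are fragmented in two with probability `split_prob`
#' (separated by exactly `split_gap` bp, so merging at a gap >=
#' `split_gap` re-fuses them), and uniform background false peaks are added
#' as a Poisson process of `background_rate` per Mb, rejecting any overlap
#' with the reference so ground truth stays unambiguous. Deterministic
#' given `config$seed`. With recall 1 and no jitter/splitting/background
#' the query equals the reference.
#'
#' @param reference a [peak_set()] of ground-truth peaks.
#' @param layout a [genome_layout()].
#' @param config a [sim_config()].
#' @return a [peak_set()] labelled `"query"`.
#' @export
simulate_query_peaks <- function(reference, layout, config) {
  stopifnot(inherits(reference, "peak_set"), inherits(config, "sim_config"))
  refdf <- reference$intervals
  refm <- merge_adjacent(reference, 0)$intervals
  with_seed(stage_seed(config$seed, "query"), {
    keep <- stats::runif(nrow(refdf)) < config$planted_recall
    d <- refdf[keep, , drop = FALSE]
    lenc <- chrom_length(d$chrom, layout)
    if (nrow(d) > 0L && config$jitter_sd > 0) {
      d$start <- d$start + round(stats::rnorm(nrow(d), 0, config$jitter_sd))
      d$end <- d$end + round(stats::rnorm(nrow(d), 0, config$jitter_sd))
      d$start <- pmax(0, d$start)
      d$end <- pmin(lenc, d$end)
      # re-centre any interval the jitter collapsed below 50 bp
      bad <- which(d$end - d$start < 50)
      if (length(bad)) {
        mid <- floor((d$start[bad] + d$end[bad]) / 2)
        d$start[bad] <- pmax(0, mid - 25)
        d$end[bad] <- pmin(lenc[bad], d$start[bad] + 50)
      }
    }
    chroms <- d$chrom
    starts <- d$start
    ends <- d$end
    if (nrow(d) > 0L && config$split_prob > 0) {
      width <- ends - starts
      do_split <- stats::runif(nrow(d)) < config$split_prob &
        width > config$split_gap + 2
      if (any(do_split)) {
        a <- starts[do_split] +
          floor((width[do_split] - config$split_gap) / 2)
        b <- a + config$split_gap
        chroms <- c(chroms[!do_split], rep(chroms[do_split], 2L))
        newstarts <- c(starts[!do_split], starts[do_split], b)
        newends <- c(ends[!do_split], a, ends[do_split])
        starts <- newstarts
        ends <- newends
      }
    }
    if (config$background_rate > 0) {
      for (i in seq_len(nrow(layout))) {
        nm <- layout$name[i]
        len <- layout$length[i]
        nb <- stats::rpois(1L, config$background_rate * len / 1e6)
        ri <- refm[refm$chrom == nm, , drop = FALSE]
        placed <- 0L
        attempts <- 0L
        while (placed < nb && attempts < 1000L * max(1L, nb)) {
          attempts <- attempts + 1L
          w <- max(50, round(stats::rnorm(1L, config$peak_width_mean,
                                          config$peak_width_sd)))
          if (w >= len) next
          s <- floor(stats::runif(1L, 0, len - w))
          # 1 bp guard: background may not overlap OR touch the reference,
          # so gap-0 normalization can never fuse it with a planted peak
          if (covered_in_chrom(max(0, s - 1), min(len, s + w + 1),
                               ri$start, ri$end) > 0) next
          chroms <- c(chroms, nm)
          starts <- c(starts, s)
          ends <- c(ends, s + w)
          placed <- placed + 1L
        }
        if (placed < nb) {
          .fail("could not place background peaks without touching the ",
                "reference on ", nm)
        }
      }
    }
    peak_set(chroms, starts, ends, label = "query", layout = layout)
  })
}

#' Simulate binned read counts over a peak landscape
#'
#' Per-bin counts are Poisson with a background rate inside peak-free bins
#' and `enrichment`-fold that rate inside peaks (proportional to the
#' fraction of the bin covered), scaled so each library totals
#' approximately `depth` reads. Libraries are independent replicates of the
#' same landscape. Deterministic given `seed`.
#'
#' @param peaks a [peak_set()] (the enriched regions).
#' @param layout a [genome_layout()].
#' @param grid a [bin_grid()].
#' @param enrichment fold enrichment inside peaks (1 = flat field).
#' @param depth expected total count per library.
#' @param n_libraries number of replicate libraries.
#' @param seed integer seed.
#' @return a [binned_counts()] object.
#' @export
simulate_binned_counts <- function(peaks, layout, grid, enrichment = 10,
                                   depth = 1e6, n_libraries = 1L, seed = 1L) {
  stopifnot(inherits(peaks, "peak_set"), inherits(grid, "bin_grid"))
  if (enrichment <= 0) .fail("enrichment must be > 0")
  if (depth < 0) .fail("depth must be >= 0")
  bins <- grid$bins
  merged <- merge_adjacent(peaks, 0)$intervals
  frac <- covered_bp(bins, merged) / (bins$end - bins$start)
  wgt <- (bins$end - bins$start) / grid$bin_size *
    (1 + (enrichment - 1) * frac)
  lam <- if (sum(wgt) > 0) depth * wgt / sum(wgt) else rep(0, nrow(bins))
  m <- with_seed(stage_seed(seed, "counts"), {
    matrix(stats::rpois(nrow(bins) * n_libraries, rep(lam, n_libraries)),
           nrow = nrow(bins), ncol = n_libraries)
  })
  binned_counts(grid, m, labels = sprintf("lib%d", seq_len(n_libraries)))
}

#' Run the full synthetic world for one configuration
#'
#' Genome + genes, reference peaks, degraded query peaks, and (when
#' `depth > 0`) two replicate libraries of binned counts on a 1 kb / 500 bp
#' grid.
#'
#' @param config a [sim_config()].
#' @return a list with `config`, `layout`, `genes`, `reference`, `query`,
#'   and `counts` (`NULL` when `depth` is 0).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genome(config)
  reference <- simulate_reference_peaks(g$genes, g$layout, config)
  query <- simulate_query_peaks(reference, g$layout, config)
  counts <- NULL
  if (config$depth > 0) {
    grid <- bin_grid(g$layout, 1000, 500)
    counts <- simulate_binned_counts(reference, g$layout, grid,
                                     enrichment = config$enrichment,
                                     depth = config$depth, n_libraries = 2L,
                                     seed = config$seed)
  }
  list(config = config, layout = g$layout, genes = g$genes,
       reference = reference, query = query, counts = counts)
}

#' Write a simulated experiment as standard text files
#'
#' Emits `chrom.sizes`, `genes.bed` (BED6), `reference.bed`, `query.bed`,
#' `counts.tsv` (when present) and a `manifest.json` recording the full
#' configuration, into `dir`. Reruns with the same configuration produce
#' byte-identical files.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(sim$layout, file.path(dir, "chrom.sizes"))
  write_genes(sim$genes, file.path(dir, "genes.bed"))
  write_bed(sim$reference, file.path(dir, "reference.bed"))
  write_bed(sim$query, file.path(dir, "query.bed"))
  if (!is.null(sim$counts)) {
    df <- cbind(sim$counts$grid$bins, as.data.frame(sim$counts$counts))
    utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(sim$config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
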