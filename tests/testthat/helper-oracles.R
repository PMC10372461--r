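# Brute-force oracles, deliberately independent of the package's sorted
# sweep / findInterval machinery: per-base-pair painting and graph closure.

# random interval set on a small genome
random_intervals <- function(n, layout, max_len = 200, seed = 0) {
  set.seed(seed)
  ri <- sample(nrow(layout), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, pmax(1, layout$length[ri] - len)))
  peak_set(layout$name[ri], start, start + len, label = paste0("rand", seed),
           layout = layout)
}

# merge-with-gap by transitive closure of the "within gap" relation,
# via connected components found by BFS on an explicit adjacency matrix
oracle_merge <- function(df, gap) {
  out <- NULL
  for (nm in unique(df$chrom)) {
    d <- df[df$chrom == nm, , drop = FALSE]
    n <- nrow(d)
    # uncovered distance between i and j; <= gap means the pair merges
    dist <- outer(d$start, d$end, function(s, e) s - e)
    near <- pmax(dist, t(dist)) <= gap
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      frontier <- i
      comp[i] <- cid
      while (length(frontier)) {
        nxt <- which(apply(near[frontier, , drop = FALSE], 2L, any) &
                       is.na(comp))
        comp[nxt] <- cid
        frontier <- nxt
      }
    }
    for (k in seq_len(cid)) {
      out <- rbind(out, data.frame(chrom = nm,
                                   start = min(d$start[comp == k]),
                                   end = max(d$end[comp == k]),
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# complement by per-bp painting
oracle_complement <- function(df, layout) {
  out <- NULL
  for (i in seq_len(nrow(layout))) {
    nm <- layout$name[i]
    len <- layout$length[i]
    cov <- logical(len)
    d <- df[df$chrom == nm, , drop = FALSE]
    for (j in seq_len(nrow(d))) {
      cov[seq(d$start[j] + 1L, d$end[j])] <- TRUE
    }
    r <- rle(!cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out <- rbind(out, data.frame(chrom = nm, start = starts[keep],
                                   end = ends[keep],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# union coverage of one query interval by a reference set, per-bp
oracle_covered_one <- function(chrom, s, e, ref) {
  cov <- logical(e - s)
  d <- ref[ref$chrom == chrom & ref$start < e & ref$end > s, , drop = FALSE]
  for (j in seq_len(nrow(d))) {
    a <- max(s, d$start[j]) - s
    b <- min(e, d$end[j]) - s
    cov[seq(a + 1L, b)] <- TRUE
  }
  sum(cov)
}

# all-pairs hit labels for intersect_fraction
oracle_hits <- function(qdf, rdf, f) {
  vapply(seq_len(nrow(qdf)), function(i) {
    cov <- oracle_covered_one(qdf$chrom[i], qdf$start[i], qdf$end[i], rdf)
    cov >= f * (qdf$end[i] - qdf$start[i]) - 1e-9
  }, TRUE)
}

# full confusion matrix by per-bp enumeration
oracle_confusion <- function(qdf, rdf, layout, f) {
  qn <- oracle_merge(qdf, 0)
  rn <- oracle_merge(rdf, 0)
  hits_q <- oracle_hits(qn, rn, f)
  cq <- oracle_complement(qn, layout)
  cr <- oracle_complement(rn, layout)
  hits_tn <- if (is.null(cr) || nrow(cr) == 0) logical() else {
    if (is.null(cq) || nrow(cq) == 0) rep(FALSE, nrow(cr))
    else oracle_hits(cr, cq, f)
  }
  list(query_peaks = nrow(qn), reference_peaks = nrow(rn),
       true_positives = sum(hits_q), false_positives = sum(!hits_q),
       true_negatives = sum(hits_tn))
}

# exact two-sided rank-sum p-value by exhaustive enumeration of which
# ranks go to sample a (no ties assumed)
oracle_ranksum_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2L, function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  })
  # note: rank(pooled) is fixed; enumerating index subsets enumerates all
  # equally likely rank assignments under the null
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# dense-grid locator for the sensitivity/specificity crossing in log10 cells
oracle_crossing <- function(series, n_grid = 200001) {
  x <- log10(series$cells)
  g <- seq(min(x), max(x), length.out = n_grid)
  sens <- approx(x, series$sensitivity, g)$y
  spec <- approx(x, series$specificity, g)$y
  d <- sens - spec
  sign_change <- which(d[-length(d)] * d[-1] <= 0 &
                         !(d[-length(d)] == 0 & d[-1] == 0))
  if (!length(sign_change)) return(NA_real_)
  i <- max(sign_change)
  10^((g[i] + g[i + 1]) / 2)
}

tiny_layout <- function(lens = c(c1 = 10000, c2 = 6000)) {
  genome_layout(names(lens), unname(lens))
}
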