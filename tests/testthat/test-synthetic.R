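# synthetic-data generators: determinism, ground-truth recovery

test_that("simulate_genome is reproducible and places genes without overlap", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 1e6, n_genes = 200, seed = 1)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 200L)
  expect_setequal(unique(g1$genes$strand), c("+", "-"))
  for (nm in g1$layout$name) {
    d <- g1$genes[g1$genes$chrom == nm, ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    expect_true(all(d$end <= 1e6))
  }
})

test_that("zero genes gives an empty annotation", {
  cfg <- sim_config(n_genes = 0, seed = 3)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 0L)
})

test_that("gene placement is uniform over the free space (order-statistics check)", {
  # sparse case: 40 genes of fixed length on 1 Mb; midpoints should be
  # close to uniform (Kolmogorov-Smirnov at alpha = 0.001)
  cfg <- sim_config(n_chrom = 1, chrom_length = 1e6, n_genes = 40,
                    gene_length_mean = 500, gene_length_sd = 1, seed = 4)
  mids <- NULL
  for (s in 1:25) {
    cfg$seed <- s
    g <- simulate_genome(cfg)
    mids <- c(mids, (g$genes$start + g$genes$end) / 2 / 1e6)
  }
  ks <- suppressWarnings(ks.test(mids, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("reference peaks follow p_tss_peak exactly at the extremes", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 2e6, n_genes = 500,
                    p_tss_peak = 1, seed = 5)
  g <- simulate_genome(cfg)
  ref <- simulate_reference_peaks(g$genes, g$layout, cfg)
  expect_equal(n_peaks(ref), 500L)

  cfg0 <- sim_config(p_tss_peak = 0, seed = 5)
  expect_equal(n_peaks(simulate_reference_peaks(g$genes, g$layout, cfg0)), 0L)
})

test_that("reference peak count lands in the binomial 99% CI at p = 0.5", {
  cfg <- sim_config(n_chrom = 5, chrom_length = 4e6, n_genes = 5000,
                    p_tss_peak = 0.5, seed = 6)
  g <- simulate_genome(cfg)
  ref <- simulate_reference_peaks(g$genes, g$layout, cfg)
  ci <- qbinom(c(0.005, 0.995), 5000, 0.5)
  expect_gte(n_peaks(ref), ci[1])
  expect_lte(n_peaks(ref), ci[2])
})

test_that("query equals reference when nothing is degraded", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 1e6, n_genes = 300,
                    p_tss_peak = 1, planted_recall = 1, jitter_sd = 0,
                    split_prob = 0, background_rate = 0, seed = 7)
  g <- simulate_genome(cfg)
  ref <- simulate_reference_peaks(g$genes, g$layout, cfg)
  q <- simulate_query_peaks(ref, g$layout, cfg)
  expect_equal(as.data.frame(q), as.data.frame(ref))
})

test_that("planted recall 0.8 is recovered by the confusion pipeline", {
  cfg <- sim_config(n_chrom = 5, chrom_length = 4e6, n_genes = 5000,
                    p_tss_peak = 1, planted_recall = 0.8, jitter_sd = 0,
                    split_prob = 0, background_rate = 0, seed = 8)
  g <- simulate_genome(cfg)
  ref <- simulate_reference_peaks(g$genes, g$layout, cfg)
  q <- simulate_query_peaks(ref, g$layout, cfg)
  cc <- confusion_counts(q, ref, g$layout)
  sens <- concordance_metrics(cc)$sensitivity
  # binomial 95% CI half-width at n = 5000, p = 0.8 is ~0.011
  expect_lt(abs(sens - 0.8), 0.02)
})

test_that("split peaks re-fuse after merging at the split gap", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 2e6, n_genes = 400,
                    p_tss_peak = 1, planted_recall = 1, jitter_sd = 0,
                    split_prob = 1, split_gap = 150, background_rate = 0,
                    peak_width_mean = 900, peak_width_sd = 100, seed = 9)
  g <- simulate_genome(cfg)
  ref <- simulate_reference_peaks(g$genes, g$layout, cfg)
  q <- simulate_query_peaks(ref, g$layout, cfg)
  expect_gt(n_peaks(q), n_peaks(ref))  # fragmentation happened
  # merging at the split gap re-fuses every fragment pair; distances
  # between distinct reference peaks are untouched by splitting, so the
  # result equals the reference merged at the same gap
  refused <- merge_adjacent(q, 150)
  expect_equal(n_peaks(refused), n_peaks(merge_adjacent(ref, 150)))
})

test_that("background peaks never touch the reference and dilute PPV only", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 2e6, n_genes = 400,
                    p_tss_peak = 1, planted_recall = 0.9, jitter_sd = 0,
                    split_prob = 0, background_rate = 20, seed = 10)
  g <- simulate_genome(cfg)
  ref <- simulate_reference_peaks(g$genes, g$layout, cfg)
  q <- simulate_query_peaks(ref, g$layout, cfg)
  # sensitivity with background equals sensitivity without
  cfg0 <- cfg
  cfg0$background_rate <- 0
  q0 <- simulate_query_peaks(ref, g$layout, cfg0)
  cc <- confusion_counts(q, ref, g$layout)
  cc0 <- confusion_counts(q0, ref, g$layout)
  m <- concordance_metrics(cc)
  m0 <- concordance_metrics(cc0)
  expect_equal(m$sensitivity, m0$sensitivity)
  expect_lt(m$ppv, m0$ppv)
})

test_that("binned counts: flat field at enrichment 1, replicates correlate at 10x", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 5e6, n_genes = 500,
                    p_tss_peak = 1, seed = 11)
  g <- simulate_genome(cfg)
  ref <- simulate_reference_peaks(g$genes, g$layout, cfg)
  grid <- bin_grid(g$layout, 1000, 500)

  flat <- simulate_binned_counts(ref, g$layout, grid, enrichment = 1,
                                 depth = 1e6, n_libraries = 1, seed = 12)
  genes_ok <- g$genes[g$genes$strand == "+", ]
  prof <- occupancy_profile(flat, genes_ok, g$layout, library = 1)
  expect_lt(max(abs(prof$profile$enrichment), na.rm = TRUE), 0.2)

  reps <- simulate_binned_counts(ref, g$layout, grid, enrichment = 10,
                                 depth = 1e6, n_libraries = 2, seed = 13)
  r <- count_correlation(reps)
  expect_gt(r[1, 2], 0.8)

  zero <- simulate_binned_counts(ref, g$layout, grid, depth = 0, seed = 14)
  expect_true(all(zero$counts == 0))
})

test_that("written simulations are byte-identical across reruns", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 5e5, n_genes = 150,
                    depth = 1e5, seed = 15)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_experiment(cfg), d1)
  write_simulation(simulate_experiment(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
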