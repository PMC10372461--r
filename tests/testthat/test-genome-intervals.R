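# genome layout + BED I/O + interval algebra

test_that("chrom.sizes parsing validates structure and reports line numbers", {
  p <- tempfile(fileext = ".sizes")
  writeLines(c("c1\t1000", "c2\t500"), p)
  gl <- read_chrom_sizes(p)
  expect_s3_class(gl, "genome_layout")
  expect_equal(gl$name, c("c1", "c2"))
  expect_equal(genome_size(gl), 1500)

  writeLines(character(), p)
  expect_error(read_chrom_sizes(p), "no chromosomes")

  writeLines(c("c1\t1000", "c1\t900"), p)
  expect_error(read_chrom_sizes(p), "duplicate.*line 2|line 2.*duplicate")

  writeLines(c("c1\t1000", "c2\t-5"), p)
  expect_error(read_chrom_sizes(p), "line 2")
  unlink(p)
})

test_that("BED reading sorts, validates, and reports offending lines", {
  gl <- genome_layout(c("c1", "c2"), c(1000, 500))
  p <- tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=x", "c1\t100\t200", "c1\t50\t80"), p)
  ps <- read_bed(p, gl)
  expect_equal(ps$intervals$start, c(50, 100))

  writeLines("c1\t200\t100", p)
  expect_error(read_bed(p, gl), "start >= end")

  writeLines("cX\t0\t10", p)
  expect_error(read_bed(p, gl), "unknown chromosome")

  writeLines("c1\t0\t2000", p)
  expect_error(read_bed(p, gl), "outside")
  unlink(p)
})

test_that("zero-length and malformed intervals are rejected at construction", {
  gl <- genome_layout("c1", 1000)
  expect_error(peak_set("c1", 100, 100, layout = gl), "start >= end")
  expect_error(peak_set("c1", -1, 10, layout = gl), "negative")
  expect_error(peak_set("cZ", 0, 10, layout = gl), "unknown chromosome")
})

test_that("merge_adjacent honours the gap boundary exactly", {
  gl <- genome_layout("c1", 1000)
  # distance exactly 150 merges
  p <- peak_set("c1", c(100, 350), c(200, 400), layout = gl)
  m <- merge_adjacent(p, 150)
  expect_equal(as.data.frame(m)$start, 100)
  expect_equal(as.data.frame(m)$end, 400)
  # distance 151 does not
  p2 <- peak_set("c1", c(100, 351), c(200, 400), layout = gl)
  expect_equal(n_peaks(merge_adjacent(p2, 150)), 2L)
})

test_that("merge_adjacent matches the pairwise-closure oracle on random sets", {
  gl <- tiny_layout()
  for (seed in 0:9) {
    p <- random_intervals(200, gl, max_len = 120, seed = seed)
    gap <- c(0, 10, 150)[seed %% 3 + 1]
    got <- as.data.frame(merge_adjacent(p, gap))
    want <- oracle_merge(as.data.frame(p), gap)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("merge_adjacent is idempotent and never increases the count", {
  gl <- tiny_layout()
  p <- random_intervals(300, gl, seed = 42)
  m <- merge_adjacent(p, 150)
  expect_lte(n_peaks(m), n_peaks(p))
  expect_equal(as.data.frame(merge_adjacent(m, 150)), as.data.frame(m))
})

test_that("complement covers exactly the uncovered genome", {
  gl <- genome_layout("c1", 1000)
  p <- peak_set("c1", c(100, 400), c(200, 500), layout = gl)
  cp <- as.data.frame(complement_peaks(p, gl))
  expect_equal(cp$start, c(0, 200, 500))
  expect_equal(cp$end, c(100, 400, 1000))

  # full-chromosome peak leaves nothing
  full <- peak_set("c1", 0, 1000, layout = gl)
  expect_equal(n_peaks(complement_peaks(full, gl)), 0L)

  # chromosome without peaks contributes one full-length interval
  gl2 <- genome_layout(c("c1", "c2"), c(1000, 700))
  p2 <- peak_set("c1", 10, 20, layout = gl2)
  cp2 <- as.data.frame(complement_peaks(p2, gl2))
  expect_true(any(cp2$chrom == "c2" & cp2$start == 0 & cp2$end == 700))
})

test_that("complement is an involution and bp totals sum to genome size", {
  gl <- tiny_layout()
  for (seed in 0:9) {
    p <- random_intervals(150, gl, seed = seed)
    norm <- merge_adjacent(p, 0)
    cp <- complement_peaks(p, gl)
    expect_equal(total_bp(norm) + total_bp(cp), genome_size(gl))
    expect_equal(as.data.frame(complement_peaks(cp, gl)),
                 as.data.frame(norm))
    # oracle agreement
    want <- oracle_complement(as.data.frame(p), gl)
    expect_equal(as.data.frame(cp)$start, want$start)
    expect_equal(as.data.frame(cp)$end, want$end)
  }
})

test_that("intersect_fraction applies the fraction to the query side, union-accumulated", {
  gl <- genome_layout("c1", 1000)
  r <- peak_set("c1", 80, 300, layout = gl)
  # overlap of exactly 20% is a hit
  q <- peak_set("c1", 0, 100, layout = gl)
  expect_equal(n_peaks(intersect_fraction(q, r, 0.2)$hits), 1L)
  # 19 bp of 100 is a miss
  r2 <- peak_set("c1", 81, 300, layout = gl)
  expect_equal(n_peaks(intersect_fraction(q, r2, 0.2)$hits), 0L)
  # coverage accumulates across reference intervals
  r3 <- peak_set("c1", c(0, 50), c(10, 60), layout = gl)  # 10 + 10 bp
  expect_equal(n_peaks(intersect_fraction(q, r3, 0.2)$hits), 1L)
  expect_error(intersect_fraction(q, r, 0), "min_fraction")
  expect_error(intersect_fraction(q, r, 1.5), "min_fraction")
})

test_that("intersect_fraction edge semantics: any-overlap at f->0+, containment at 1", {
  gl <- genome_layout("c1", 1000)
  q <- peak_set("c1", c(0, 200, 500), c(100, 300, 600), layout = gl)
  r <- peak_set("c1", c(99, 200), c(150, 300), layout = gl)
  tiny <- intersect_fraction(q, r, 1e-9)
  expect_equal(n_peaks(tiny$hits), 2L)  # 1 bp overlap counts
  full <- intersect_fraction(q, r, 1)
  expect_equal(as.data.frame(full$hits)$start, 200)  # only fully covered
})

test_that("intersect_fraction matches the O(n^2) per-bp oracle on random sets", {
  gl <- tiny_layout()
  for (seed in 0:9) {
    q <- random_intervals(500, gl, max_len = 150, seed = seed)
    r <- random_intervals(500, gl, max_len = 150, seed = seed + 100)
    f <- c(0.2, 0.5, 1)[seed %% 3 + 1]
    got <- intersect_fraction(q, r, f)
    want <- oracle_hits(as.data.frame(q), as.data.frame(r), f)
    expect_equal(n_peaks(got$hits), sum(want))
    expect_equal(as.data.frame(got$hits),
                 as.data.frame(q)[want, , drop = FALSE],
                 ignore_attr = TRUE)
    # hits and misses partition the query
    expect_equal(n_peaks(got$hits) + n_peaks(got$misses), n_peaks(q))
  }
})

test_that("reciprocal mode also requires the fraction of a reference interval", {
  gl <- genome_layout("c1", 10000)
  q <- peak_set("c1", 0, 100, layout = gl)
  r <- peak_set("c1", 0, 5000, layout = gl)   # covers all of q
  expect_equal(n_peaks(intersect_fraction(q, r, 0.2)$hits), 1L)
  expect_equal(n_peaks(intersect_fraction(q, r, 0.2, reciprocal = TRUE)$hits),
               0L)  # 100/5000 = 2% of the reference interval
})

test_that("BED round-trips are bit-exact, including label and empty sets", {
  gl <- tiny_layout()
  p <- random_intervals(10000, gl, seed = 3)
  f1 <- tempfile(fileext = ".bed")
  f2 <- tempfile(fileext = ".bed")
  write_bed(p, f1)
  back <- read_bed(f1, gl)
  expect_equal(as.data.frame(back), as.data.frame(p))
  expect_equal(back$label, p$label)
  write_bed(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  empty <- peak_set(label = "void", layout = gl)
  write_bed(empty, f1)
  expect_identical(readLines(f1), "# label: void")
  back <- read_bed(f1, gl)
  expect_equal(n_peaks(back), 0L)
  expect_equal(back$label, "void")
  unlink(c(f1, f2))
})
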