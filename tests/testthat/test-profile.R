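mk_reads <- function(chrom, pos, genome) {
  n <- length(chrom)
  structure(data.frame(chrom = chrom, pos = pos, mapq = rep(60L, n),
                       strand = rep("+", n), is_unmapped = rep(FALSE, n),
                       is_secondary = rep(FALSE, n),
                       is_supplementary = rep(FALSE, n),
                       is_duplicate = rep(FALSE, n),
                       stringsAsFactors = FALSE),
            read_length = 100L, class = c("read_records", "data.frame"))
}

test_that("bins are half-open 10 kb windows keyed by first-base position", {
  expect_equal(assign_bin(0), 0L)
  expect_equal(assign_bin(9999), 0L)
  expect_equal(assign_bin(10000), 1L)
  expect_equal(assign_bin(25000), 2L)
  expect_error(assign_bin(-1), ">= 0")
  expect_error(assign_bin(5, bin_size = 0), "> 0")
})

test_that("read binning increments exactly one cell per read", {
  g <- make_genome(2, 30000)
  cts <- bin_counts(mk_reads("chr1", c(0, 9999, 10000), g), g)
  expect_equal(as.data.frame(cts)[, c("bin", "count")],
               data.frame(bin = c(0L, 1L), count = c(2L, 1L)))

  empty <- bin_counts(mk_reads(character(0), numeric(0), g), g,
                      library_size = 5)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "library_size"), 5L)

  r <- mk_reads(rep(c("chr1", "chr2"), 50), rep(seq(0, 24500, by = 500), 2), g)
  perm <- r[sample(nrow(r)), ]
  expect_equal(as.data.frame(bin_counts(r, g)),
               as.data.frame(bin_counts(perm, g)))

  expect_error(bin_counts(mk_reads("chr9", 0, g), g), "absent")
})

test_that("normalization scales by library size and drops sparse bins", {
  g <- make_genome(1, 40000)
  raw <- oxoprofiler:::new_binned_counts(
    data.frame(chrom = factor("chr1", "chr1"), bin = 0:2,
               count = c(9L, 10L, 100L)),
    library_size = 119L, bin_size = 10000, genome = g)
  prof <- normalize_and_filter(raw)
  expect_equal(prof$bin, 1:2)   # 9 discarded, 10 retained (strict < 10)
  expect_equal(prof$count, c(10L, 100L))

  raw2 <- oxoprofiler:::new_binned_counts(
    data.frame(chrom = factor("chr1", "chr1"), bin = 0:1,
               count = c(10L, 30L)),
    library_size = 40L, bin_size = 10000, genome = g)
  prof2 <- normalize_and_filter(raw2, scale = 1e6, min_hits = 10)
  expect_equal(prof2$value, c(250000, 750000))

  # conservation at min_hits = 0
  prof0 <- normalize_and_filter(raw, min_hits = 0)
  expect_equal(sum(prof0$value), 1e6 * sum(raw$count) / 119)

  bad <- raw
  attr(bad, "library_size") <- 0L
  expect_error(normalize_and_filter(bad), "library_size")
})

test_that("sparsity threshold can instead be applied to normalized values", {
  g <- make_genome(1, 40000)
  raw <- oxoprofiler:::new_binned_counts(
    data.frame(chrom = factor("chr1", "chr1"), bin = 0:1,
               count = c(5L, 15L)),
    library_size = 20L, bin_size = 10000, genome = g)
  # normalized values are 250000 and 750000: both clear min_hits = 10
  prof <- normalize_and_filter(raw, min_hits_on = "normalized")
  expect_equal(nrow(prof), 2)
  expect_equal(nrow(normalize_and_filter(raw)), 1)
})

test_that("chromosome totals sum retained bins, reporting empty chroms as 0", {
  g <- make_genome(2, 30000)
  raw <- oxoprofiler:::new_binned_counts(
    data.frame(chrom = factor(c("chr1", "chr1", "chr2"), c("chr1", "chr2")),
               bin = c(0L, 1L, 0L), count = c(50L, 70L, 30L)),
    library_size = 150L, bin_size = 10000, genome = g)
  prof <- normalize_and_filter(raw, scale = 1, min_hits = 0)
  tot <- chrom_totals(prof)
  expect_equal(as.numeric(tot), c(120, 30) / 150)
  expect_equal(names(tot), c("chr1", "chr2"))

  empty <- normalize_and_filter(raw, min_hits = 1000)
  expect_equal(as.numeric(chrom_totals(empty)), c(0, 0))
})

test_that("raising min_hits never increases a chromosome total", {
  g <- make_genome(3, 100000, include_mito = TRUE)
  set.seed(31)
  for (rep in 1:5) {
    reads <- random_reads(3000, g)
    fs <- filter_stream(reads)
    cts <- bin_counts(fs$reads, g, library_size = fs$library_size)
    prev <- rep(Inf, 3)
    for (mh in c(0, 5, 10, 20, 50)) {
      tot <- as.numeric(chrom_totals(normalize_and_filter(cts, min_hits = mh)))
      expect_true(all(tot <= prev + 1e-9))
      prev <- tot
    }
  }
})

test_that("normalized values are invariant to common depth scaling", {
  g <- make_genome(1, 50000)
  base <- data.frame(chrom = factor("chr1", "chr1"), bin = 0:4,
                     count = c(12L, 40L, 7L, 25L, 16L))
  for (k in c(2L, 5L)) {
    a <- normalize_and_filter(oxoprofiler:::new_binned_counts(
      base, library_size = sum(base$count), bin_size = 10000, genome = g),
      min_hits = 10)
    scaled <- transform(base, count = count * k)
    b <- normalize_and_filter(oxoprofiler:::new_binned_counts(
      scaled, library_size = sum(scaled$count), bin_size = 10000, genome = g),
      min_hits = 10 * k)
    expect_equal(a$value, b$value)
  }
})

test_that("condition means average replicates over identical chromosomes", {
  t1 <- structure(c(chr1 = 2), class = "chrom_totals")
  t2 <- structure(c(chr1 = 4), class = "chrom_totals")
  m <- condition_mean(list(t1, t2), "wt")
  expect_equal(as.numeric(m), 3)
  expect_equal(attr(m, "n_replicates"), 2)
  expect_equal(as.numeric(condition_mean(list(t1))), 2)
  t3 <- structure(c(chr1 = 1, chr2 = 2), class = "chrom_totals")
  expect_error(condition_mean(list(t1, t3)), "mismatched")
})

test_that("bedGraph output round-trips byte-stably", {
  g <- make_genome(2, 30000)
  raw <- oxoprofiler:::new_binned_counts(
    data.frame(chrom = factor(c("chr1", "chr2"), c("chr1", "chr2")),
               bin = c(1L, 0L), count = c(10L, 30L)),
    library_size = 40L, bin_size = 10000, genome = g)
  prof <- normalize_and_filter(raw)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_profile(prof, f)
  lines <- readLines(f)
  expect_equal(lines[2], "chr1\t10000\t20000\t250000")

  back <- read_profile(f, g)
  f2 <- withr::local_tempfile(fileext = ".bedgraph")
  write_profile(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # the same holds for fractional normalized values
  raw2 <- oxoprofiler:::new_binned_counts(
    data.frame(chrom = factor("chr1", c("chr1", "chr2")), bin = 0:2,
               count = c(17L, 23L, 101L)),
    library_size = 141L, bin_size = 10000, genome = g)
  p2 <- normalize_and_filter(raw2)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_profile(p2, fa)
  write_profile(read_profile(fa, g), fb)
  expect_identical(readLines(fa), readLines(fb))

  # empty profile -> header-only file
  pe <- normalize_and_filter(raw, min_hits = 1000)
  fe <- withr::local_tempfile()
  write_profile(pe, fe)
  expect_equal(readLines(fe), "track type=bedGraph")
})

test_that("per-chromosome totals round-trip through TSV", {
  tot <- structure(c(chr1 = 120000.25, chr2 = 30.5), sample = "wt_rep1",
                   class = "chrom_totals")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_totals(tot, f)
  back <- read_totals(f)
  expect_equal(as.numeric(back), as.numeric(tot))
  expect_equal(names(back), names(tot))
  expect_equal(attr(back, "sample"), "wt_rep1")
})
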