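toy_config <- function(...) {
  sim_config(n_reads_per_sample = 2000, read_length = 100,
             mapq_low_fraction = 0, mito_fraction = 0,
             duplicate_fraction = 0, seed = 42L, ...)
}

test_that("intensity maps allocate mass as configured", {
  g <- make_genome(2, 200000)
  flat <- build_intensity_map(g, toy_config(hotspot_fraction = 0,
                                            hotspot_mass = c(wt = 0, mut = 0),
                                            background_model =
                                              c(wt = "uniform",
                                                mut = "uniform")), "wt")
  expect_equal(flat$weight, rep(1 / nrow(flat), nrow(flat)))

  cfg <- toy_config(hotspot_fraction = 0.05,
                    hotspot_mass = c(wt = 0.5, mut = 0.5),
                    background_model = c(wt = "uniform", mut = "uniform"))
  m <- build_intensity_map(g, cfg, "wt")
  expect_equal(sum(m$weight), 1)
  expect_equal(sum(m$weight[m$hotspot]), 0.5)

  # hotspot bins are shared between conditions; only the mass differs
  cfg2 <- toy_config(hotspot_mass = c(wt = 0.1, mut = 0.6))
  m_wt <- build_intensity_map(g, cfg2, "wt")
  m_mut <- build_intensity_map(g, cfg2, "mut")
  expect_identical(which(m_wt$hotspot), which(m_mut$hotspot))
  expect_equal(sum(m_mut$weight[m_mut$hotspot]), 0.6)

  expect_identical(build_intensity_map(g, cfg2, "wt"),
                   build_intensity_map(g, cfg2, "wt"))
  expect_error(build_intensity_map(
    g, toy_config(hotspot_fraction = 0, hotspot_mass = c(wt = 0.3, mut = 0.3)),
    "wt"), "hotspot_fraction")
})

test_that("count draws conserve the library and match the map on average", {
  g <- make_genome(1, 20000)
  cfg <- toy_config(hotspot_mass = c(wt = 0.75, mut = 0.75),
                    hotspot_fraction = 0.5,
                    background_model = c(wt = "uniform", mut = "uniform"))
  m <- build_intensity_map(g, cfg, "wt")  # 2 bins
  expect_equal(nrow(m), 2)
  cts <- simulate_counts(m, 5000, seed = 1)
  expect_equal(sum(cts$count), 5000)
  expect_equal(attr(cts, "library_size"), 5000L)
  expect_error(simulate_counts(m, 0, seed = 1), "> 0")

  # empirical mean over replicates within Monte-Carlo error of n * weight
  n_rep <- 1000; n_reads <- 10000
  draws <- vapply(seq_len(n_rep),
                  function(i) simulate_counts(m, n_reads, seed = i)$count[1],
                  numeric(1))
  w1 <- m$weight[1]
  se <- sqrt(n_reads * w1 * (1 - w1) / n_rep)
  expect_lt(abs(mean(draws) - n_reads * w1), 3 * se)
})

test_that("a single-bin map receives the whole library", {
  g <- make_genome(1, 9000)  # one partial bin
  cfg <- toy_config(hotspot_fraction = 0, hotspot_mass = c(wt = 0, mut = 0),
                    background_model = c(wt = "uniform", mut = "uniform"))
  m <- build_intensity_map(g, cfg, "wt")
  expect_equal(nrow(m), 1)
  expect_equal(simulate_counts(m, 123, seed = 9)$count, 123L)
})

test_that("read-level simulation matches count-level draws when noise-free", {
  g <- make_genome(3, 100000)
  cfg <- toy_config()
  m <- build_intensity_map(g, cfg, "mut")
  cts <- simulate_counts(m, cfg$n_reads_per_sample, seed = 5)
  reads <- simulate_reads(m, g, cfg, seed = 5)
  rebinned <- bin_counts(reads, g, library_size = nrow(reads))
  key <- function(df) setNames(df$count, paste(df$chrom, df$bin))
  full <- key(as.data.frame(cts))
  got <- key(as.data.frame(rebinned))
  expect_equal(got, full[full > 0][names(got)])
  expect_equal(sum(got), sum(full))
})

test_that("noise classes are injected deterministically from the seed", {
  g <- make_genome(3, 100000, include_mito = TRUE)
  cfg <- sim_config(n_reads_per_sample = 10000, mito_fraction = 0.1,
                    mapq_low_fraction = 0.2, duplicate_fraction = 0.1,
                    seed = 8L)
  m <- build_intensity_map(g, cfg, "wt")
  r1 <- simulate_reads(m, g, cfg, seed = 8)
  r2 <- simulate_reads(m, g, cfg, seed = 8)
  expect_identical(r1, r2)
  n_mito <- sum(r1$chrom == "chrM")
  expect_gt(n_mito, 0)
  # every mitochondrial read is removed by the default filter
  fs <- filter_stream(r1)
  expect_equal(sum(fs$reads$chrom == "chrM"), 0)
  expect_true(all(fs$reads$mapq >= 20))
  expect_false(any(fs$reads$is_duplicate))

  no_mito_genome <- make_genome(3, 100000)
  expect_error(simulate_reads(m, no_mito_genome, cfg, seed = 1),
               "mitochondrial")
})

test_that("SAM output is valid and round-trips losslessly", {
  g <- make_genome(2, 50000, include_mito = TRUE)
  cfg <- sim_config(n_reads_per_sample = 500, mito_fraction = 0.05,
                    mapq_low_fraction = 0.1, duplicate_fraction = 0.1,
                    seed = 3L)
  m <- build_intensity_map(g, cfg, "wt")
  reads <- simulate_reads(m, g, cfg, seed = 3)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, g, f)

  lines <- readLines(f)
  expect_match(lines[1], "^@HD")
  expect_equal(sum(grepl("^@SQ", lines)), nrow(g))
  # internal 0-based position 0 would print as POS 1; check 1-based shift
  body <- read.table(text = lines[!grepl("^@", lines)], sep = "\t")
  expect_equal(sort(body$V4), sort(as.integer(reads$pos) + 1L))

  back <- read_alignments(f)
  sig <- function(df) sort(paste(df$chrom, df$pos, df$mapq, df$strand,
                                 df$is_duplicate))
  expect_identical(sig(back), sig(reads))

  # header-only file for an empty stream
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads[0, ], g, f2, read_length = 100)
  expect_true(all(grepl("^@", readLines(f2))))

  bad <- reads
  bad$pos[1] <- g$length[1]  # read would extend past the contig
  expect_error(write_sam(bad, g, withr::local_tempfile(fileext = ".sam")),
               "beyond")
})
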