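# Independent brute-force oracle for the exact signed-rank test: enumerate
# all 2^n sign assignments explicitly. Intentionally slow and literal.
brute_signed_rank <- function(differences, alternative = "two.sided") {
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- numeric(2^n)
  for (i in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(i))[1:n]
    w_all[i + 1] <- sum(r[bits == 1L])
  }
  eps <- 1e-9
  p_ge <- mean(w_all >= w_obs - eps)
  p_le <- mean(w_all <= w_obs + eps)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Naive read-by-read profiling reference: explicit loops and dictionaries,
# no vectorized shortcuts shared with the implementation.
naive_chrom_totals <- function(reads, genome, min_mapq = 20,
                               excluded = "chrM", bin_size = 10000,
                               scale = 1e6, min_hits = 10) {
  kept <- new.env(parent = emptyenv())
  lib <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$mapq[i] < min_mapq) next
    if (reads$chrom[i] %in% excluded) next
    if (reads$is_unmapped[i] || reads$is_secondary[i] ||
        reads$is_supplementary[i] || reads$is_duplicate[i]) next
    lib <- lib + 1L
    key <- paste0(reads$chrom[i], ":", floor(reads$pos[i] / bin_size))
    prev <- if (is.null(kept[[key]])) 0L else kept[[key]]
    kept[[key]] <- prev + 1L
  }
  chroms <- genome$chrom[!genome$is_mito]
  totals <- setNames(numeric(length(chroms)), chroms)
  for (key in ls(kept)) {
    if (kept[[key]] < min_hits) next
    chrom <- sub(":.*$", "", key)
    totals[chrom] <- totals[chrom] + kept[[key]] * scale / lib
  }
  list(totals = totals, library_size = lib)
}

# Random read table over a toy genome, covering noise classes the filters
# must handle.
random_reads <- function(n, genome, p_low_mapq = 0.2, p_mito = 0.1,
                         p_dup = 0.1) {
  chroms <- genome$chrom[!genome$is_mito]
  chrom <- sample(chroms, n, replace = TRUE)
  if (any(genome$is_mito)) {
    mito <- genome$chrom[genome$is_mito][1]
    chrom[runif(n) < p_mito] <- mito
  }
  clen <- genome$length[match(chrom, genome$chrom)]
  structure(data.frame(
    chrom = chrom,
    pos = floor(runif(n) * (clen - 100)),
    mapq = ifelse(runif(n) < p_low_mapq, sample(0:19, n, replace = TRUE),
                  sample(20:60, n, replace = TRUE)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    is_unmapped = FALSE, is_secondary = FALSE, is_supplementary = FALSE,
    is_duplicate = runif(n) < p_dup,
    stringsAsFactors = FALSE),
    read_length = 100L, class = c("read_records", "data.frame"))
}

# Probability that the two-sided exact test rejects at level alpha when all
# n absolute differences are distinct (the test's achievable size under the
# null), from the signrank distribution.
achievable_size <- function(n, alpha = 0.05) {
  w <- 0:(n * (n + 1) / 2)
  p_le <- psignrank(w, n)
  p_ge <- psignrank(w - 1, n, lower.tail = FALSE)
  p_two <- pmin(1, 2 * pmin(p_le, p_ge))
  sum(dsignrank(w, n)[p_two < alpha])
}
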