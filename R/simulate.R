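#' Simulation configuration for synthetic ChIP datasets
#'
#' Describes a two-condition replicate ChIP-style experiment: library depth,
#' read length, where the signal sits (shared hotspot bins whose share of the
#' library differs between conditions), how the remaining background mass is
#' spread, and the noise classes the read-level filters must remove (low
#' mapping quality, mitochondrial contamination, duplicates).
#'
#' Defaults describe the scenario the package's calibration suites exercise:
#' a diffuse wild-type signal (10% of reads in hotspots, uniform background)
#' against an enriched mutant signal (50% of reads in hotspots, background
#' concentrated on a tenth of the background bins), 2e5 reads per sample and
#' two replicates per condition.
#'
#' @param n_reads_per_sample Reads drawn per sample (> 0).
#' @param read_length Read length in base pairs.
#' @param hotspot_fraction Proportion of bins designated hotspots, shared
#'   between conditions.
#' @param hotspot_mass Named numeric vector, one entry per condition: the
#'   proportion of that condition's reads drawn from hotspot bins.
#' @param background_model Named character vector per condition: `"uniform"`
#'   spreads the non-hotspot mass over all background bins; `"concentrated"`
#'   spreads it over a seed-chosen subset (`concentrated_fraction` of the
#'   background bins).
#' @param concentrated_fraction Fraction of background bins carrying the
#'   background mass under the `"concentrated"` model.
#' @param mapq_low_fraction Proportion of reads assigned mapping quality 0
#'   (the rest get 60); only the >= 20 threshold matters downstream.
#' @param mito_fraction Proportion of reads reassigned to the mitochondrial
#'   contig.
#' @param duplicate_fraction Proportion of reads flagged as PCR/optical
#'   duplicates.
#' @param n_replicates Replicate samples per condition.
#' @param seed Base random seed; the same config and seed reproduce identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_reads_per_sample = 2e5,
                       read_length = 100,
                       hotspot_fraction = 0.05,
                       hotspot_mass = c(wt = 0.1, mut = 0.5),
                       background_model = c(wt = "uniform",
                                            mut = "concentrated"),
                       concentrated_fraction = 0.1,
                       mapq_low_fraction = 0.05,
                       mito_fraction = 0.01,
                       duplicate_fraction = 0.02,
                       n_replicates = 2,
                       seed = 1L) {
  props <- c(hotspot_fraction = hotspot_fraction,
             mapq_low_fraction = mapq_low_fraction,
             mito_fraction = mito_fraction,
             duplicate_fraction = duplicate_fraction,
             concentrated_fraction = concentrated_fraction,
             hotspot_mass)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (n_reads_per_sample <= 0) stop("n_reads_per_sample must be > 0")
  if (read_length <= 0) stop("read_length must be > 0")
  if (is.null(names(hotspot_mass)))
    names(hotspot_mass) <- paste0("cond", seq_along(hotspot_mass))
  if (is.null(names(background_model)))
    names(background_model) <- names(hotspot_mass)
  if (!all(background_model %in% c("uniform", "concentrated")))
    stop("background_model entries must be 'uniform' or 'concentrated'")
  structure(list(n_reads_per_sample = as.integer(n_reads_per_sample),
                 read_length = as.integer(read_length),
                 hotspot_fraction = hotspot_fraction,
                 hotspot_mass = hotspot_mass,
                 background_model = background_model,
                 concentrated_fraction = concentrated_fraction,
                 mapq_low_fraction = mapq_low_fraction,
                 mito_fraction = mito_fraction,
                 duplicate_fraction = duplicate_fraction,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Enumerate all (chrom, bin) cells of the analyzable genome for a grid.
bin_frame <- function(genome, bin_size) {
  chroms <- analyzable_chroms(genome)
  lens <- genome$length[match(chroms, genome$chrom)]
  nbins <- pmax(1L, as.integer(ceiling(lens / bin_size)))
  data.frame(chrom = factor(rep(chroms, nbins), levels = chroms),
             bin = unlist(lapply(nbins, function(k) seq_len(k) - 1L)),
             stringsAsFactors = FALSE)
}

#' Build a per-bin intensity map for one condition
#'
#' Hotspot bins (and, under the concentrated background model, the background
#' subset) are chosen reproducibly from `seed` alone, so both conditions of a
#' comparison share the same hotspot locations; the conditions differ only in
#' how much read mass those locations receive (`hotspot_mass`) and in how the
#' remainder is spread (`background_model`).
#'
#' @param genome An `oxog_genome`.
#' @param config A `sim_config`.
#' @param condition Condition label; must name an entry of
#'   `config$hotspot_mass`.
#' @param seed Seed for the (condition-independent) bin choices; defaults to
#'   `config$seed`.
#' @param bin_size Bin width in base pairs.
#' @return An `intensity_map`: data.frame with columns `chrom`, `bin`,
#'   `weight` (summing to 1), `hotspot`.
#' @export
build_intensity_map <- function(genome, config, condition,
                                seed = config$seed, bin_size = 10000) {
  stopifnot(inherits(genome, "oxog_genome"), inherits(config, "sim_config"))
  if (!condition %in% names(config$hotspot_mass))
    stop("unknown condition: ", condition)
  mass <- unname(config$hotspot_mass[condition])
  bg_model <- unname(config$background_model[condition])
  cells <- bin_frame(genome, bin_size)
  n <- nrow(cells)
  n_hot <- if (config$hotspot_fraction > 0)
    max(1L, round(config$hotspot_fraction * n)) else 0L
  if (n_hot == 0L && mass > 0)
    stop("hotspot_fraction is 0 but hotspot_mass > 0 for condition ", condition)
  sel <- with_seed(seed, {
    hot <- if (n_hot > 0L) sample.int(n, n_hot) else integer(0)
    bg <- setdiff(seq_len(n), hot)
    n_conc <- max(1L, round(config$concentrated_fraction * length(bg)))
    conc <- if (length(bg) > 0L) sort(sample(bg, min(n_conc, length(bg))))
            else integer(0)
    list(hot = hot, conc = conc)
  })
  w <- numeric(n)
  cells$hotspot <- FALSE
  cells$hotspot[sel$hot] <- TRUE
  if (n_hot > 0L) w[sel$hot] <- mass / n_hot
  bg_idx <- if (identical(bg_model, "concentrated")) sel$conc
            else setdiff(seq_len(n), sel$hot)
  if (length(bg_idx) > 0L) {
    w[bg_idx] <- w[bg_idx] + (1 - mass) / length(bg_idx)
  } else if (mass < 1) {
    stop("no background bins available to carry background mass")
  }
  cells$weight <- w / sum(w)
  structure(cells,
            bin_size = bin_size, condition = condition,
            genome = genome,
            class = c("intensity_map", "data.frame"))
}

#' Draw binned read counts from an intensity map
#'
#' One multinomial draw of `n_reads` over the map's bins; the fast path used
#' for statistical calibration, bypassing read-level simulation and I/O.
#'
#' @param map An `intensity_map`.
#' @param n_reads Library size to draw (> 0).
#' @param seed Random seed.
#' @return A `binned_counts` object (see [bin_counts()]); its `library_size`
#'   equals `n_reads`.
#' @export
simulate_counts <- function(map, n_reads, seed) {
  stopifnot(inherits(map, "intensity_map"))
  if (n_reads <= 0) stop("n_reads must be > 0")
  stopifnot(abs(sum(map$weight) - 1) < 1e-8)
  counts <- with_seed(seed, as.integer(rmultinom(1, n_reads, map$weight)))
  new_binned_counts(data.frame(chrom = map$chrom, bin = map$bin,
                               count = counts),
                    library_size = as.integer(n_reads),
                    bin_size = attr(map, "bin_size"),
                    genome = attr(map, "genome"))
}

#' Simulate aligned reads for one sample
#'
#' Draws per-bin counts exactly as [simulate_counts()] would for the same
#' `(map, seed)`, then places each read uniformly within its bin (clipped so
#' the read fits the chromosome), assigns two-point mapping qualities
#' (0 or 60), reassigns a fraction of reads to the mitochondrial contig, flags
#' duplicates, and draws strands with probability 1/2. With all noise
#' fractions zero, binning the emitted reads reproduces the
#' [simulate_counts()] table exactly.
#'
#' @param map An `intensity_map`.
#' @param genome An `oxog_genome`; must contain a mitochondrial contig when
#'   `config$mito_fraction > 0`.
#' @param config A `sim_config`.
#' @param seed Random seed.
#' @return A `read_records` data.frame with columns `chrom`, `pos` (0-based
#'   leftmost), `mapq`, `strand`, `is_unmapped`, `is_secondary`,
#'   `is_supplementary`, `is_duplicate`.
#' @export
simulate_reads <- function(map, genome, config, seed) {
  stopifnot(inherits(map, "intensity_map"), inherits(genome, "oxog_genome"),
            inherits(config, "sim_config"))
  if (config$mito_fraction > 0 && !any(genome$is_mito))
    stop("mito_fraction > 0 but the genome has no mitochondrial contig")
  rl <- config$read_length
  if (any(genome$length[!genome$is_mito] <= rl))
    stop("read_length must be smaller than every chromosome length")
  bin_size <- attr(map, "bin_size")
  n <- config$n_reads_per_sample
  res <- with_seed(seed, {
    counts <- as.integer(rmultinom(1, n, map$weight))
    idx <- rep.int(seq_len(nrow(map)), counts)
    chrom <- as.character(map$chrom)[idx]
    bin_start <- map$bin[idx] * bin_size
    clen <- genome$length[match(chrom, genome$chrom)]
    width <- pmin(bin_size, clen - bin_start)
    pos <- bin_start + floor(runif(length(idx)) * width)
    pos <- pmin(pos, clen - rl)
    mapq <- ifelse(runif(length(idx)) < config$mapq_low_fraction, 0L, 60L)
    if (config$mito_fraction > 0) {
      mito_name <- genome$chrom[genome$is_mito][1]
      mito_len <- genome$length[genome$is_mito][1]
      to_mito <- runif(length(idx)) < config$mito_fraction
      chrom[to_mito] <- mito_name
      pos[to_mito] <- floor(runif(sum(to_mito)) * max(1, mito_len - rl))
    }
    dup <- runif(length(idx)) < config$duplicate_fraction
    strand <- ifelse(runif(length(idx)) < 0.5, "+", "-")
    data.frame(chrom = chrom, pos = as.numeric(pos), mapq = mapq,
               strand = strand, is_unmapped = FALSE, is_secondary = FALSE,
               is_supplementary = FALSE, is_duplicate = dup,
               stringsAsFactors = FALSE)
  })
  structure(res, read_length = rl, class = c("read_records", "data.frame"))
}

#' Write aligned reads to a SAM file
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header lines for every contig of the
#' genome, then one alignment line per read with 1-based POS and FLAG bits for
#' strand (0x10), secondary (0x100), duplicate (0x400), supplementary (0x800)
#' and unmapped (0x4). Sequence and quality are omitted (`*`): the profiling
#' pipeline consumes only position, mapping quality and flags.
#'
#' @param reads A `read_records` data.frame (see [simulate_reads()]).
#' @param genome An `oxog_genome` declaring every contig the reads map to.
#' @param destination Output path.
#' @param read_length Read length used for the CIGAR and the end-of-contig
#'   check; defaults to the attribute recorded by [simulate_reads()].
#' @return `destination`, invisibly.
#' @export
write_sam <- function(reads, genome, destination,
                      read_length = attr(reads, "read_length")) {
  stopifnot(inherits(genome, "oxog_genome"))
  if (is.null(read_length)) read_length <- 100L
  bad <- !(reads$chrom %in% genome$chrom)
  if (any(bad))
    stop("read on undeclared contig: ", unique(reads$chrom[bad])[1])
  clen <- genome$length[match(reads$chrom, genome$chrom)]
  if (nrow(reads) > 0 && any(reads$pos + read_length > clen))
    stop("read extends beyond chromosome end")
  if (nrow(reads) > 0 && any(reads$pos < 0)) stop("negative read position")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom,
                      as.integer(genome$length)))
  con <- file(destination, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(reads) > 0) {
    flag <- 16L * (reads$strand == "-") +
      4L * reads$is_unmapped + 256L * reads$is_secondary +
      1024L * reads$is_duplicate + 2048L * reads$is_supplementary
    writeLines(sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(reads)), flag, reads$chrom,
                       as.integer(reads$pos) + 1L, as.integer(reads$mapq),
                       as.integer(read_length)),
               con)
  }
  invisible(destination)
}
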