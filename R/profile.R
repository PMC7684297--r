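# Internal constructor shared by simulate_counts() and bin_counts().
new_binned_counts <- function(df, library_size, bin_size, genome,
                              sample = NA_character_) {
  stopifnot(all(df$count >= 0), library_size >= 0)
  structure(df, library_size = as.integer(library_size),
            bin_size = bin_size, genome = genome, sample = sample,
            class = c("binned_counts", "data.frame"))
}

#' Bin index of a genomic position
#'
#' Bins are half-open `[k*bin_size, (k+1)*bin_size)` windows indexed from 0;
#' a read belongs to the bin containing its first (leftmost) aligned base.
#'
#' @param position 0-based position(s).
#' @param bin_size Bin width in base pairs (> 0).
#' @return Integer bin index (vectorized).
#' @examples
#' assign_bin(c(0, 9999, 10000, 25000), 10000)  # 0 0 1 2
#' @export
assign_bin <- function(position, bin_size = 10000) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (any(position < 0)) stop("positions must be >= 0")
  as.integer(position %/% bin_size)
}

#' Count filtered reads per (chromosome, bin)
#'
#' Each read increments exactly one cell, keyed by its leftmost aligned
#' position (use `five_prime = TRUE` to key reverse-strand reads by their
#' biological 5' end instead). Cells with no reads are simply absent; they
#' count as zero everywhere downstream.
#'
#' @param reads Filtered `read_records`.
#' @param genome An `oxog_genome`; reads on undeclared chromosomes are an
#'   error (excluded contigs should have been filtered out already).
#' @param bin_size Bin width in base pairs.
#' @param library_size The filtered-read count from [filter_stream()];
#'   defaults to `nrow(reads)`.
#' @param five_prime Key reverse-strand reads by their 5' end
#'   (`pos + read_length - 1`) rather than the leftmost base.
#' @param sample Optional sample label carried into downstream tables.
#' @return A `binned_counts` object: data.frame (`chrom`, `bin`, `count`)
#'   with attributes `library_size`, `bin_size`, `genome`, `sample`.
#' @export
bin_counts <- function(reads, genome, bin_size = 10000,
                       library_size = nrow(reads), five_prime = FALSE,
                       sample = NA_character_) {
  stopifnot(inherits(genome, "oxog_genome"))
  chroms <- analyzable_chroms(genome)
  bad <- setdiff(unique(reads$chrom), genome$chrom)
  if (length(bad) > 0L)
    stop("reads on chromosome(s) absent from the genome model: ",
         paste(bad, collapse = ", "))
  pos <- reads$pos
  if (five_prime) {
    rl <- attr(reads, "read_length")
    if (is.null(rl)) stop("five_prime = TRUE requires a known read length")
    pos <- ifelse(reads$strand == "-", pos + rl - 1, pos)
  }
  if (nrow(reads) == 0L) {
    df <- data.frame(chrom = factor(character(0), levels = chroms),
                     bin = integer(0), count = integer(0))
    return(new_binned_counts(df, library_size, bin_size, genome, sample))
  }
  bin <- assign_bin(pos, bin_size)
  key <- paste(reads$chrom, bin, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  df <- data.frame(chrom = factor(vapply(parts, `[`, "", 1L), levels = chroms),
                   bin = as.integer(vapply(parts, `[`, "", 2L)),
                   count = as.integer(tab))
  df <- df[order(df$chrom, df$bin), , drop = FALSE]
  rownames(df) <- NULL
  new_binned_counts(df, library_size, bin_size, genome, sample)
}

#' Normalize bins to library size and discard sparse bins
#'
#' Retained bins are those with at least `min_hits` raw reads (the `< 10
#' hits` discard is strict: a raw count of 10 is kept, 9 is not); each
#' retained bin's value is `count * scale / library_size`, i.e. reads per
#' `scale` filtered reads. By default the sparsity threshold is applied to
#' raw counts; `min_hits_on = "normalized"` applies it to the normalized
#' values instead.
#'
#' @param counts A `binned_counts` object with `library_size > 0`.
#' @param scale Reporting scale for normalized values (default 1e6: counts
#'   per million filtered reads). The downstream paired statistic is
#'   invariant to this choice.
#' @param min_hits Minimum hits for a bin to be retained.
#' @param min_hits_on Apply `min_hits` to `"raw"` counts (default) or to
#'   `"normalized"` values.
#' @return A `norm_profile` object: data.frame (`chrom`, `bin`, `count`,
#'   `value`) of retained bins, with the input's attributes plus `scale` and
#'   `min_hits`.
#' @export
normalize_and_filter <- function(counts, scale = 1e6, min_hits = 10L,
                                 min_hits_on = c("raw", "normalized")) {
  stopifnot(inherits(counts, "binned_counts"))
  min_hits_on <- match.arg(min_hits_on)
  lib <- attr(counts, "library_size")
  if (is.null(lib) || lib <= 0)
    stop("library_size must be > 0 to normalize")
  df <- as.data.frame(counts)
  df$value <- df$count * scale / lib
  keep <- if (min_hits_on == "raw") df$count >= min_hits
          else df$value >= min_hits
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, library_size = lib, bin_size = attr(counts, "bin_size"),
            genome = attr(counts, "genome"), sample = attr(counts, "sample"),
            scale = scale, min_hits = min_hits,
            class = c("norm_profile", "data.frame"))
}

#' Per-chromosome totals of a normalized profile
#'
#' Sums the retained normalized bin values within each analyzable chromosome;
#' chromosomes with no retained bins are reported as 0.
#'
#' @param profile A `norm_profile`.
#' @return A `chrom_totals` object: named numeric vector over the genome's
#'   analyzable chromosomes, with a `sample` attribute.
#' @export
chrom_totals <- function(profile) {
  stopifnot(inherits(profile, "norm_profile"))
  genome <- attr(profile, "genome")
  chroms <- analyzable_chroms(genome)
  tot <- setNames(numeric(length(chroms)), chroms)
  if (nrow(profile) > 0) {
    s <- tapply(profile$value, factor(profile$chrom, levels = chroms), sum)
    s[is.na(s)] <- 0
    tot[names(s)] <- s
  }
  structure(tot, sample = attr(profile, "sample"), class = "chrom_totals")
}

#' @export
print.chrom_totals <- function(x, ...) {
  cat("Per-chromosome normalized totals",
      if (!is.na(attr(x, "sample"))) sprintf(" [%s]", attr(x, "sample")),
      "\n", sep = "")
  print(unclass(setNames(as.numeric(x), names(x))), ...)
  invisible(x)
}

#' Average per-chromosome totals across a condition's replicates
#'
#' @param replicates List of `chrom_totals` from independent experiments of
#'   one condition; their chromosome sets must be identical.
#' @param condition Optional condition label.
#' @return A `condition_summary`: named numeric vector of per-chromosome
#'   means, with attributes `n_replicates` and `condition`.
#' @export
condition_mean <- function(replicates, condition = NA_character_) {
  if (!is.list(replicates)) replicates <- list(replicates)
  if (length(replicates) < 1L) stop("need at least one replicate")
  chroms <- names(replicates[[1]])
  for (r in replicates) {
    if (!identical(names(r), chroms))
      stop("replicates have mismatched chromosome sets")
  }
  m <- rowMeans(matrix(unlist(lapply(replicates, as.numeric)),
                       nrow = length(chroms)))
  structure(setNames(m, chroms), n_replicates = length(replicates),
            condition = condition, class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition summary%s: mean of %d replicate(s)\n",
              if (!is.na(attr(x, "condition")))
                sprintf(" [%s]", attr(x, "condition")) else "",
              attr(x, "n_replicates")))
  print(unclass(setNames(as.numeric(x), names(x))), ...)
  invisible(x)
}

#' Write a normalized profile as bedGraph
#'
#' One `chrom start end value` line per retained bin (0-based half-open
#' coordinates, bins sorted by chromosome then start). The numeric format is
#' stable under write-parse-write round trips.
#'
#' @param profile A `norm_profile`.
#' @param destination Output path.
#' @return `destination`, invisibly.
#' @seealso [read_profile()]
#' @export
write_profile <- function(profile, destination) {
  stopifnot(inherits(profile, "norm_profile"))
  bin_size <- attr(profile, "bin_size")
  genome <- attr(profile, "genome")
  ord <- order(profile$chrom, profile$bin)
  df <- profile[ord, , drop = FALSE]
  start <- df$bin * bin_size
  end <- pmin(start + bin_size,
              genome$length[match(as.character(df$chrom), genome$chrom)])
  lines <- sprintf("%s\t%d\t%d\t%s", as.character(df$chrom),
                   as.integer(start), as.integer(end),
                   sprintf("%.10g", df$value))
  writeLines(c("track type=bedGraph", lines), destination)
  invisible(destination)
}

#' Read a bedGraph profile written by [write_profile()]
#'
#' @param source File path.
#' @param genome The `oxog_genome` the profile was computed against.
#' @param bin_size Bin width used when the profile was written.
#' @return A `norm_profile` (raw counts are unknown after the round trip and
#'   reported as `NA`).
#' @export
read_profile <- function(source, genome, bin_size = 10000) {
  lines <- readLines(source)
  lines <- lines[!grepl("^track", lines)]
  chroms <- analyzable_chroms(genome)
  if (length(lines) == 0L) {
    df <- data.frame(chrom = factor(character(0), levels = chroms),
                     bin = integer(0), count = integer(0), value = numeric(0))
  } else {
    tab <- utils::read.table(text = lines, sep = "\t",
                             col.names = c("chrom", "start", "end", "value"),
                             stringsAsFactors = FALSE)
    if (any(tab$start %% bin_size != 0))
      stop("bedGraph intervals are not aligned to the bin grid")
    df <- data.frame(chrom = factor(tab$chrom, levels = chroms),
                     bin = as.integer(tab$start %/% bin_size),
                     count = NA_integer_, value = tab$value)
  }
  structure(df, library_size = NA_integer_, bin_size = bin_size,
            genome = genome, sample = NA_character_, scale = NA_real_,
            min_hits = NA_integer_,
            class = c("norm_profile", "data.frame"))
}

#' Write per-chromosome totals as TSV
#'
#' Columns: `sample`, `chromosome`, `total_normalized_hits`.
#'
#' @param totals A `chrom_totals` object.
#' @param destination Output path.
#' @return `destination`, invisibly.
#' @export
write_totals <- function(totals, destination) {
  stopifnot(inherits(totals, "chrom_totals"))
  df <- data.frame(sample = attr(totals, "sample"),
                   chromosome = names(totals),
                   total_normalized_hits = sprintf("%.10g", as.numeric(totals)))
  utils::write.table(df, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(destination)
}

#' Read a per-chromosome totals TSV written by [write_totals()]
#'
#' @param source File path.
#' @return A `chrom_totals` object.
#' @export
read_totals <- function(source) {
  df <- utils::read.table(source, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(setNames(as.numeric(df$total_normalized_hits), df$chromosome),
            sample = df$sample[1], class = "chrom_totals")
}
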