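#' Construct a genome model
#'
#' A genome model is the coordinate frame for binning: an ordered table of
#' chromosome names and lengths, with an optional mitochondrial contig that is
#' carried for read placement but never counted as an analyzable chromosome
#' (mitochondrial reads are discarded by the default filter policy).
#'
#' @param chroms Character vector of chromosome names, or a data.frame with
#'   columns `chrom` and `length`.
#' @param lengths Integer vector of chromosome lengths in base pairs (ignored
#'   when `chroms` is a data.frame).
#' @param mito Name of the contig to treat as mitochondrial, or `NA` for none.
#'   If absent from `chroms` it is appended with length `mito_length`.
#' @param mito_length Length used when the mitochondrial contig is appended.
#' @return An object of class `oxog_genome`: a data.frame with columns
#'   `chrom`, `length`, `is_mito`.
#' @seealso [make_genome()] for a systematic toy genome, [read_genome()] to
#'   load a chromosome table from TSV.
#' @export
genome_model <- function(chroms, lengths = NULL, mito = NA_character_,
                         mito_length = 16569L) {
  if (is.data.frame(chroms)) {
    stopifnot(all(c("chrom", "length") %in% names(chroms)))
    lengths <- chroms$length
    chroms <- as.character(chroms$chrom)
  }
  if (length(chroms) < 1L) stop("genome must contain at least one chromosome")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  lengths <- as.numeric(lengths)
  if (length(lengths) != length(chroms) || any(!is.finite(lengths)) ||
      any(lengths <= 0)) {
    stop("every chromosome length must be a positive number")
  }
  if (!is.na(mito) && !(mito %in% chroms)) {
    chroms <- c(chroms, mito)
    lengths <- c(lengths, mito_length)
  }
  g <- data.frame(chrom = chroms, length = lengths,
                  is_mito = !is.na(mito) & chroms == mito,
                  stringsAsFactors = FALSE)
  if (sum(!g$is_mito) < 1L) {
    stop("genome must contain at least one analyzable (non-mitochondrial) chromosome")
  }
  class(g) <- c("oxog_genome", "data.frame")
  g
}

#' Build a systematically named toy genome
#'
#' Convenience constructor used by the simulator: `n_chroms` equally sized
#' chromosomes named `chr1 ... chrN`, optionally followed by a mitochondrial
#' contig `chrM`.
#'
#' @param n_chroms Number of analyzable chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in base pairs.
#' @param include_mito Append a `chrM` contig?
#' @param mito_length Length of the mitochondrial contig.
#' @return An `oxog_genome`.
#' @examples
#' make_genome(2, 30000)
#' @export
make_genome <- function(n_chroms, chrom_length, include_mito = FALSE,
                        mito_length = 16569L) {
  if (!is.numeric(n_chroms) || length(n_chroms) != 1L || n_chroms < 1)
    stop("n_chroms must be a positive integer")
  if (!is.numeric(chrom_length) || chrom_length <= 0)
    stop("chrom_length must be positive")
  genome_model(paste0("chr", seq_len(n_chroms)),
               rep(chrom_length, n_chroms),
               mito = if (include_mito) "chrM" else NA_character_,
               mito_length = mito_length)
}

#' Analyzable chromosomes of a genome model
#'
#' @param genome An `oxog_genome`.
#' @return Character vector of non-mitochondrial chromosome names, in genome
#'   order.
#' @export
analyzable_chroms <- function(genome) {
  stopifnot(inherits(genome, "oxog_genome"))
  genome$chrom[!genome$is_mito]
}

#' Read a chromosome name/length table
#'
#' Expects a headerless (or `chrom`/`length`-headed) two-column TSV such as a
#' `.chrom.sizes` / faidx-style table.
#'
#' @param path File path.
#' @param mito Mitochondrial contig name; defaults to `chrM` when present in
#'   the table, else none.
#' @return An `oxog_genome`.
#' @export
read_genome <- function(path, mito = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) > 0 && tab$chrom[1] == "chrom") tab <- tab[-1, , drop = FALSE]
  tab$length <- as.numeric(tab$length)
  if (is.null(mito)) mito <- if ("chrM" %in% tab$chrom) "chrM" else NA_character_
  genome_model(tab, mito = mito)
}

#' @export
print.oxog_genome <- function(x, ...) {
  cat(sprintf("Genome model: %d analyzable chromosome(s)%s\n",
              sum(!x$is_mito),
              if (any(x$is_mito))
                sprintf(" + mitochondrial contig %s", x$chrom[x$is_mito])
              else ""))
  print.data.frame(x, ...)
  invisible(x)
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
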