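#' Read-level filter policy
#'
#' The defaults implement the profiling pipeline's read filters: keep primary
#' mapped, non-duplicate reads with mapping quality >= 20 (the threshold is
#' inclusive) that do not map to the mitochondrial contig. Each class is an
#' independent switch, so the minimal MAPQ-only filter is also expressible.
#'
#' @param min_mapq Minimum mapping quality retained (inclusive).
#' @param excluded_chroms Contigs whose reads are discarded.
#' @param drop_unmapped,drop_secondary,drop_supplementary,drop_duplicates
#'   Discard the corresponding alignment class?
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_mapq = 20L, excluded_chroms = "chrM",
                          drop_unmapped = TRUE, drop_secondary = TRUE,
                          drop_supplementary = TRUE, drop_duplicates = TRUE) {
  if (min_mapq < 0) stop("min_mapq must be >= 0")
  structure(list(min_mapq = min_mapq,
                 excluded_chroms = as.character(excluded_chroms),
                 drop_unmapped = drop_unmapped,
                 drop_secondary = drop_secondary,
                 drop_supplementary = drop_supplementary,
                 drop_duplicates = drop_duplicates),
            class = "filter_policy")
}

#' Read an alignment file into a read table
#'
#' SAM/BAM files are read through Rsamtools (SAM text is converted in a
#' temporary directory first); 1-based POS is converted to the package's
#' 0-based convention and FLAG bits are decoded. BED3/BED6 is accepted as a
#' fallback for deposited interval files: `chromStart` is consumed as the
#' 0-based position, the score column (when present) as the mapping quality;
#' records without a score are treated as passing the MAPQ filter (a message
#' notes this).
#'
#' @param source File path.
#' @param format `"sam"`, `"bam"` or `"bed"`; guessed from the extension by
#'   default.
#' @return A `read_records` data.frame (columns `chrom`, `pos`, `mapq`,
#'   `strand`, `is_unmapped`, `is_secondary`, `is_supplementary`,
#'   `is_duplicate`).
#' @export
read_alignments <- function(source, format = c("auto", "sam", "bam", "bed")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("no such file: ", source)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(source)),
                     sam = "sam", bam = "bam", bed = "bed",
                     stop("cannot guess format of ", source,
                          "; pass format= explicitly"))
  }
  if (format == "bed") return(read_bed_records(source))
  bam <- if (format == "sam") {
    validate_sam(source)
    dest <- tempfile(fileext = ".bam")
    tryCatch(Rsamtools::asBam(source, sub("\\.bam$", "", dest),
                              indexDestination = FALSE),
             error = function(e) stop("malformed SAM file '", source, "': ",
                                      conditionMessage(e), call. = FALSE))
  } else source
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag", "strand"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- rec$flag
  res <- data.frame(
    chrom = as.character(rec$rname),
    pos = as.numeric(rec$pos) - 1,
    mapq = as.integer(rec$mapq),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    is_unmapped = bitwAnd(flag, 4L) > 0L,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    stringsAsFactors = FALSE)
  res$mapq[is.na(res$mapq)] <- 0L
  structure(res, class = c("read_records", "data.frame"))
}

# Structural check of SAM text (htslib's converter only warns on parse
# errors): every alignment line needs the 11 mandatory fields with numeric
# FLAG, POS and MAPQ. Reports the first offending line by number.
validate_sam <- function(source) {
  lines <- readLines(source)
  body <- !startsWith(lines, "@")
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 11L && !anyNA(suppressWarnings(as.numeric(f[c(2, 4, 5)])))
  }, logical(1))
  if (any(!ok)) {
    stop("malformed SAM record at line ", which(body)[which(!ok)[1]],
         " of '", source, "'", call. = FALSE)
  }
  invisible(TRUE)
}

read_bed_records <- function(source) {
  gr <- tryCatch(rtracklayer::import(source, format = "BED"),
                 error = function(e) stop("malformed BED file '", source,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  score <- if ("score" %in% names(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr)$score else rep(NA_real_, length(gr))
  if (anyNA(score)) {
    message("BED records without a score column: treating mapping quality ",
            "as passing any threshold (mapq = 255)")
  }
  mapq <- ifelse(is.na(score), 255L, as.integer(score))
  strand <- as.character(BiocGenerics::strand(gr))
  structure(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = BiocGenerics::start(gr) - 1,  # GRanges is 1-based
    mapq = mapq,
    strand = ifelse(strand == "-", "-", "+"),
    is_unmapped = FALSE, is_secondary = FALSE,
    is_supplementary = FALSE, is_duplicate = FALSE,
    stringsAsFactors = FALSE), class = c("read_records", "data.frame"))
}

#' Does a read pass the filter policy?
#'
#' @param read A one-row `read_records` data.frame (or a full table:
#'   the check is vectorized).
#' @param policy A [filter_policy()].
#' @return Logical vector, `TRUE` for reads that survive.
#' @export
passes_filter <- function(read, policy = filter_policy()) {
  keep <- read$mapq >= policy$min_mapq &
    !(read$chrom %in% policy$excluded_chroms)
  if (policy$drop_unmapped) keep <- keep & !read$is_unmapped
  if (policy$drop_secondary) keep <- keep & !read$is_secondary
  if (policy$drop_supplementary) keep <- keep & !read$is_supplementary
  if (policy$drop_duplicates) keep <- keep & !read$is_duplicate
  keep
}

#' Apply the read filters and record the library size
#'
#' The number of surviving reads is the "filtered reads" denominator used for
#' library-size normalization downstream; it is computed after all filters
#' and before binning.
#'
#' @param reads A `read_records` data.frame.
#' @param policy A [filter_policy()].
#' @return A list with `reads` (the surviving subset, same class) and
#'   `library_size` (their count). Errors if nothing survives, since
#'   normalization would be undefined.
#' @export
filter_stream <- function(reads, policy = filter_policy()) {
  keep <- passes_filter(reads, policy)
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no reads survive the filter policy; library size would be 0")
  attr_rl <- attr(reads, "read_length")
  out <- structure(out, read_length = attr_rl,
                   class = c("read_records", "data.frame"))
  list(reads = out, library_size = nrow(out))
}
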