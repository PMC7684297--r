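#' Profile one sample: filter, bin, normalize, total
#'
#' Runs the per-sample stages of the damage-profiling pipeline on an
#' alignment file (or an already-loaded read table): read-level filtering,
#' first-base binning, library-size normalization with sparse-bin discard,
#' and per-chromosome totalling.
#'
#' @param source Alignment file path, or a `read_records` data.frame.
#' @param genome An `oxog_genome`.
#' @param policy A [filter_policy()]; mitochondrial and other excluded
#'   contigs are removed here.
#' @param bin_size,scale,min_hits See [normalize_and_filter()].
#' @param sample Sample label for the output tables.
#' @param format Passed to [read_alignments()] when `source` is a path.
#' @param five_prime Passed to [bin_counts()].
#' @return List with `profile` (`norm_profile`), `totals` (`chrom_totals`),
#'   `library_size`, and `n_input` (reads before filtering).
#' @export
profile_sample <- function(source, genome, policy = filter_policy(),
                           bin_size = 10000, scale = 1e6, min_hits = 10L,
                           sample = NA_character_, format = "auto",
                           five_prime = FALSE) {
  reads <- if (is.character(source)) read_alignments(source, format) else source
  n_input <- nrow(reads)
  fs <- filter_stream(reads, policy)
  counts <- bin_counts(fs$reads, genome, bin_size = bin_size,
                       library_size = fs$library_size,
                       five_prime = five_prime, sample = sample)
  profile <- normalize_and_filter(counts, scale = scale, min_hits = min_hits)
  list(profile = profile, totals = chrom_totals(profile),
       library_size = fs$library_size, n_input = n_input)
}

#' Simulate a two-condition replicate study at the count level
#'
#' The fast calibration path: per-condition intensity maps (hotspot bins
#' shared between conditions), one multinomial draw per replicate, then
#' normalization, sparse-bin discard and per-chromosome totalling — no reads,
#' no files. Per-replicate seeds are derived deterministically from `seed`.
#'
#' @param genome An `oxog_genome`.
#' @param config A [sim_config()].
#' @param bin_size,scale,min_hits Profiling parameters.
#' @param seed Master seed (defaults to `config$seed`).
#' @param null_mode Draw every condition from the first condition's intensity
#'   map (a true null: conditions differ only by sampling noise).
#' @return Named list of `condition_summary` objects, one per condition.
#' @export
simulate_study <- function(genome, config, bin_size = 10000, scale = 1e6,
                           min_hits = 10L, seed = config$seed,
                           null_mode = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  conditions <- names(config$hotspot_mass)
  maps <- lapply(conditions, function(cond) {
    build_intensity_map(genome, config,
                        if (null_mode) conditions[1] else cond,
                        seed = seed, bin_size = bin_size)
  })
  names(maps) <- conditions
  n_rep <- config$n_replicates
  rep_seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max, length(conditions) * n_rep),
    nrow = n_rep, ncol = length(conditions)))
  summaries <- lapply(seq_along(conditions), function(j) {
    reps <- lapply(seq_len(n_rep), function(i) {
      counts <- simulate_counts(maps[[j]], config$n_reads_per_sample,
                                seed = rep_seeds[i, j])
      chrom_totals(normalize_and_filter(counts, scale = scale,
                                        min_hits = min_hits))
    })
    condition_mean(reps, condition = conditions[j])
  })
  names(summaries) <- conditions
  summaries
}

#' Validate a run configuration
#'
#' @param config A run configuration list (see [run_full_comparison()]).
#' @return Character vector of diagnostics, each naming the offending field;
#'   empty when the configuration is runnable.
#' @export
validate_config <- function(config) {
  diags <- character(0)
  note <- function(msg) diags <<- c(diags, msg)
  for (side in c("condition_a", "condition_b")) {
    files <- config[[side]]
    if (is.null(files) || length(files) < 1L) {
      note(sprintf("%s: need at least one alignment file", side))
    } else {
      for (f in files) if (!file.exists(f))
        note(sprintf("%s: missing input path '%s'", side, f))
    }
  }
  if (!is.null(config$genome) && is.character(config$genome) &&
      !file.exists(config$genome))
    note(sprintf("genome: missing path '%s'", config$genome))
  num_rules <- list(
    bin_size = function(x) x > 0,
    min_mapq = function(x) x >= 0,
    min_hits = function(x) x >= 0,
    scale = function(x) x > 0,
    alpha = function(x) x > 0 && x < 1)
  for (field in names(num_rules)) {
    x <- config[[field]]
    if (!is.null(x) && (!is.numeric(x) || !num_rules[[field]](x)))
      note(sprintf("%s: value %s violates its allowed range", field,
                   paste(x, collapse = ",")))
  }
  if (!is.null(config$alternative) &&
      !config$alternative %in% c("two.sided", "greater", "less"))
    note("alternative: must be two.sided, greater or less")
  diags
}

config_defaults <- function(config) {
  defaults <- list(bin_size = 10000, min_mapq = 20L, min_hits = 10L,
                   scale = 1e6, excluded_chroms = "chrM", alpha = 0.05,
                   alternative = "two.sided", method = "auto",
                   label_a = "A", label_b = "B", format = "auto",
                   out_prefix = NULL)
  for (field in names(defaults)) {
    if (is.null(config[[field]])) config[[field]] <- defaults[[field]]
  }
  config
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file mirroring the fields of [run_full_comparison()]'s
#'   `config`.
#' @return Configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  config_defaults(yaml::read_yaml(path))
}

#' Run the full two-condition comparison
#'
#' End-to-end orchestration: each alignment file is filtered, binned,
#' normalized and totalled; replicate totals are averaged per condition; the
#' condition means are compared with the paired Wilcoxon signed-rank test.
#' When `out_prefix` is set, per-sample bedGraph profiles and totals TSVs, a
#' JSON comparison report and a run log (tunables, input checksums, library
#' sizes) are written, so a run is reproducible from its log alone.
#'
#' @param config List (or YAML via [read_run_config()]) with fields
#'   `condition_a`, `condition_b` (character vectors of alignment files),
#'   `genome` (path to a chromosome table or an `oxog_genome`), and optional
#'   `label_a`, `label_b`, `bin_size`, `min_mapq`, `min_hits`, `scale`,
#'   `excluded_chroms`, `alpha`, `alternative`, `method`, `format`,
#'   `out_prefix`.
#' @return An `oxog_comparison`, with the per-sample results attached as
#'   attribute `samples`.
#' @export
run_full_comparison <- function(config) {
  config <- config_defaults(config)
  diags <- validate_config(config)
  if (length(diags) > 0L)
    stop("invalid configuration:\n  ", paste(diags, collapse = "\n  "))
  genome <- if (inherits(config$genome, "oxog_genome")) config$genome
            else read_genome(config$genome)
  policy <- filter_policy(min_mapq = config$min_mapq,
                          excluded_chroms = config$excluded_chroms)
  out <- config$out_prefix
  run_one <- function(side, label) {
    files <- config[[side]]
    lapply(seq_along(files), function(i) {
      sample_id <- sprintf("%s_rep%d", label, i)
      res <- tryCatch(
        profile_sample(files[i], genome, policy,
                       bin_size = config$bin_size, scale = config$scale,
                       min_hits = config$min_hits, sample = sample_id,
                       format = config$format),
        error = function(e) stop("stage profile[", sample_id, "]: ",
                                 conditionMessage(e), call. = FALSE))
      if (!is.null(out)) {
        write_profile(res$profile, sprintf("%s.%s.bedgraph", out, sample_id))
        write_totals(res$totals, sprintf("%s.%s.totals.tsv", out, sample_id))
      }
      res
    })
  }
  samples_a <- run_one("condition_a", config$label_a)
  samples_b <- run_one("condition_b", config$label_b)
  mean_a <- condition_mean(lapply(samples_a, `[[`, "totals"), config$label_a)
  mean_b <- condition_mean(lapply(samples_b, `[[`, "totals"), config$label_b)
  cmp <- tryCatch(
    compare_conditions(mean_a, mean_b, alpha = config$alpha,
                       method = config$method,
                       alternative = config$alternative),
    error = function(e) stop("stage compare: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.null(out)) {
    report <- list(
      condition_a = config$label_a, condition_b = config$label_b,
      table = cmp$table,
      w_plus = cmp$wilcoxon$w_plus, w_minus = cmp$wilcoxon$w_minus,
      n_pairs_used = cmp$wilcoxon$n_pairs_used,
      p_value = cmp$wilcoxon$p_value, method = cmp$wilcoxon$method,
      alternative = cmp$wilcoxon$alternative,
      alpha = cmp$alpha, significant = cmp$significant)
    jsonlite::write_json(report, sprintf("%s.report.json", out),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    all_files <- c(config$condition_a, config$condition_b)
    log_lines <- c(
      sprintf("tunable\t%s\t%s",
              c("bin_size", "min_mapq", "min_hits", "scale", "alpha",
                "alternative", "method"),
              c(config$bin_size, config$min_mapq, config$min_hits,
                config$scale, config$alpha, config$alternative,
                config$method)),
      sprintf("excluded_chroms\t%s",
              paste(config$excluded_chroms, collapse = ",")),
      sprintf("input\t%s\tmd5=%s", all_files, tools::md5sum(all_files)),
      sprintf("library_size\t%s\t%d",
              vapply(c(samples_a, samples_b),
                     function(s) attr(s$totals, "sample"), ""),
              vapply(c(samples_a, samples_b),
                     function(s) s$library_size, integer(1))),
      sprintf("reads_in\t%s\t%d",
              vapply(c(samples_a, samples_b),
                     function(s) attr(s$totals, "sample"), ""),
              vapply(c(samples_a, samples_b),
                     function(s) s$n_input, integer(1))))
    writeLines(log_lines, sprintf("%s.run.log", out))
  }
  attr(cmp, "samples") <- list(a = samples_a, b = samples_b)
  cmp
}
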