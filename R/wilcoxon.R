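# Exact null distribution of the signed-rank sum W+ over all 2^n sign
# assignments, computed by dynamic programming on doubled ranks (midranks are
# multiples of 1/2, so doubling makes every achievable rank sum an integer).
# Returns counts f[k+1] = #assignments with doubled W+ equal to k.
signed_rank_null_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f
}

prepare_differences <- function(differences) {
  d <- differences[is.finite(differences) & differences != 0]
  if (length(d) == 0L)
    stop("statistic undefined: all differences are zero")
  r <- rank(abs(d))
  list(d = d, r = r, n = length(d),
       w_plus = sum(r[d > 0]), w_minus = sum(r[d < 0]))
}

new_wilcoxon_result <- function(prep, p, alternative, method) {
  structure(list(n_pairs_used = prep$n,
                 w_plus = prep$w_plus, w_minus = prep$w_minus,
                 statistic = min(prep$w_plus, prep$w_minus),
                 p_value = p, alternative = alternative, method = method),
            class = "oxog_wilcoxon")
}

#' Exact Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are removed; tied absolute differences receive midranks.
#' The p-value comes from the exact permutation distribution of the
#' positive-rank sum W+ over all 2^n sign assignments, computed by dynamic
#' programming over achievable rank sums (midranks are handled by doubling
#' the ranks, which makes every rank sum an integer). The two-sided p-value
#' is twice the smaller tail probability, capped at 1.
#'
#' @param differences Numeric vector of paired differences.
#' @param alternative `"two.sided"` (default), `"greater"` (W+ large, i.e.
#'   positive shift) or `"less"`.
#' @return An `oxog_wilcoxon` result: `n_pairs_used`, `w_plus`, `w_minus`,
#'   `statistic = min(w_plus, w_minus)`, `p_value`, `alternative`, `method`.
#' @examples
#' signed_rank_exact(c(1, 2, 3, 4, 5, 6))$p_value  # 2/2^6 = 0.03125
#' @export
signed_rank_exact <- function(differences,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  prep <- prepare_differences(differences)
  ranks2 <- as.integer(round(2 * prep$r))
  f <- signed_rank_null_counts(ranks2)
  total2 <- sum(ranks2)
  w2 <- as.integer(round(2 * prep$w_plus))
  denom <- 2^prep$n
  p_le <- sum(f[seq_len(w2 + 1L)]) / denom
  p_ge <- sum(f[(w2 + 1L):(total2 + 1L)]) / denom
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_le, p_ge)))
  new_wilcoxon_result(prep, p, alternative, "exact")
}

#' Normal-approximation Wilcoxon signed-rank test
#'
#' Large-sample approximation with mean n(n+1)/4 and variance
#' n(n+1)(2n+1)/24 minus the standard correction for tied absolute
#' differences; an optional continuity correction shifts W+ by 1/2 toward
#' the mean. With a single nonzero difference (or a degenerate variance) the
#' method falls back to the exact test.
#'
#' @inheritParams signed_rank_exact
#' @param continuity_correction Apply the 1/2 continuity correction?
#' @return An `oxog_wilcoxon` result with `method = "normal-approximation"`.
#' @export
signed_rank_approx <- function(differences,
                               alternative = c("two.sided", "greater", "less"),
                               continuity_correction = TRUE) {
  alternative <- match.arg(alternative)
  prep <- prepare_differences(differences)
  n <- prep$n
  if (n < 2L) return(signed_rank_exact(differences, alternative))
  ties <- table(prep$r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(signed_rank_exact(differences, alternative))
  mu <- n * (n + 1) / 4
  dev <- prep$w_plus - mu
  cc <- if (continuity_correction) 0.5 else 0
  z_ge <- (dev - cc) / sqrt(sigma2)
  z_le <- (dev + cc) / sqrt(sigma2)
  p <- switch(alternative,
              greater = stats::pnorm(z_ge, lower.tail = FALSE),
              less = stats::pnorm(z_le),
              two.sided = {
                z <- (abs(dev) - cc) / sqrt(sigma2)
                min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
              })
  new_wilcoxon_result(prep, p, alternative, "normal-approximation")
}

#' @export
print.oxog_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank test (%s, %s)\n", x$method, x$alternative))
  cat(sprintf("  n pairs used: %d (zero differences removed)\n", x$n_pairs_used))
  cat(sprintf("  W+ = %g, W- = %g, statistic = %g\n",
              x$w_plus, x$w_minus, x$statistic))
  cat(sprintf("  p-value = %.4g\n", x$p_value))
  invisible(x)
}

#' Compare per-chromosome condition summaries
#'
#' The final inference of the damage-profiling pipeline: a paired Wilcoxon
#' signed-rank test on the per-chromosome differences between two conditions'
#' mean normalized totals (differences are `b - a`, so a positive shift means
#' more signal in `b`).
#'
#' @param a,b `condition_summary` objects (or named numeric vectors) over
#'   identical chromosome sets; `a` is the reference (e.g. wild type).
#' @param alpha Significance threshold (default 0.05).
#' @param method `"auto"` (exact when the number of nonzero differences is at
#'   most `exact_cap`, else normal approximation), `"exact"`, or `"approx"`.
#' @param alternative Sidedness of the test; two-sided by default.
#' @param exact_cap Largest n for which `"auto"` uses the exact distribution.
#' @return An `oxog_comparison`: the per-chromosome table, the
#'   `oxog_wilcoxon` result, `alpha` and the `significant` flag
#'   (`p_value < alpha`).
#' @examples
#' a <- condition_mean(list(structure(setNames(1:6 * 1.0, paste0("chr", 1:6)),
#'                                    class = "chrom_totals")), "wt")
#' b <- condition_mean(list(structure(setNames(1:6 + 2.5, paste0("chr", 1:6)),
#'                                    class = "chrom_totals")), "mut")
#' compare_conditions(a, b)
#' @export
compare_conditions <- function(a, b, alpha = 0.05,
                               method = c("auto", "exact", "approx"),
                               alternative = c("two.sided", "greater", "less"),
                               exact_cap = 25L) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!identical(names(a), names(b)))
    stop("condition summaries have mismatched chromosome sets")
  d <- as.numeric(b) - as.numeric(a)
  n_nonzero <- sum(d != 0)
  if (n_nonzero == 0L) stop("statistic undefined: all differences are zero")
  use_exact <- switch(method, exact = TRUE, approx = FALSE,
                      auto = n_nonzero <= exact_cap)
  wres <- if (use_exact) signed_rank_exact(d, alternative)
          else signed_rank_approx(d, alternative)
  tab <- data.frame(chromosome = names(a),
                    mean_a = as.numeric(a), mean_b = as.numeric(b),
                    difference = d, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 condition_a = attr(a, "condition"),
                 condition_b = attr(b, "condition"),
                 wilcoxon = wres, alpha = alpha,
                 significant = wres$p_value < alpha),
            class = "oxog_comparison")
}

#' @export
print.oxog_comparison <- function(x, ...) {
  lab_a <- if (is.null(x$condition_a) || is.na(x$condition_a)) "A" else x$condition_a
  lab_b <- if (is.null(x$condition_b) || is.na(x$condition_b)) "B" else x$condition_b
  cat(sprintf("Per-chromosome comparison: %s vs %s (%d chromosomes)\n",
              lab_b, lab_a, nrow(x$table)))
  print(x$wilcoxon)
  cat(sprintf("  significant at alpha = %g: %s\n", x$alpha,
              ifelse(x$significant, "yes", "no")))
  invisible(x)
}

#' @export
summary.oxog_comparison <- function(object, ...) {
  md <- stats::median(object$table$difference)
  cat(sprintf("Median per-chromosome difference (b - a): %g\n", md))
  cat(sprintf("Chromosomes with positive difference: %d of %d\n",
              sum(object$table$difference > 0), nrow(object$table)))
  print(object)
  invisible(object)
}

#' @export
plot.oxog_comparison <- function(x, ...) {
  tab <- x$table
  m <- t(as.matrix(tab[, c("mean_a", "mean_b")]))
  colnames(m) <- tab$chromosome
  lab_a <- if (is.null(x$condition_a) || is.na(x$condition_a)) "A" else x$condition_a
  lab_b <- if (is.null(x$condition_b) || is.na(x$condition_b)) "B" else x$condition_b
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = c(lab_a, lab_b),
                    ylab = "normalized hits per chromosome",
                    main = sprintf("Wilcoxon signed-rank p = %.3g",
                                   x$wilcoxon$p_value), ...)
  invisible(x)
}

#' Fold change between two positive quantities
#'
#' @param numerator,denominator Positive values (denominator > 0).
#' @return The plain ratio `numerator / denominator`.
#' @seealso [format_fold()] for the "x-fold increase/decrease" reporting
#'   convention.
#' @export
fold_change <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  numerator / denominator
}

#' Report a fold change in the increase/decrease convention
#'
#' Ratios of at least 1 read "x fold increase"; ratios below 1 are reported
#' as the reciprocal fold decrease.
#'
#' @param ratio A fold change from [fold_change()].
#' @param digits Significant digits in the report.
#' @return Character vector like `"2 fold increase"`.
#' @export
format_fold <- function(ratio, digits = 3) {
  ifelse(ratio >= 1,
         sprintf("%.*g fold increase", digits, ratio),
         sprintf("%.*g fold decrease", digits, 1 / ratio))
}
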