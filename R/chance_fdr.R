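#' By-chance false-discovery rate for a genome-wide scan
#'
#' Ratio of the number of significant results expected by chance under a
#' global null — the number of tests times the significance level — to the
#' number actually observed:
#' `FDR = (n_tests * alpha) / n_significant`.
#'
#' @param n_tests number of tests performed (SNPs x probes).
#' @param alpha per-test significance cutoff, in (0, 1).
#' @param n_significant observed number of significant results.
#' @return the FDR as a fraction. When `n_significant` is 0 the value is
#'   0 if the expected count is also 0, otherwise `NaN` with a warning
#'   (no discoveries to attribute the expected false positives to).
#' @export
#' @examples
#' chance_fdr(214399 * 30128, 1e-5, 389573)   # ~0.166
#' chance_fdr(471394 * 30128, 1e-5, 1214416)  # ~0.117
chance_fdr <- function(n_tests, alpha, n_significant) {
  if (!is.numeric(n_tests) || n_tests < 1) stop("'n_tests' must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly in (0, 1)")
  if (!is.numeric(n_significant) || n_significant < 0)
    stop("'n_significant' must be >= 0")
  expected <- n_tests * alpha
  if (n_significant == 0) {
    if (expected == 0) return(0)
    warning("no significant results but ", format(expected),
            " expected by chance; FDR undefined")
    return(NaN)
  }
  expected / n_significant
}

#' Summarize a trio scan
#'
#' Counts trios significant at `alpha` (analytic p by default), the
#' distinct SNPs and distinct probes among them, and attaches the
#' by-chance FDR — the row shape of the published mediation summary
#' table.
#'
#' @param results trio results data.frame from [scan_trios()].
#' @param alpha significance cutoff applied to the p-values.
#' @param n_tests total number of SNP x probe tests in the scan (needed
#'   because `results` may hold only emitted records).
#' @param p_column which p-value column to threshold, `"p_analytic"`
#'   (default) or `"p_permutation"`.
#' @return object of class `scan_summary`: list with `n_tests`, `alpha`,
#'   `n_significant_trios`, `n_significant_snps`, `n_significant_probes`,
#'   `fdr`.
#' @export
summarize_scan <- function(results, alpha, n_tests,
                           p_column = c("p_analytic", "p_permutation")) {
  p_column <- match.arg(p_column)
  p <- results[[p_column]]
  sig <- !is.na(p) & p < alpha
  n_sig <- sum(sig)
  structure(list(
    n_tests = n_tests,
    alpha = alpha,
    n_significant_trios = n_sig,
    n_significant_snps = length(unique(results$snp_id[sig])),
    n_significant_probes = length(unique(results$probe_id[sig])),
    fdr = suppressWarnings(chance_fdr(n_tests, alpha, n_sig))
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "trio scan summary: %d tests at alpha = %g\n",
    "  significant trios:  %d\n",
    "  distinct SNPs:      %d\n",
    "  distinct probes:    %d\n",
    "  by-chance FDR:      %s\n"),
    x$n_tests, x$alpha, x$n_significant_trios, x$n_significant_snps,
    x$n_significant_probes,
    if (is.nan(x$fdr)) "undefined" else sprintf("%.2f%%", 100 * x$fdr)))
  invisible(x)
}

#' Write a one-row scan summary table
#'
#' @param summary a `scan_summary` object.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_scan_summary <- function(summary, path) {
  stopifnot(inherits(summary, "scan_summary"))
  df <- data.frame(n_tests = summary$n_tests, alpha = summary$alpha,
                   n_sig_trios = summary$n_significant_trios,
                   n_sig_snps = summary$n_significant_snps,
                   n_sig_probes = summary$n_significant_probes,
                   fdr = format_num(summary$fdr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
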