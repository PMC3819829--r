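#' Remove samples with low genotyping call rate
#'
#' Drops samples whose fraction of non-missing genotype calls is strictly
#' below `min_rate` ("less than 95% are removed" in the source cohort, so
#' a sample at exactly the threshold is kept).
#'
#' @param g a [genotype_matrix()].
#' @param min_rate minimum call-rate fraction in (0, 1].
#' @return the filtered [genotype_matrix()].
#' @export
sample_call_rate_filter <- function(g, min_rate = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(min_rate) || min_rate <= 0 || min_rate > 1)
    stop("'min_rate' must lie in (0, 1]")
  rate <- rowMeans(!is.na(g$dose))
  keep <- rate >= min_rate
  if (!any(keep)) stop("all samples fall below the call-rate threshold")
  if (any(!keep))
    .log_msg("sample call-rate filter removed %d sample(s): %s",
             sum(!keep), paste(head(rownames(g$dose)[!keep], 10), collapse = ", "))
  genotype_matrix(g$dose[keep, , drop = FALSE], g$snp_chrom, g$snp_pos)
}

#' Minor allele frequency of a dose vector
#'
#' @param doses numeric vector of gene doses (0/1/2, NA allowed; NAs are
#'   excluded from the denominator).
#' @return min(f, 1 - f) where f is the alternate-allele frequency.
#' @export
#' @examples
#' minor_allele_frequency(c(0, 0, 1, 2))  # 0.375
minor_allele_frequency <- function(doses) {
  doses <- doses[!is.na(doses)]
  if (!length(doses)) stop("all doses missing; MAF undefined")
  f <- sum(doses) / (2 * length(doses))
  min(f, 1 - f)
}

#' SNP-level quality-control filter
#'
#' Applies the three marker filters of the source analysis: SNPs are
#' discarded when their call rate is strictly below `call_rate_min`, when
#' the Hardy-Weinberg exact test is significant at `hwe_alpha` (strictly
#' below), or when the minor allele frequency is strictly below
#' `maf_min`. Statistics are computed on the data as passed in, i.e.
#' after any sample-level filtering.
#'
#' @param g a [genotype_matrix()] (after [sample_call_rate_filter()]).
#' @param call_rate_min minimum per-SNP call rate in (0, 1].
#' @param hwe_alpha HWE significance level in (0, 1).
#' @param maf_min minimum minor allele frequency in \[0, 0.5\].
#' @param hwe_test "exact" (default) or "chisq".
#' @return list with `genotype` (the filtered matrix) and `report`, a
#'   data.frame with one row per input SNP: `snp_id`, `call_rate`, `maf`,
#'   `hwe_p`, `pass`, `fail_reasons` (comma-joined subset of
#'   `call_rate`, `hwe`, `maf`).
#' @export
snp_filter <- function(g, call_rate_min = 0.95, hwe_alpha = 0.001,
                       maf_min = 0.10, hwe_test = c("exact", "chisq")) {
  stopifnot(inherits(g, "genotype_matrix"))
  hwe_test <- match.arg(hwe_test)
  if (call_rate_min <= 0 || call_rate_min > 1) stop("'call_rate_min' in (0,1]")
  if (hwe_alpha <= 0 || hwe_alpha >= 1) stop("'hwe_alpha' in (0,1)")
  if (maf_min < 0 || maf_min > 0.5) stop("'maf_min' in [0,0.5]")
  d <- g$dose
  call_rate <- colMeans(!is.na(d))
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2
  maf <- ifelse(nn > 0, pmin(1, (n1 + 2 * n2) / (2 * pmax(nn, 1L))), NA_real_)
  maf <- pmin(maf, 1 - maf)
  hwe_fun <- if (hwe_test == "exact") hwe_exact_test else hwe_chisq_test
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    if (nn[j] == 0) return(NA_real_)
    hwe_fun(n0[j], n1[j], n2[j])
  }, numeric(1))
  fail_cr <- call_rate < call_rate_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  fail_maf <- is.na(maf) | maf < maf_min
  pass <- !(fail_cr | fail_hwe | fail_maf)
  reasons <- mapply(function(a, b, c2) {
    paste(c(if (a) "call_rate", if (b) "hwe", if (c2) "maf"), collapse = ",")
  }, fail_cr, fail_hwe, fail_maf)
  report <- data.frame(snp_id = colnames(d), call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, pass = pass,
                       fail_reasons = reasons,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!any(pass)) stop("no SNPs survive quality control")
  .log_msg("SNP QC kept %d of %d SNPs", sum(pass), length(pass))
  g2 <- genotype_matrix(d[, pass, drop = FALSE],
                        g$snp_chrom[pass], g$snp_pos[pass])
  list(genotype = g2, report = report)
}

#' Write a SNP QC report
#'
#' @param report the `report` element of [snp_filter()]'s result.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- report
  out$call_rate <- format_num(out$call_rate)
  out$maf <- format_num(out$maf)
  out$hwe_p <- format_num(out$hwe_p)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
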