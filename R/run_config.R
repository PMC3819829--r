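#' Run configuration for the trio/eQTL pipeline
#'
#' Bundles every threshold the pipeline uses, with defaults matching the
#' published analysis of the human liver cohort: trio and eQTL significance
#' at P < 1e-5, hotspots defined as SNPs associated with at least 20
#' transcripts, sample and SNP call-rate minima of 95%, Hardy-Weinberg
#' exact-test alpha of 0.001, and a minor-allele-frequency floor of 10%.
#'
#' @param trio_p_cutoff significance cutoff for mediation trios.
#' @param eqtl_p_cutoff significance cutoff for SNP-transcript eQTL pairs.
#' @param hotspot_min_probes minimum number of significantly associated
#'   transcripts for a SNP to be called a hotspot.
#' @param sample_call_rate_min minimum per-sample genotyping call rate;
#'   samples strictly below it are removed.
#' @param snp_call_rate_min minimum per-SNP call rate; SNPs strictly below
#'   it are removed.
#' @param hwe_alpha Hardy-Weinberg exact-test significance level; SNPs with
#'   HWE p strictly below it are removed.
#' @param maf_min minor-allele-frequency floor; SNPs strictly below it are
#'   removed.
#' @param B number of permutations for the permutation test of the
#'   coefficient product; 0 disables permutation and reports only the
#'   analytic Sobel p-value.
#' @param seed integer seed controlling all randomness.
#' @param cis_window distance in base pairs within which a same-chromosome
#'   SNP-transcript pair is called cis (inclusive bound).
#' @param hotspot_p0 binomial null probability for hotspot enrichment;
#'   defaults to the nominal pair-level cutoff.
#' @param emit_all if TRUE, scans emit every tested pair rather than only
#'   significant ones.
#'
#' @return an object of class `run_config` (a named list).
#' @export
#' @examples
#' cfg <- run_config(B = 1000, seed = 7)
#' cfg$trio_p_cutoff
run_config <- function(trio_p_cutoff = 1e-5,
                       eqtl_p_cutoff = 1e-5,
                       hotspot_min_probes = 20L,
                       sample_call_rate_min = 0.95,
                       snp_call_rate_min = 0.95,
                       hwe_alpha = 0.001,
                       maf_min = 0.10,
                       B = 0L,
                       seed = 1L,
                       cis_window = 1e6,
                       hotspot_p0 = eqtl_p_cutoff,
                       emit_all = FALSE) {
  cfg <- list(
    trio_p_cutoff = as.numeric(trio_p_cutoff),
    eqtl_p_cutoff = as.numeric(eqtl_p_cutoff),
    hotspot_min_probes = as.integer(hotspot_min_probes),
    sample_call_rate_min = as.numeric(sample_call_rate_min),
    snp_call_rate_min = as.numeric(snp_call_rate_min),
    hwe_alpha = as.numeric(hwe_alpha),
    maf_min = as.numeric(maf_min),
    B = as.integer(B),
    seed = as.integer(seed),
    cis_window = as.numeric(cis_window),
    hotspot_p0 = as.numeric(hotspot_p0),
    emit_all = isTRUE(emit_all)
  )
  for (k in c("trio_p_cutoff", "eqtl_p_cutoff", "hwe_alpha", "hotspot_p0")) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1)
      stop(sprintf("'%s' must lie strictly in (0, 1), got %s", k, cfg[[k]]))
  }
  for (k in c("sample_call_rate_min", "snp_call_rate_min")) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] > 1)
      stop(sprintf("'%s' must lie in (0, 1], got %s", k, cfg[[k]]))
  }
  if (!is.finite(cfg$maf_min) || cfg$maf_min < 0 || cfg$maf_min > 0.5)
    stop("'maf_min' must lie in [0, 0.5]")
  if (is.na(cfg$hotspot_min_probes) || cfg$hotspot_min_probes < 1L)
    stop("'hotspot_min_probes' must be a count >= 1")
  if (is.na(cfg$B) || cfg$B < 0L) stop("'B' must be a count >= 0")
  if (!is.finite(cfg$cis_window) || cfg$cis_window < 0)
    stop("'cis_window' must be >= 0 base pairs")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys raise an
#' error, absent keys keep their defaults. `overrides` (typically parsed
#' from command-line flags) take precedence over file values.
#'
#' @param path path to a YAML file, or NULL for pure defaults.
#' @param overrides named list applied on top of the file values.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- modifyList(vals, overrides)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("trioscan run configuration\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
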