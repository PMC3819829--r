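#' Run the full file-based analysis pipeline
#'
#' Stage order: read inputs, align samples, sample-level QC, SNP-level QC,
#' covariate adjustment + inverse-normal transformation, mediation trio
#' scan, by-chance FDR summary, eQTL scan, hotspot detection, hotspot /
#' mediation overlap, and the eQTL map figure. Each stage writes its
#' table into `out_dir`; stages communicate only through files, and a
#' re-run with the same inputs, config and seed reproduces the outputs
#' byte-identically.
#'
#' @param genotype path to the genotype TSV or VCF.
#' @param expression path to the expression TSV.
#' @param phenotype path to the phenotype TSV.
#' @param out_dir output directory (created if needed).
#' @param cfg a [run_config()].
#' @param genotype_format "tsv" or "vcf".
#' @param snp_annotation,probe_annotation optional annotation TSV paths
#'   (`id`, `chrom`, `pos`) for coordinates.
#' @param plot whether to render the eQTL map PNG.
#' @return a `pipeline_manifest`: list of stage names, output paths,
#'   config snapshot, seed and timestamps.
#' @export
run_pipeline <- function(genotype, expression, phenotype, out_dir,
                         cfg = run_config(),
                         genotype_format = c("tsv", "vcf"),
                         snp_annotation = NULL, probe_annotation = NULL,
                         plot = TRUE) {
  genotype_format <- match.arg(genotype_format)
  for (f in c(genotype, expression, phenotype, snp_annotation,
              probe_annotation))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- Sys.time()
  stages <- character(0)
  outputs <- character(0)
  stage <- function(name, fun) {
    .log_msg("stage: %s", name)
    res <- tryCatch(fun(), error = function(err) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(err)), call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }
  snp_ann <- if (!is.null(snp_annotation)) read_annotation(snp_annotation)
  probe_ann <- if (!is.null(probe_annotation)) read_annotation(probe_annotation)

  g <- stage("read_genotype", function()
    read_genotype_matrix(genotype, genotype_format, annotation = snp_ann))
  e <- stage("read_expression", function()
    read_expression_matrix(expression, annotation = probe_ann))
  p <- stage("read_phenotype", function() read_phenotype_table(phenotype))

  al <- stage("align_samples", function() align_samples(g, e, p))
  g <- al$genotype; e <- al$expression; p <- al$phenotype

  g <- stage("sample_qc", function()
    sample_call_rate_filter(g, cfg$sample_call_rate_min))
  # re-align after sample removal
  al <- align_samples(g, e, p)
  g <- al$genotype; e <- al$expression; p <- al$phenotype

  qc <- stage("snp_qc", function()
    snp_filter(g, cfg$snp_call_rate_min, cfg$hwe_alpha, cfg$maf_min))
  g <- qc$genotype
  qc_path <- file.path(out_dir, "snp_qc.tsv")
  write_qc_report(qc$report, qc_path)
  outputs <- c(outputs, snp_qc = qc_path)

  norm <- stage("normalize", function() {
    list(y = preprocess_phenotype(p), e = preprocess_expression(e, p))
  })
  y <- norm$y; en <- norm$e

  trios <- stage("mediation_scan", function() scan_trios(g, en, y, cfg))
  trio_path <- file.path(out_dir, "trios.tsv")
  write_trio_results(trios, trio_path)
  outputs <- c(outputs, trios = trio_path)

  summ <- stage("fdr_summary", function()
    summarize_scan(trios, cfg$trio_p_cutoff,
                   n_tests = ncol(g$dose) * ncol(en$values)))
  summ_path <- file.path(out_dir, "scan_summary.tsv")
  write_scan_summary(summ, summ_path)
  outputs <- c(outputs, scan_summary = summ_path)

  eqtl <- stage("eqtl_scan", function()
    eqtl_scan(g, en, cfg$eqtl_p_cutoff, cis_window = cfg$cis_window))
  eqtl_path <- file.path(out_dir, "eqtl.tsv")
  write_eqtl_records(eqtl, eqtl_path)
  outputs <- c(outputs, eqtl = eqtl_path)

  hot <- stage("hotspots", function()
    detect_hotspots(eqtl, cfg$hotspot_min_probes,
                    n_probes_total = ncol(en$values), p0 = cfg$hotspot_p0,
                    n_snps_tested = ncol(g$dose)))
  hot_path <- file.path(out_dir, "hotspots.tsv")
  write_hotspots(hot, hot_path, g = g)
  outputs <- c(outputs, hotspots = hot_path)

  ov <- stage("overlap", function() {
    sig <- trios[!is.na(trios$p_analytic) &
                   trios$p_analytic < cfg$trio_p_cutoff, , drop = FALSE]
    overlap_hotspots_with_mediation(hot, sig)
  })
  ov_path <- file.path(out_dir, "overlap.tsv")
  write.table(data.frame(n_overlap_trios = ov$n_overlap_trios,
                         n_overlap_snps = ov$n_overlap_snps,
                         n_overlap_probes = ov$n_overlap_probes),
              ov_path, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, overlap = ov_path)

  if (plot && !is.null(g$snp_pos) && !is.null(en$probe_pos)) {
    fig_path <- file.path(out_dir, "eqtl_map.png")
    stage("plot", function() plot_eqtl_map(eqtl, hot, g, en, fig_path))
    outputs <- c(outputs, eqtl_map = fig_path)
  }

  manifest <- structure(list(stages = stages, outputs = outputs,
                             config = unclass(cfg), seed = cfg$seed,
                             started = started, finished = Sys.time()),
                        class = "pipeline_manifest")
  yaml::write_yaml(list(stages = as.list(stages),
                        outputs = as.list(outputs),
                        config = unclass(cfg), seed = cfg$seed),
                   file.path(out_dir, "manifest.yaml"))
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("trioscan pipeline manifest\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  outputs:\n")
  for (i in seq_along(x$outputs))
    cat(sprintf("    %-14s %s\n", names(x$outputs)[i], x$outputs[i]))
  invisible(x)
}
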