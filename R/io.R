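MISSING_TOKENS <- c("NA", "", ".")

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect is the common array convention: SNPs in rows, samples
#' in columns, a header row of sample ids, the first column holding SNP
#' ids, values 0/1/2 with "NA", "" or "." for missing. VCF genotypes are
#' converted to alternate-allele dose (0/0 -> 0, 0/1 -> 1, 1/1 -> 2,
#' ./. -> NA); phased and unphased separators are treated identically and
#' multi-allelic records are skipped with a warning.
#'
#' @param path path to the genotype file.
#' @param format "tsv" or "vcf".
#' @param annotation optional data.frame with columns `id`, `chrom`, `pos`
#'   attaching coordinates to TSV input (VCF carries its own).
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("tsv", "vcf"),
                                 annotation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  g <- switch(format,
              tsv = read_genotype_tsv(path),
              vcf = read_genotype_vcf(path))
  if (!is.null(annotation)) g <- attach_snp_annotation(g, annotation)
  g
}

read_genotype_tsv <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L)
    stop("malformed genotype TSV header in ", path,
         ": need an id column plus at least one sample column")
  snp_ids <- raw[[1L]]
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids in ", path)
  samples <- colnames(raw)[-1L]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  m[m %in% MISSING_TOKENS] <- NA
  bad <- !is.na(m) & !(m %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype token '%s' at SNP '%s', sample '%s' in %s (expected 0/1/2/NA)",
      m[idx[1L], idx[2L]], snp_ids[idx[1L]], samples[idx[2L]], path))
  }
  dose <- t(matrix(as.numeric(m), nrow = nrow(m),
                   dimnames = list(snp_ids, samples)))
  genotype_matrix(dose)
}

read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warning(sum(!bi), " multi-allelic VCF record(s) skipped")
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@fix) == 0L) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose_of <- function(s) {
    if (is.na(s)) return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dose <- t(apply(gt, c(1, 2), dose_of))
  snp_ids <- vcf@fix[, "ID"]
  miss_id <- is.na(snp_ids) | snp_ids == "."
  snp_ids[miss_id] <- paste0(vcf@fix[miss_id, "CHROM"], ":", vcf@fix[miss_id, "POS"])
  colnames(dose) <- snp_ids
  genotype_matrix(dose,
                  snp_chrom = vcf@fix[, "CHROM"],
                  snp_pos = as.numeric(vcf@fix[, "POS"]))
}

#' Read an expression matrix from TSV
#'
#' Probes in rows, samples in columns, header row of sample ids, first
#' column of probe ids; "NA", "" and "." are missing.
#'
#' @inheritParams read_genotype_matrix
#' @param annotation optional data.frame (`id`, `chrom`, `pos`) giving
#'   probe coordinates.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = MISSING_TOKENS)
  if (ncol(raw) < 2L)
    stop("malformed expression TSV header in ", path)
  probe_ids <- as.character(raw[[1L]])
  vals <- t(as.matrix(raw[, -1L, drop = FALSE]))
  colnames(vals) <- probe_ids
  e <- expression_matrix(vals)
  if (!is.null(annotation)) e <- attach_probe_annotation(e, annotation)
  e
}

#' Read a phenotype table from TSV
#'
#' Expects named columns `sample_id`, `trait`, `age`, `sex` (any order;
#' extra columns ignored).
#'
#' @param path path to the tab-delimited phenotype table.
#' @return a [phenotype_table()].
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = MISSING_TOKENS)
  need <- c("sample_id", "trait", "age", "sex")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("phenotype table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  phenotype_table(raw$sample_id, raw$trait, raw$age, raw$sex)
}

#' Read a feature annotation map (id, chrom, pos)
#'
#' @param path tab-delimited file with header columns `id`, `chrom`, `pos`
#'   (1-based positions).
#' @return a data.frame with those three columns.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  a <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                  na.strings = MISSING_TOKENS)
  need <- c("id", "chrom", "pos")
  miss <- setdiff(need, colnames(a))
  if (length(miss))
    stop("annotation ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  data.frame(id = as.character(a$id), chrom = as.character(a$chrom),
             pos = as.numeric(a$pos), stringsAsFactors = FALSE)
}

attach_snp_annotation <- function(g, annotation) {
  i <- match(colnames(g$dose), annotation$id)
  genotype_matrix(g$dose, snp_chrom = annotation$chrom[i],
                  snp_pos = annotation$pos[i])
}

attach_probe_annotation <- function(e, annotation) {
  i <- match(colnames(e$values), annotation$id)
  expression_matrix(e$values, probe_chrom = annotation$chrom[i],
                    probe_pos = annotation$pos[i])
}

TRIO_COLUMNS <- c("snp_id", "probe_id", "beta2", "beta4", "beta5",
                  "sobel_z", "p_analytic", "p_permutation")

#' Write / read mediation trio results
#'
#' Tab-delimited, fixed column order `snp_id, probe_id, beta2, beta4,
#' beta5, sobel_z, p_analytic, p_permutation` (`p_permutation` is NA when
#' permutation was disabled). Numbers are written with 15 significant
#' digits so a round trip reproduces the records to printed precision.
#'
#' @param results data.frame of trio results as produced by [scan_trios()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trio_results <- function(results, path) {
  stopifnot(all(TRIO_COLUMNS %in% colnames(results)))
  out <- results[, TRIO_COLUMNS, drop = FALSE]
  for (k in TRIO_COLUMNS[-(1:2)]) out[[k]] <- format_num(out[[k]])
  ok <- tryCatch(write.table(out, path, sep = "\t", quote = FALSE,
                             row.names = FALSE, col.names = TRUE),
                 error = function(e) stop("cannot write trio results to ",
                                          path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_trio_results
#' @export
read_trio_results <- function(path) {
  if (!file.exists(path)) stop("trio result file not found: ", path)
  out <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = MISSING_TOKENS,
                    colClasses = c(snp_id = "character", probe_id = "character"))
  miss <- setdiff(TRIO_COLUMNS, colnames(out))
  if (length(miss))
    stop("trio result file lacks column(s): ", paste(miss, collapse = ", "))
  out[, TRIO_COLUMNS, drop = FALSE]
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 15, format = "g"))
}

#' Write a dataset in the TSV formats the readers accept
#'
#' Writes `genotype.tsv`, `expression.tsv`, `phenotype.tsv`,
#' `snp_annotation.tsv` and `probe_annotation.tsv` into `dir`, so that a
#' simulated dataset can be run through the file-based pipeline.
#'
#' @param g a [genotype_matrix()].
#' @param e an [expression_matrix()].
#' @param p a [phenotype_table()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_dataset_tsv <- function(g, e, p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotype = file.path(dir, "genotype.tsv"),
             expression = file.path(dir, "expression.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             snp_annotation = file.path(dir, "snp_annotation.tsv"),
             probe_annotation = file.path(dir, "probe_annotation.tsv"))
  gt <- t(g$dose)
  write.table(data.frame(snp_id = rownames(gt), gt, check.names = FALSE),
              paths["genotype"], sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- t(e$values)
  write.table(data.frame(probe_id = rownames(ev),
                         apply(ev, 2, format_num), check.names = FALSE),
              paths["expression"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(p), paths["phenotype"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(g$snp_pos))
    write.table(data.frame(id = colnames(g$dose), chrom = g$snp_chrom,
                           pos = g$snp_pos),
                paths["snp_annotation"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(e$probe_pos))
    write.table(data.frame(id = colnames(e$values), chrom = e$probe_chrom,
                           pos = e$probe_pos),
                paths["probe_annotation"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  paths[file.exists(paths)]
}
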