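#' Genotype matrix container
#'
#' Samples-by-SNPs additive gene-dose matrix (0/1/2 copies of the
#' alternate allele, NA for missing calls) with optional per-SNP genomic
#' coordinates.
#'
#' @param dose numeric matrix, samples in rows, SNPs in columns; rownames
#'   are sample ids, colnames are SNP ids; values must be 0, 1, 2 or NA.
#' @param snp_chrom chromosome label per SNP (optional).
#' @param snp_pos 1-based base-pair position per SNP (optional).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dose, snp_chrom = NULL, snp_pos = NULL) {
  if (!is.matrix(dose)) stop("'dose' must be a matrix (samples x SNPs)")
  if (is.null(rownames(dose)) || is.null(colnames(dose)))
    stop("'dose' needs sample ids as rownames and SNP ids as colnames")
  if (anyDuplicated(rownames(dose))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(dose))) stop("duplicated SNP ids")
  vals <- dose[!is.na(dose)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("gene doses must be 0, 1, 2 or NA")
  storage.mode(dose) <- "double"
  if (!is.null(snp_chrom) && length(snp_chrom) != ncol(dose))
    stop("'snp_chrom' length must equal the number of SNPs")
  if (!is.null(snp_pos) && length(snp_pos) != ncol(dose))
    stop("'snp_pos' length must equal the number of SNPs")
  structure(list(dose = dose,
                 snp_chrom = if (is.null(snp_chrom)) NULL else as.character(snp_chrom),
                 snp_pos = if (is.null(snp_pos)) NULL else as.numeric(snp_pos)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)%s\n",
              nrow(x$dose), ncol(x$dose),
              100 * mean(is.na(x$dose)),
              if (is.null(x$snp_pos)) ", no coordinates" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dose)

sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.genotype_matrix <- function(x) rownames(x$dose)
#' @export
sample_ids.expression_matrix <- function(x) rownames(x$values)
#' @export
sample_ids.phenotype_table <- function(x) x$sample_id

#' Expression matrix container
#'
#' Samples-by-probes continuous expression matrix with optional per-probe
#' genomic coordinates. Probes that are entirely missing are rejected.
#'
#' @param values numeric matrix, samples in rows, probes in columns, with
#'   sample ids as rownames and probe ids as colnames.
#' @param probe_chrom chromosome label per probe (optional).
#' @param probe_pos 1-based base-pair position per probe (optional).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_chrom = NULL, probe_pos = NULL) {
  if (!is.matrix(values)) stop("'values' must be a matrix (samples x probes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs sample ids as rownames and probe ids as colnames")
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated probe ids")
  storage.mode(values) <- "double"
  all_na <- colSums(!is.na(values)) == 0L
  if (any(all_na))
    stop("probe(s) with no observed values: ",
         paste(head(colnames(values)[all_na], 5), collapse = ", "))
  if (!is.null(probe_chrom) && length(probe_chrom) != ncol(values))
    stop("'probe_chrom' length must equal the number of probes")
  if (!is.null(probe_pos) && length(probe_pos) != ncol(values))
    stop("'probe_pos' length must equal the number of probes")
  structure(list(values = values,
                 probe_chrom = if (is.null(probe_chrom)) NULL else as.character(probe_chrom),
                 probe_pos = if (is.null(probe_pos)) NULL else as.numeric(probe_pos)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Phenotype table container
#'
#' One row per sample: a quantitative trait (e.g. enzyme activity) plus
#' the age and sex covariates used for adjustment. Sex is recoded to 0/1
#' from any two-level labelling.
#'
#' @param sample_id character vector of unique sample ids.
#' @param trait numeric trait values (NA allowed; such samples are dropped
#'   at alignment or adjustment).
#' @param age numeric ages in years.
#' @param sex two-level vector (0/1, "M"/"F", ...); recoded to 0/1 by the
#'   sorted order of its levels.
#' @return an object of class `phenotype_table` (a data.frame).
#' @export
phenotype_table <- function(sample_id, trait, age, sex) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicated sample ids")
  n <- length(sample_id)
  if (length(trait) != n || length(age) != n || length(sex) != n)
    stop("'trait', 'age' and 'sex' must each have one value per sample")
  sex <- recode_sex(sex)
  structure(data.frame(sample_id = sample_id,
                       trait = as.numeric(trait),
                       age = as.numeric(age),
                       sex = sex,
                       stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

recode_sex <- function(sex) {
  if (is.numeric(sex)) {
    u <- sort(unique(sex[!is.na(sex)]))
    if (!all(u %in% c(0, 1)) && length(u) > 2)
      stop("'sex' must be two-level; got ", length(u), " levels")
    if (all(u %in% c(0, 1))) return(as.numeric(sex))
  }
  u <- sort(unique(as.character(sex[!is.na(sex)])))
  if (length(u) > 2) stop("'sex' must be two-level; got ", length(u), " levels")
  as.numeric(match(as.character(sex), u) - 1L)
}

#' Restrict genotype, expression and phenotype to their shared samples
#'
#' Intersects the three sample-id sets and returns all three objects
#' restricted to the intersection, in one shared order (the genotype
#' matrix's sample order). The published liver-cohort analysis worked on
#' exactly such an intersection (167 and 180 samples for the two
#' genotyping platforms).
#'
#' @param g a [genotype_matrix()].
#' @param e an [expression_matrix()].
#' @param p a [phenotype_table()].
#' @return list with elements `genotype`, `expression`, `phenotype`.
#' @export
align_samples <- function(g, e, p) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(e, "expression_matrix"),
            inherits(p, "phenotype_table"))
  shared <- intersect(intersect(sample_ids(g), sample_ids(e)), sample_ids(p))
  if (!length(shared)) stop("no samples shared by genotype, expression and phenotype")
  shared <- sample_ids(g)[sample_ids(g) %in% shared]  # deterministic order
  .log_msg("aligned to %d shared samples", length(shared))
  g2 <- genotype_matrix(g$dose[shared, , drop = FALSE], g$snp_chrom, g$snp_pos)
  e2 <- expression_matrix(e$values[shared, , drop = FALSE], e$probe_chrom, e$probe_pos)
  p2 <- p[match(shared, p$sample_id), , drop = FALSE]
  rownames(p2) <- NULL
  class(p2) <- c("phenotype_table", "data.frame")
  list(genotype = g2, expression = e2, phenotype = p2)
}
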