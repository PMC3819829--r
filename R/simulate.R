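#' Specification for a synthetic genotype-expression-phenotype dataset
#'
#' Describes a dataset with known mediation and hotspot architecture.
#' Defaults emulate the shape of the human liver cohort the method was
#' developed on, scaled to desk size: ~200 samples, SNPs in
#' Hardy-Weinberg proportions with MAF drawn uniformly above the 10% QC
#' floor, continuous expression probes, one quantitative enzyme-activity
#' trait, and age/sex covariates with modest (0.2 SD) effects.
#'
#' @param n_samples number of samples.
#' @param n_snps number of SNPs.
#' @param n_probes number of expression probes.
#' @param maf_range interval in (0, 0.5\] from which each SNP's minor
#'   allele frequency is drawn uniformly.
#' @param planted_trios data.frame with columns `snp`, `probe`, `beta2`,
#'   `beta4` (indices and true path coefficients) or NULL.
#' @param hotspot_spec list of `list(snp = i, probes = idx, effect = b)`
#'   entries: SNP i drives each probe in `idx` with slope `b`.
#' @param direct_effects data.frame with columns `snp`, `beta5` (SNP
#'   effects on the trait not through expression) or NULL.
#' @param noise_sd residual standard deviation for expression and trait.
#' @param missing_rate per-entry genotype missingness in \[0, 0.5).
#' @param age_effect trait effect of age, in trait-SD units per
#'   covariate SD.
#' @param sex_effect trait effect of sex, likewise.
#' @param seed integer seed; every generator is reproducible given the
#'   spec and this seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 200L, n_snps = 500L,
                            n_probes = 1000L, maf_range = c(0.1, 0.5),
                            planted_trios = NULL, hotspot_spec = list(),
                            direct_effects = NULL, noise_sd = 1,
                            missing_rate = 0.02, age_effect = 0.2,
                            sex_effect = 0.2, seed = 1L) {
  stopifnot(n_samples >= 4, n_snps >= 1, n_probes >= 1)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("'missing_rate' must lie in [0, 0.5)")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  check_idx <- function(i, nmax, what) {
    if (length(i) && (any(i < 1) || any(i > nmax)))
      stop(sprintf("%s index out of range 1..%d", what, nmax))
  }
  if (!is.null(planted_trios)) {
    stopifnot(all(c("snp", "probe", "beta2", "beta4") %in%
                    colnames(planted_trios)))
    check_idx(planted_trios$snp, n_snps, "planted trio SNP")
    check_idx(planted_trios$probe, n_probes, "planted trio probe")
  }
  for (h in hotspot_spec) {
    stopifnot(all(c("snp", "probes", "effect") %in% names(h)))
    check_idx(h$snp, n_snps, "hotspot SNP")
    check_idx(h$probes, n_probes, "hotspot probe")
  }
  if (!is.null(direct_effects)) {
    stopifnot(all(c("snp", "beta5") %in% colnames(direct_effects)))
    check_idx(direct_effects$snp, n_snps, "direct-effect SNP")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 n_probes = as.integer(n_probes),
                 maf_range = as.numeric(maf_range),
                 planted_trios = planted_trios,
                 hotspot_spec = hotspot_spec,
                 direct_effects = direct_effects,
                 noise_sd = as.numeric(noise_sd),
                 missing_rate = as.numeric(missing_rate),
                 age_effect = as.numeric(age_effect),
                 sex_effect = as.numeric(sex_effect),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a genotype matrix in Hardy-Weinberg proportions
#'
#' Per SNP, a minor allele frequency is drawn uniformly from
#' `spec$maf_range` and doses are drawn binomially (2 trials at the
#' alternate-allele frequency), i.e. the HWE trinomial; missing calls
#' are sprinkled at `spec$missing_rate`. SNPs receive coordinates spread
#' over 22 autosomes.
#'
#' @param spec a [simulation_spec()].
#' @return a [genotype_matrix()] with attribute `maf` holding the true
#'   allele frequencies.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_samples; s <- spec$n_snps
  maf <- runif(s, spec$maf_range[1], spec$maf_range[2])
  dose <- vapply(maf, function(p) rbinom(n, 2L, p), numeric(n))
  if (spec$missing_rate > 0)
    dose[runif(length(dose)) < spec$missing_rate] <- NA_real_
  dimnames(dose) <- list(sprintf("S%03d", seq_len(n)),
                         sprintf("snp%05d", seq_len(s)))
  coords <- .genome_coords(s)
  g <- genotype_matrix(dose, snp_chrom = coords$chrom, snp_pos = coords$pos)
  attr(g, "maf") <- maf
  g
}

# Deterministic feature coordinates: features spread evenly over 22
# autosomes with sizes proportional to the human karyotype scale.
.genome_coords <- function(k, offset = 0) {
  chrom_len <- round(seq(250, 50, length.out = 22)) * 1e6
  chrom <- rep(seq_len(22), length.out = k)
  idx_on <- stats::ave(seq_len(k), chrom, FUN = seq_along)
  per <- tabulate(chrom, 22)
  pos <- round(chrom_len[chrom] * (idx_on - 0.5 + offset) / pmax(per[chrom], 1))
  list(chrom = as.character(chrom), pos = pmax(1, pos))
}

#' Simulate expression and phenotype over a genotype matrix
#'
#' Expression: probe j is the sum of its planted mediation effects
#' (beta2 x dose), any hotspot effects, and N(0, noise_sd^2) noise.
#' Phenotype: the sum of the planted mediator effects (beta4 x probe),
#' direct SNP effects (beta5 x dose), age and sex effects, and noise.
#' Missing doses enter generation at their SNP's mean dose, so a
#' sample's trait does not become missing just because a call failed.
#' Age is uniform on 20-80 years, sex Bernoulli(1/2).
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param spec the same [simulation_spec()].
#' @return list with `expression` (an [expression_matrix()]),
#'   `phenotype` (a [phenotype_table()]) and `truth` (the planted
#'   architecture: trios, hotspots, direct effects, covariate effects),
#'   sufficient to score any scan output against the ground truth.
#' @export
simulate_expression_and_phenotype <- function(g, spec) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "simulation_spec"))
  if (ncol(g$dose) != spec$n_snps || nrow(g$dose) != spec$n_samples)
    stop("genotype matrix does not match the simulation spec")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed + 1L)
  n <- spec$n_samples; P <- spec$n_probes
  dose <- g$dose
  if (anyNA(dose)) {
    mu <- colMeans(dose, na.rm = TRUE)
    na <- which(is.na(dose), arr.ind = TRUE)
    dose[na] <- mu[na[, 2]]
  }
  expr <- matrix(rnorm(n * P, sd = spec$noise_sd), n, P,
                 dimnames = list(rownames(g$dose),
                                 sprintf("probe%05d", seq_len(P))))
  if (!is.null(spec$planted_trios))
    for (i in seq_len(nrow(spec$planted_trios))) {
      tr <- spec$planted_trios[i, ]
      expr[, tr$probe] <- expr[, tr$probe] + tr$beta2 * dose[, tr$snp]
    }
  for (h in spec$hotspot_spec)
    expr[, h$probes] <- expr[, h$probes] + h$effect * dose[, h$snp]
  age <- runif(n, 20, 80)
  sex <- rbinom(n, 1L, 0.5)
  trait <- rnorm(n, sd = spec$noise_sd) +
    spec$age_effect * (age - 50) / sd(age) +
    spec$sex_effect * sex
  if (!is.null(spec$planted_trios))
    for (i in seq_len(nrow(spec$planted_trios))) {
      tr <- spec$planted_trios[i, ]
      trait <- trait + tr$beta4 * expr[, tr$probe]
    }
  if (!is.null(spec$direct_effects))
    for (i in seq_len(nrow(spec$direct_effects))) {
      de <- spec$direct_effects[i, ]
      trait <- trait + de$beta5 * dose[, de$snp]
    }
  coords <- .genome_coords(P, offset = 0.25)
  e <- expression_matrix(expr, probe_chrom = coords$chrom,
                         probe_pos = coords$pos)
  p <- phenotype_table(rownames(g$dose), trait, age, sex)
  truth <- list(planted_trios = spec$planted_trios,
                hotspot_spec = spec$hotspot_spec,
                direct_effects = spec$direct_effects,
                age_effect = spec$age_effect, sex_effect = spec$sex_effect,
                snp_ids = colnames(g$dose), probe_ids = colnames(expr))
  list(expression = e, phenotype = p, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_genotypes()] then
#' [simulate_expression_and_phenotype()].
#'
#' @param spec a [simulation_spec()].
#' @return list with `genotype`, `expression`, `phenotype`, `truth`.
#' @export
simulate_dataset <- function(spec) {
  g <- simulate_genotypes(spec)
  rest <- simulate_expression_and_phenotype(g, spec)
  c(list(genotype = g), rest)
}
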