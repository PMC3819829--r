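# Small in-code fixtures shared across test files.

# genotype matrix from a SNPs-in-columns numeric matrix
gm <- function(m, samples = sprintf("S%d", seq_len(nrow(m))),
               snps = sprintf("snp%d", seq_len(ncol(m))),
               chrom = NULL, pos = NULL) {
  dimnames(m) <- list(samples, snps)
  genotype_matrix(m, snp_chrom = chrom, snp_pos = pos)
}

em <- function(m, samples = sprintf("S%d", seq_len(nrow(m))),
               probes = sprintf("p%d", seq_len(ncol(m))),
               chrom = NULL, pos = NULL) {
  dimnames(m) <- list(samples, probes)
  expression_matrix(m, probe_chrom = chrom, probe_pos = pos)
}

pt <- function(n, trait = rnorm(n), age = runif(n, 20, 80),
               sex = rep_len(0:1, n), ids = sprintf("S%d", seq_len(n))) {
  phenotype_table(ids, trait, age, sex)
}

# Write a SNPs-as-rows genotype TSV from a samples x SNPs matrix.
write_geno_tsv <- function(dose, path) {
  tab <- t(dose)
  df <- data.frame(snp_id = rownames(tab), tab, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent exact-HWE oracle: direct conditional probability of every
# attainable heterozygote count via binomial coefficients.
oracle_hwe <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  n_alt <- 2 * n_alt_hom + n_het
  hs <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  prob <- vapply(hs, function(h) {
    bb <- (n_alt - h) / 2
    choose(n, bb) * choose(n - bb, h) * 2^h / choose(2 * n, n_alt)
  }, numeric(1))
  obs <- prob[hs == n_het]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# Normal-equation OLS oracle (explicit design matrix, solve()).
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = unname(drop(beta)),
       se = unname(sqrt(diag(solve(XtX)) * sigma2)))
}
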