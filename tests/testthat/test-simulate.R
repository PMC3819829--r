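test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  spec <- simulation_spec(n_samples = 10000, n_snps = 1, n_probes = 1,
                          maf_range = c(0.3, 0.3), missing_rate = 0,
                          seed = 31)
  g <- simulate_genotypes(spec)
  freq <- tabulate(g$dose[, 1] + 1, 3) / 10000
  expected <- c(0.49, 0.42, 0.09)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(freq - expected) < 3 * se))
})

test_that("genotype generator is reproducible and respects missing_rate", {
  spec <- simulation_spec(n_samples = 50, n_snps = 40, n_probes = 1,
                          missing_rate = 0, seed = 32)
  g1 <- simulate_genotypes(spec)
  g2 <- simulate_genotypes(spec)
  expect_identical(g1$dose, g2$dose)
  expect_false(anyNA(g1$dose))
  expect_identical(length(unique(g1$snp_chrom)), 22L)

  spec_m <- simulation_spec(n_samples = 200, n_snps = 100, n_probes = 1,
                            missing_rate = 0.1, seed = 32)
  gm_ <- simulate_genotypes(spec_m)
  expect_gt(mean(is.na(gm_$dose)), 0.07)
  expect_lt(mean(is.na(gm_$dose)), 0.13)
})

test_that("expression/phenotype generator is reproducible with full truth", {
  spec <- simulation_spec(
    n_samples = 100, n_snps = 20, n_probes = 30,
    planted_trios = data.frame(snp = 2, probe = 5, beta2 = 0.8, beta4 = 0.8),
    direct_effects = data.frame(snp = 7, beta5 = 0.5),
    hotspot_spec = list(list(snp = 9, probes = 10:14, effect = 0.6)),
    missing_rate = 0.02, seed = 33)
  d1 <- simulate_dataset(spec)
  d2 <- simulate_dataset(spec)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$phenotype$trait, d2$phenotype$trait)
  expect_identical(d1$truth$planted_trios, spec$planted_trios)
  expect_identical(d1$truth$probe_ids[5], "probe00005")

  # planted paths leave visible correlations
  dose <- d1$genotype$dose[, 2]
  keep <- !is.na(dose)
  expect_gt(cor(dose[keep], d1$expression$values[keep, 5]), 0.2)
  expect_gt(cor(d1$expression$values[, 5], d1$phenotype$trait), 0.3)
})

test_that("an all-null simulation carries no planted structure", {
  spec <- simulation_spec(n_samples = 150, n_snps = 40, n_probes = 40,
                          missing_rate = 0, seed = 34)
  ds <- simulate_dataset(spec)
  y <- preprocess_phenotype(ds$phenotype)
  en <- preprocess_expression(ds$expression, ds$phenotype)
  out <- scan_trios(ds$genotype, en, y, run_config(trio_p_cutoff = 1e-4))
  expect_lte(nrow(out), qbinom(0.999, 1600, 1e-4))
})

test_that("simulation spec validates its fields", {
  expect_error(simulation_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_spec(missing_rate = 0.6), "missing_rate")
  expect_error(simulation_spec(
    planted_trios = data.frame(snp = 99, probe = 1, beta2 = 1, beta4 = 1),
    n_snps = 10), "out of range")
  expect_error(simulation_spec(
    hotspot_spec = list(list(snp = 1, probes = 2000, effect = 1)),
    n_probes = 10), "out of range")
})

test_that("written TSVs round-trip through the readers", {
  spec <- simulation_spec(n_samples = 30, n_snps = 8, n_probes = 6,
                          missing_rate = 0.05, seed = 35)
  ds <- simulate_dataset(spec)
  dir <- withr::local_tempdir()
  paths <- write_dataset_tsv(ds$genotype, ds$expression, ds$phenotype, dir)
  g <- read_genotype_matrix(paths[["genotype"]], "tsv",
                            annotation = read_annotation(paths[["snp_annotation"]]))
  e <- read_expression_matrix(paths[["expression"]],
                              annotation = read_annotation(paths[["probe_annotation"]]))
  p <- read_phenotype_table(paths[["phenotype"]])
  expect_identical(g$dose, ds$genotype$dose)
  expect_equal(e$values, ds$expression$values, tolerance = 1e-12)
  expect_identical(g$snp_pos, ds$genotype$snp_pos)
  expect_equal(p$trait, ds$phenotype$trait, tolerance = 1e-12)
  expect_identical(p$sex, ds$phenotype$sex)
})
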