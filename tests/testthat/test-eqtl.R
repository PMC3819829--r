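test_that("eQTL scan emits planted signals and matches simple_regression", {
  set.seed(27)
  n <- 200
  x <- rbinom(n, 2, 0.4)
  probes <- cbind(0.9 * x + rnorm(n, sd = 0.5), rnorm(n), rnorm(n))
  g <- gm(matrix(x, ncol = 1))
  e <- em(probes)
  out <- eqtl_scan(g, e, p_cutoff = 1e-5)
  expect_true(all(out$probe_id == "p1"))
  expect_lt(out$p[1], 1e-5)

  all_out <- eqtl_scan(g, e, emit_all = TRUE)
  expect_identical(nrow(all_out), 3L)
  for (j in 1:3) {
    ref <- simple_regression(x, probes[, j])
    expect_equal(all_out$beta[j], ref$slope, tolerance = 1e-12)
    expect_equal(all_out$p[j], ref$p_value, tolerance = 1e-12)
  }
})

test_that("eQTL scan honours per-SNP missingness", {
  set.seed(28)
  n <- 80
  x <- rbinom(n, 2, 0.4); x[1:6] <- NA
  m <- 0.8 * ifelse(is.na(x), 0, x) + rnorm(n)
  out <- eqtl_scan(gm(matrix(x, ncol = 1)), em(matrix(m, ncol = 1)),
                   emit_all = TRUE)
  ref <- simple_regression(x, m)
  expect_equal(out$beta, ref$slope, tolerance = 1e-12)
  expect_equal(out$p, ref$p_value, tolerance = 1e-12)
})

test_that("cis/trans classification uses same-chromosome inclusive window", {
  g <- gm(matrix(rbinom(9, 2, 0.5), 3, 3), chrom = c("1", "1", "2"),
          pos = c(1000, 5000, 1000))
  e <- em(matrix(rnorm(9), 3, 3), chrom = c("1", "2", "1"),
          pos = c(1000, 1000, 2000))
  rec <- data.frame(snp_id = c("snp1", "snp1", "snp3", "snp1"),
                    probe_id = c("p1", "p2", "p2", "p3"))
  cis <- classify_cis_trans(rec, g, e, window = 1000)
  expect_identical(cis, c(TRUE,   # same chrom, distance 0
                          FALSE,  # different chromosomes
                          TRUE,   # chrom 2, distance 0
                          TRUE))  # distance exactly the window: inclusive
  expect_false(classify_cis_trans(
    data.frame(snp_id = "snp1", probe_id = "p3"), g, e, window = 999))
  g0 <- gm(matrix(rbinom(9, 2, 0.5), 3, 3))
  expect_true(all(is.na(classify_cis_trans(rec, g0, e))))
})

test_that("hotspot detection applies the count floor and exact binomial tail", {
  rec <- data.frame(
    snp_id = c(rep("hot", 25), rep("warm", 19), rep("cold", 2)),
    probe_id = sprintf("p%d", c(1:25, 1:19, 1:2)))
  hs <- detect_hotspots(rec, min_probes = 20, n_probes_total = 30000,
                        p0 = 1e-5, n_snps_tested = 500)
  expect_identical(hs$snp_id, "hot")   # 19 < 20: not a hotspot
  # lgamma summation oracle for the upper binomial tail
  k <- 25; N <- 30000; p0 <- 1e-5
  logterm <- lgamma(N + 1) - lgamma((k:N) + 1) - lgamma(N - (k:N) + 1) +
    (k:N) * log(p0) + (N - (k:N)) * log1p(-p0)
  oracle <- sum(exp(logterm[logterm > -745]))
  expect_equal(hs$enrichment_p_raw, oracle, tolerance = 1e-10)
  expect_equal(hs$enrichment_p_bonferroni, min(1, oracle * 500),
               tolerance = 1e-10)
  expect_equal(hs$enrichment_score, -log10(hs$enrichment_p_bonferroni))
  expect_gte(hs$enrichment_p_bonferroni, hs$enrichment_p_raw)
})

test_that("hotspot count is monotone in the probe floor and p capped at 1", {
  set.seed(29)
  rec <- data.frame(snp_id = rep(sprintf("s%02d", 1:30), times = 1:30),
                    probe_id = "p")
  n_prev <- Inf
  for (floor_ in c(1, 5, 10, 20, 31)) {
    hs <- detect_hotspots(rec, min_probes = floor_, n_probes_total = 50,
                          p0 = 0.5, n_snps_tested = 1e6)
    expect_lte(nrow(hs), n_prev)
    n_prev <- nrow(hs)
    if (nrow(hs)) expect_true(all(hs$enrichment_p_bonferroni <= 1))
  }
  expect_error(detect_hotspots(rec, 20, 50, p0 = 0), "p0")
})

test_that("hotspot-mediation overlap reports the published table triple", {
  trios <- data.frame(snp_id = c("s1", "s1", "s2", "s3"),
                      probe_id = c("p1", "p2", "p1", "p3"))
  none <- overlap_hotspots_with_mediation(
    data.frame(snp_id = character()), trios)
  expect_equal(none$n_overlap_trios, 0L)
  expect_equal(none$n_overlap_snps, 0L)

  all_hot <- overlap_hotspots_with_mediation(
    data.frame(snp_id = c("s1", "s2", "s3")), trios)
  expect_equal(all_hot$n_overlap_trios, 4L)
  expect_equal(all_hot$n_overlap_snps, 3L)
  expect_equal(all_hot$n_overlap_probes, 3L)

  some <- overlap_hotspots_with_mediation(
    data.frame(snp_id = "s1"), trios)
  expect_equal(some$n_overlap_trios, 2L)
  expect_equal(some$n_overlap_probes, 2L)
})

test_that("planted master-regulator architecture is recovered end to end", {
  spec <- simulation_spec(
    n_samples = 200, n_snps = 100, n_probes = 120,
    hotspot_spec = list(list(snp = 42, probes = 11:35, effect = 0.7)),
    planted_trios = data.frame(snp = 42, probe = 11, beta2 = 0.7, beta4 = 0.8),
    missing_rate = 0, seed = 30)
  ds <- simulate_dataset(spec)
  y <- preprocess_phenotype(ds$phenotype)
  en <- preprocess_expression(ds$expression, ds$phenotype)
  rec <- eqtl_scan(ds$genotype, en, p_cutoff = 1e-5)
  hs <- detect_hotspots(rec, min_probes = 20, n_probes_total = 120,
                        p0 = 1e-5, n_snps_tested = 100)
  expect_identical(hs$snp_id, "snp00042")
  trios <- scan_trios(ds$genotype, en, y, run_config(trio_p_cutoff = 1e-5))
  ov <- overlap_hotspots_with_mediation(hs, trios)
  expect_equal(ov$n_overlap_snps, 1L)
  expect_gte(ov$n_overlap_probes, 1L)
  expect_true(all(ov$trios$snp_id == "snp00042"))
})
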