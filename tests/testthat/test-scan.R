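test_that("a 1x1 scan reduces exactly to the single-trio path", {
  set.seed(20)
  n <- 50
  x <- rbinom(n, 2, 0.4); m <- rnorm(n, 0.6 * x); y <- rnorm(n, 0.7 * m)
  g <- gm(matrix(x, ncol = 1))
  e <- em(matrix(m, ncol = 1))
  cfg <- run_config(emit_all = TRUE)
  out <- scan_trios(g, e, y, cfg)
  ref <- mediation_test(x, m, y)
  expect_identical(nrow(out), 1L)
  expect_equal(out$beta2, ref$fit_xm$slope, tolerance = 1e-12)
  expect_equal(out$beta4, ref$fit_y$slope_m, tolerance = 1e-12)
  expect_equal(out$beta5, ref$beta5, tolerance = 1e-12)
  expect_equal(out$sobel_z, ref$sobel$z, tolerance = 1e-12)
  expect_equal(out$p_analytic, ref$sobel$p_analytic, tolerance = 1e-12)
})

test_that("scan recovers a planted mediated trio as its top hit", {
  spec <- simulation_spec(
    n_samples = 200, n_snps = 50, n_probes = 50,
    planted_trios = data.frame(snp = 17, probe = 31,
                               beta2 = 0.8, beta4 = 0.8),
    missing_rate = 0, seed = 21)
  ds <- simulate_dataset(spec)
  y <- preprocess_phenotype(ds$phenotype)
  en <- preprocess_expression(ds$expression, ds$phenotype)
  out <- scan_trios(ds$genotype, en, y, run_config(emit_all = TRUE))
  expect_identical(nrow(out), 2500L)
  top <- out[which.min(out$p_analytic), ]
  expect_identical(top$snp_id, "snp00017")
  expect_identical(top$probe_id, "probe00031")
})

test_that("scan output is invariant to SNP-block size, including permutation p", {
  spec <- simulation_spec(n_samples = 80, n_snps = 23, n_probes = 15,
                          planted_trios = data.frame(snp = 3, probe = 2,
                                                     beta2 = 1, beta4 = 1),
                          missing_rate = 0.03, seed = 22)
  ds <- simulate_dataset(spec)
  y <- preprocess_phenotype(ds$phenotype)
  en <- preprocess_expression(ds$expression, ds$phenotype)
  cfg <- run_config(trio_p_cutoff = 0.01, B = 99, seed = 9)
  outs <- lapply(c(1L, 7L, 64L), function(bs)
    scan_trios(ds$genotype, en, y, cfg, block_size = bs))
  expect_identical(outs[[1]], outs[[2]])
  expect_identical(outs[[1]], outs[[3]])
  expect_true(any(!is.na(outs[[1]]$p_permutation)))
})

test_that("null scans emit significant trios at the nominal rate", {
  spec <- simulation_spec(n_samples = 150, n_snps = 100, n_probes = 100,
                          missing_rate = 0, seed = 23)
  ds <- simulate_dataset(spec)
  y <- preprocess_phenotype(ds$phenotype)
  en <- preprocess_expression(ds$expression, ds$phenotype)
  out <- scan_trios(ds$genotype, en, y, run_config(trio_p_cutoff = 1e-3))
  # 10,000 tests at nominal 1e-3 (Sobel is conservative, so <= upper envelope)
  expect_lte(nrow(out), qbinom(0.995, 10000, 1e-3))
})

test_that("scan validates dimensions and handles missing data per trio", {
  g <- gm(matrix(rbinom(40, 2, 0.5), 20, 2))
  e <- em(matrix(rnorm(30), 15, 2))
  expect_error(scan_trios(g, e, rnorm(20)), "dimension mismatch")

  set.seed(24)
  n <- 60
  x <- rbinom(n, 2, 0.4); x[c(2, 9)] <- NA
  m <- 0.9 * ifelse(is.na(x), 0, x) + rnorm(n); m[5] <- NA
  y <- rnorm(n)
  g <- gm(matrix(x, ncol = 1)); e <- em(matrix(m, ncol = 1))
  out <- scan_trios(g, e, y, run_config(emit_all = TRUE))
  ref <- mediation_test(x, m, y)
  expect_equal(out$beta2, ref$fit_xm$slope, tolerance = 1e-12)
  expect_equal(out$p_analytic, ref$sobel$p_analytic, tolerance = 1e-12)
})

test_that("optional causal-steps gate restricts emission", {
  spec <- simulation_spec(n_samples = 150, n_snps = 10, n_probes = 10,
                          planted_trios = data.frame(snp = 1, probe = 1,
                                                     beta2 = 1, beta4 = 1),
                          missing_rate = 0, seed = 25)
  ds <- simulate_dataset(spec)
  y <- preprocess_phenotype(ds$phenotype)
  en <- preprocess_expression(ds$expression, ds$phenotype)
  cfg <- run_config(emit_all = TRUE)
  free <- scan_trios(ds$genotype, en, y, cfg)
  gated <- scan_trios(ds$genotype, en, y, cfg, gate_steps = TRUE)
  expect_lt(nrow(gated), nrow(free))
  # the planted trio passes the zero-order screens
  expect_true(any(gated$snp_id == "snp00001" & gated$probe_id == "probe00001"))
  key <- function(d) paste(d$snp_id, d$probe_id)
  expect_true(all(key(gated) %in% key(free)))
})
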