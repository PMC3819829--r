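# Per-SNP vectorized OLS kernels. All arithmetic is per SNP (vector and
# matrix-vector operations across probes only), so scan output is
# bit-identical whatever SNP-block size is used for chunking.

# Centered expression cache for samples without missingness.
.center_expression <- function(M) {
  cm <- colMeans(M)
  Mc <- M - rep(cm, each = nrow(M))
  list(Mc = Mc, smm = colSums(Mc * Mc))
}

#' Genome-wide mediation scan over SNP x probe trios
#'
#' For every SNP x probe pair, fits the exposure-to-mediator regression
#' (transcript on gene dose) and the two-predictor outcome regression
#' (phenotype on transcript plus gene dose), forms the Sobel test of the
#' indirect effect, and optionally adds a permutation p-value for pairs
#' whose analytic p falls below the significance cutoff
#' (screen-then-permute). Missingness is handled complete-case per trio.
#'
#' Processing is chunked in SNP blocks for progress reporting and memory
#' bounding; results are independent of the block size and emitted in
#' deterministic SNP-major order. Permutation seeds are derived per trio
#' from (`cfg$seed`, SNP index, probe index), so permutation p-values do
#' not depend on chunking either.
#'
#' @param g a [genotype_matrix()], QC'd and sample-aligned.
#' @param e an [expression_matrix()], covariate-adjusted, normalized and
#'   sample-aligned.
#' @param y numeric phenotype vector (adjusted and normalized), one value
#'   per sample in the shared sample order.
#' @param cfg a [run_config()]; uses `trio_p_cutoff`, `B`, `seed`,
#'   `emit_all`.
#' @param block_size SNPs per processing block.
#' @param gate_steps if TRUE, additionally require the zero-order
#'   regressions (phenotype on dose; phenotype on transcript) to be
#'   significant at `gate_alpha` before a trio is emitted — the classic
#'   causal-steps screen. Off by default: the indirect-effect test itself
#'   is the significance criterion.
#' @param gate_alpha significance level for the optional causal-steps gate.
#' @return data.frame with columns `snp_id`, `probe_id`, `beta2`,
#'   `beta4`, `beta5`, `sobel_z`, `p_analytic`, `p_permutation`.
#' @export
scan_trios <- function(g, e, y, cfg = run_config(), block_size = 64L,
                       gate_steps = FALSE, gate_alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(e, "expression_matrix"))
  n <- nrow(g$dose)
  if (nrow(e$values) != n || length(y) != n)
    stop(sprintf("dimension mismatch: %d genotype, %d expression, %d phenotype samples",
                 n, nrow(e$values), length(y)))
  if (!is.null(names(y)) && !identical(names(y), rownames(g$dose)))
    stop("phenotype sample names do not match genotype sample order")
  y <- as.numeric(y)
  P <- ncol(e$values)
  snp_ids <- colnames(g$dose)
  probe_ids <- colnames(e$values)
  e_complete <- !anyNA(e$values)
  y_complete <- !anyNA(y)
  cache <- if (e_complete && y_complete) .center_expression(e$values) else NULL
  yc_all <- if (y_complete) y - mean(y) else NULL
  smy_all <- if (!is.null(cache)) as.vector(crossprod(cache$Mc, yc_all)) else NULL
  syy_all <- if (y_complete) sum(yc_all * yc_all) else NULL

  blocks <- split(seq_len(ncol(g$dose)),
                  ceiling(seq_len(ncol(g$dose)) / max(1L, block_size)))
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    rows <- lapply(blocks[[bi]], function(j) {
      .scan_one_snp(j, g, e, y, cfg, cache, smy_all, syy_all,
                    snp_ids, probe_ids, gate_steps, gate_alpha)
    })
    out[[bi]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (bi %% 10L == 0L)
      .log_msg("trio scan: %d / %d SNP blocks done", bi, length(blocks))
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(snp_id = character(), probe_id = character(),
                      beta2 = numeric(), beta4 = numeric(), beta5 = numeric(),
                      sobel_z = numeric(), p_analytic = numeric(),
                      p_permutation = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.scan_one_snp <- function(j, g, e, y, cfg, cache, smy_all, syy_all,
                          snp_ids, probe_ids, gate_steps, gate_alpha) {
  x <- g$dose[, j]
  x_complete <- !anyNA(x)
  if (!is.null(cache) && x_complete) {
    keep <- seq_along(x)
    Mc <- cache$Mc; smm <- cache$smm
    yc <- y - mean(y); smy <- smy_all; syy <- syy_all
  } else {
    keep <- which(!is.na(x) & !is.na(y))
    if (length(keep) < 4L) return(NULL)
    M <- e$values[keep, , drop = FALSE]
    if (anyNA(M)) {
      # probes with their own missingness fall back to scalar fits
      return(.scan_one_snp_slow(j, x, e, y, cfg, snp_ids, probe_ids,
                                gate_steps, gate_alpha))
    }
    cc <- .center_expression(M)
    Mc <- cc$Mc; smm <- cc$smm
    yk <- y[keep]; yc <- yk - mean(yk)
    smy <- as.vector(crossprod(Mc, yc))
    syy <- sum(yc * yc)
    x <- x[keep]
  }
  n <- length(keep)
  if (n < 4L) return(NULL)
  xv <- if (x_complete && !is.null(cache)) x else x
  xc <- xv - mean(xv)
  sxx <- sum(xc * xc)
  if (sxx == 0) return(NULL)
  sxm <- as.vector(crossprod(Mc, xc))
  sxy <- sum(xc * yc)
  b2 <- sxm / sxx
  se2 <- sqrt(pmax(smm - b2 * sxm, 0) / (n - 2) / sxx)
  det <- sxx * smm - sxm * sxm
  valid <- smm > 0 & det > 1e-12 * sxx * smm
  det[!valid] <- NA_real_
  b4 <- (sxx * smy - sxm * sxy) / det
  b5 <- (smm * sxy - sxm * smy) / det
  rss <- pmax(syy - b4 * smy - b5 * sxy, 0)
  sig2 <- rss / (n - 3)
  se4 <- sqrt(sig2 * sxx / det)
  se5 <- sqrt(sig2 * smm / det)
  ind <- b2 * b4
  se_ind <- sqrt(b2^2 * se4^2 + b4^2 * se2^2)
  z <- ifelse(se_ind > 0, ind / se_ind,
              ifelse(ind == 0, 0, sign(ind) * Inf))
  p <- ifelse(is.finite(z), 2 * pnorm(-abs(z)), ifelse(z == 0, 1, 0))
  keep_probe <- valid & !is.na(p)
  if (gate_steps) {
    f1 <- tryCatch(simple_regression(xv, if (is.null(cache)) y[keep] else y),
                   error = function(err) NULL)
    p1 <- if (is.null(f1)) 1 else f1$p_value
    t3 <- ifelse(smm > 0 & syy > 0,
                 smy / sqrt(pmax(smm * syy - smy^2, 1e-300) / (n - 2)), 0)
    p3 <- 2 * pt(-abs(t3), df = n - 2)
    keep_probe <- keep_probe & (p1 < gate_alpha) & (p3 < gate_alpha)
  }
  emit <- keep_probe & (cfg$emit_all | p < cfg$trio_p_cutoff)
  if (!any(emit)) return(NULL)
  idx <- which(emit)
  p_perm <- rep(NA_real_, length(idx))
  if (cfg$B > 0L) {
    for (k in seq_along(idx)) {
      pr <- idx[k]
      if (p[pr] < cfg$trio_p_cutoff) {
        nul <- permutation_null(g$dose[, j], e$values[, pr], y,
                                B = cfg$B, seed = .trio_seed(cfg$seed, j, pr))
        p_perm[k] <- permutation_pvalue(ind[pr], nul)
      }
    }
  }
  data.frame(snp_id = snp_ids[j], probe_id = probe_ids[idx],
             beta2 = b2[idx], beta4 = b4[idx], beta5 = b5[idx],
             sobel_z = z[idx], p_analytic = p[idx], p_permutation = p_perm,
             stringsAsFactors = FALSE)
}

# Scalar fallback for probes carrying their own missing values.
.scan_one_snp_slow <- function(j, x, e, y, cfg, snp_ids, probe_ids,
                               gate_steps, gate_alpha) {
  rows <- lapply(seq_len(ncol(e$values)), function(pr) {
    m <- e$values[, pr]
    res <- tryCatch(mediation_test(x, m, y), error = function(err) NULL)
    if (is.null(res)) return(NULL)
    p <- res$sobel$p_analytic
    if (gate_steps) {
      f1 <- tryCatch(simple_regression(x, y), error = function(err) NULL)
      f3 <- tryCatch(simple_regression(m, y), error = function(err) NULL)
      if (is.null(f1) || is.null(f3) ||
          f1$p_value >= gate_alpha || f3$p_value >= gate_alpha)
        return(NULL)
    }
    if (!cfg$emit_all && p >= cfg$trio_p_cutoff) return(NULL)
    p_perm <- NA_real_
    if (cfg$B > 0L && p < cfg$trio_p_cutoff) {
      nul <- permutation_null(x, m, y, B = cfg$B,
                              seed = .trio_seed(cfg$seed, j, pr))
      p_perm <- permutation_pvalue(res$sobel$indirect, nul)
    }
    data.frame(snp_id = snp_ids[j], probe_id = probe_ids[pr],
               beta2 = res$fit_xm$slope, beta4 = res$fit_y$slope_m,
               beta5 = res$beta5, sobel_z = res$sobel$z,
               p_analytic = p, p_permutation = p_perm,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Deterministic per-trio permutation seed; independent of block layout.
.trio_seed <- function(seed, snp_idx, probe_idx) {
  as.integer((as.numeric(seed) + snp_idx * 100003 + probe_idx * 7919) %%
               2147483629) + 1L
}
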