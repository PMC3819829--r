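#' Genome-wide eQTL scan
#'
#' Per SNP x probe pair, simple linear regression of transcript level on
#' gene dose; records with p below the cutoff are returned (all records
#' with `emit_all = TRUE`). The per-pair model and p-value are identical
#' to [simple_regression()] on the same pair. When coordinates are
#' present each record is classified cis or trans via
#' [classify_cis_trans()].
#'
#' @param g a [genotype_matrix()], QC'd and sample-aligned.
#' @param e an [expression_matrix()], adjusted/normalized and aligned.
#' @param p_cutoff per-pair significance cutoff.
#' @param emit_all if TRUE, return every tested pair.
#' @param cis_window base-pair window for the cis call (inclusive).
#' @return data.frame with columns `snp_id`, `probe_id`, `beta`, `p`,
#'   `cis` (logical; NA when coordinates are unavailable).
#' @export
eqtl_scan <- function(g, e, p_cutoff = 1e-5, emit_all = FALSE,
                      cis_window = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(e, "expression_matrix"))
  n <- nrow(g$dose)
  if (nrow(e$values) != n)
    stop(sprintf("dimension mismatch: %d genotype vs %d expression samples",
                 n, nrow(e$values)))
  snp_ids <- colnames(g$dose)
  probe_ids <- colnames(e$values)
  e_complete <- !anyNA(e$values)
  cache <- if (e_complete) .center_expression(e$values) else NULL
  out <- vector("list", ncol(g$dose))
  for (j in seq_len(ncol(g$dose))) {
    x <- g$dose[, j]
    if (!anyNA(x) && !is.null(cache)) {
      Mc <- cache$Mc; smm <- cache$smm; nj <- n
    } else {
      keep <- which(!is.na(x))
      if (length(keep) < 3L) next
      M <- e$values[keep, , drop = FALSE]
      if (anyNA(M)) {
        out[[j]] <- .eqtl_one_snp_slow(j, x, e, p_cutoff, emit_all,
                                       snp_ids, probe_ids)
        next
      }
      cc <- .center_expression(M)
      Mc <- cc$Mc; smm <- cc$smm
      x <- x[keep]; nj <- length(keep)
    }
    xc <- x - mean(x)
    sxx <- sum(xc * xc)
    if (sxx == 0) next
    sxm <- as.vector(crossprod(Mc, xc))
    beta <- sxm / sxx
    rss <- pmax(smm - beta * sxm, 0)
    se <- sqrt(rss / (nj - 2) / sxx)
    tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
    p <- ifelse(is.finite(tval), 2 * pt(-abs(tval), df = nj - 2),
                ifelse(tval == 0, 1, 0))
    emit <- if (emit_all) rep(TRUE, length(p)) else p < p_cutoff
    if (!any(emit)) next
    idx <- which(emit)
    out[[j]] <- data.frame(snp_id = snp_ids[j], probe_id = probe_ids[idx],
                           beta = beta[idx], p = p[idx],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(snp_id = character(), probe_id = character(),
                      beta = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$cis <- classify_cis_trans(out, g, e, window = cis_window)
  out
}

.eqtl_one_snp_slow <- function(j, x, e, p_cutoff, emit_all,
                               snp_ids, probe_ids) {
  rows <- lapply(seq_len(ncol(e$values)), function(pr) {
    fit <- tryCatch(simple_regression(x, e$values[, pr]),
                    error = function(err) NULL)
    if (is.null(fit)) return(NULL)
    if (!emit_all && fit$p_value >= p_cutoff) return(NULL)
    data.frame(snp_id = snp_ids[j], probe_id = probe_ids[pr],
               beta = fit$slope, p = fit$p_value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Classify SNP-probe pairs as cis or trans
#'
#' A pair is cis when SNP and probe sit on the same chromosome no more
#' than `window` base pairs apart (inclusive bound); otherwise trans.
#' Pairs with missing coordinates are classified NA with a message.
#'
#' @param records data.frame with `snp_id` and `probe_id` columns.
#' @param g a [genotype_matrix()] carrying SNP coordinates.
#' @param e an [expression_matrix()] carrying probe coordinates.
#' @param window base-pair distance bound, inclusive.
#' @return logical vector: TRUE cis, FALSE trans, NA unknown.
#' @export
classify_cis_trans <- function(records, g, e, window = 1e6) {
  if (!nrow(records)) return(logical(0))
  if (is.null(g$snp_pos) || is.null(e$probe_pos))
    return(rep(NA, nrow(records)))
  si <- match(records$snp_id, colnames(g$dose))
  pi <- match(records$probe_id, colnames(e$values))
  sc <- g$snp_chrom[si]; sp <- g$snp_pos[si]
  pc <- e$probe_chrom[pi]; pp <- e$probe_pos[pi]
  cis <- (sc == pc) & (abs(sp - pp) <= window)
  if (anyNA(cis))
    .log_msg("%d pair(s) lack coordinates; cis status unknown", sum(is.na(cis)))
  cis
}

#' Detect trans-eQTL hotspots by exact binomial enrichment
#'
#' A hotspot is a SNP significantly associated with at least
#' `min_probes` transcripts. For each such SNP with k significant probes
#' the enrichment p-value is the exact upper-tail binomial probability
#' P(K >= k) with size `n_probes_total` and success probability `p0`,
#' Bonferroni-corrected by the number of SNPs tested in the scan; the
#' enrichment score is -log10 of the corrected p (capped at 1).
#'
#' @param records significant eQTL records (already filtered at the
#'   pair-level cutoff), as from [eqtl_scan()].
#' @param min_probes minimum number of associated transcripts (the
#'   published analysis used 20).
#' @param n_probes_total number of probes in the scan.
#' @param p0 binomial null probability; defaults to the nominal
#'   pair-level cutoff.
#' @param n_snps_tested Bonferroni family size: the number of SNPs in the
#'   whole scan. Defaults to the number of distinct SNPs in `records`,
#'   but the genome-wide family should be passed when known.
#' @return data.frame with one row per hotspot: `snp_id`,
#'   `n_significant_probes`, `enrichment_p_raw`, `enrichment_p_bonferroni`,
#'   `enrichment_score`, ordered by decreasing probe count.
#' @export
detect_hotspots <- function(records, min_probes = 20L, n_probes_total,
                            p0 = 1e-5,
                            n_snps_tested = length(unique(records$snp_id))) {
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly in (0, 1)")
  if (min_probes < 1L) stop("'min_probes' must be >= 1")
  if (missing(n_probes_total) || n_probes_total < 1)
    stop("'n_probes_total' (probes in the scan) is required")
  counts <- table(records$snp_id)
  counts <- counts[counts >= min_probes]
  if (!length(counts))
    return(data.frame(snp_id = character(), n_significant_probes = integer(),
                      enrichment_p_raw = numeric(),
                      enrichment_p_bonferroni = numeric(),
                      enrichment_score = numeric(), stringsAsFactors = FALSE))
  k <- as.integer(counts)
  p_raw <- pbinom(k - 1L, size = n_probes_total, prob = p0,
                  lower.tail = FALSE)
  p_bonf <- pmin(1, p_raw * max(1L, n_snps_tested))
  out <- data.frame(snp_id = names(counts), n_significant_probes = k,
                    enrichment_p_raw = p_raw,
                    enrichment_p_bonferroni = p_bonf,
                    enrichment_score = -log10(p_bonf),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_significant_probes, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap eQTL hotspots with significant mediation trios
#'
#' Retains the significant trios whose SNP is a hotspot and reports the
#' trio count, the number of distinct hotspot SNPs involved and the
#' number of distinct mediator probes — the triple reported in the
#' published overlap table.
#'
#' @param hotspots hotspot table from [detect_hotspots()].
#' @param trios significant trio records (pre-filtered at the trio
#'   cutoff), as from [scan_trios()].
#' @return list with `trios` (the overlapping records),
#'   `n_overlap_trios`, `n_overlap_snps`, `n_overlap_probes`,
#'   `hotspot_snp_ids`.
#' @export
overlap_hotspots_with_mediation <- function(hotspots, trios) {
  hot_ids <- unique(hotspots$snp_id)
  sel <- trios$snp_id %in% hot_ids
  sub <- trios[sel, , drop = FALSE]
  rownames(sub) <- NULL
  list(trios = sub,
       n_overlap_trios = nrow(sub),
       n_overlap_snps = length(unique(sub$snp_id)),
       n_overlap_probes = length(unique(sub$probe_id)),
       hotspot_snp_ids = hot_ids)
}

#' Write eQTL records / hotspot tables
#'
#' @param records data.frame from [eqtl_scan()].
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_eqtl_records <- function(records, path) {
  out <- records
  out$beta <- format_num(out$beta)
  out$p <- format_num(out$p)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqtl_records
#' @param hotspots data.frame from [detect_hotspots()].
#' @param g optional [genotype_matrix()] supplying SNP coordinates for
#'   the table.
#' @export
write_hotspots <- function(hotspots, path, g = NULL) {
  out <- hotspots
  if (!is.null(g) && !is.null(g$snp_pos)) {
    i <- match(out$snp_id, colnames(g$dose))
    out <- cbind(out[, "snp_id", drop = FALSE],
                 chrom = g$snp_chrom[i], pos = g$snp_pos[i],
                 out[, setdiff(colnames(out), "snp_id"), drop = FALSE])
  }
  for (k in intersect(c("enrichment_p_raw", "enrichment_p_bonferroni",
                        "enrichment_score"), colnames(out)))
    out[[k]] <- format_num(out[[k]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
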