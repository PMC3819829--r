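#' eQTL map figure: association scatter, per-SNP counts, enrichment track
#'
#' Three stacked panels over a shared genome axis (autosomes 1-22 laid
#' end to end by cumulative base-pair offset): the bottom panel scatters
#' each significant SNP-probe pair at (SNP position, probe position)
#' with darker grey for smaller p (dark means more significant, cis
#' pairs fall on the diagonal); the middle panel draws one circle per
#' SNP with radius proportional to its count of significant probes; the
#' top panel is the hotspot enrichment-score track,
#' -log10(Bonferroni-corrected binomial p).
#'
#' @param records significant eQTL records from [eqtl_scan()].
#' @param hotspots hotspot table from [detect_hotspots()] (may have zero
#'   rows).
#' @param g a [genotype_matrix()] with SNP coordinates.
#' @param e an [expression_matrix()] with probe coordinates.
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
plot_eqtl_map <- function(records, hotspots, g, e, path,
                          width = 1200, height = 1200) {
  if (is.null(g$snp_pos) || is.null(e$probe_pos))
    stop("plotting needs SNP and probe coordinates")
  off <- .chrom_offsets(c(g$snp_chrom, e$probe_chrom))
  snp_x <- off$offset[g$snp_chrom] + g$snp_pos
  names(snp_x) <- colnames(g$dose)
  probe_y <- off$offset[e$probe_chrom] + e$probe_pos
  names(probe_y) <- colnames(e$values)
  xlim <- c(0, off$total)

  png(path, width = width, height = height)
  on.exit(dev.off(), add = TRUE)
  layout(matrix(3:1, ncol = 1), heights = c(1, 1, 3))
  par(mar = c(0.5, 5, 0.5, 1), oma = c(4, 0, 2, 0))

  # bottom: scatter
  plot(NA, xlim = xlim, ylim = c(0, off$total), xlab = "", ylab = "Gene position",
       xaxt = "n", yaxt = "n")
  axis(2, at = off$mid, labels = names(off$mid), las = 2, cex.axis = 0.7)
  abline(v = off$bounds, h = off$bounds, col = "grey90")
  if (nrow(records)) {
    shade <- .p_to_gray(records$p)
    points(snp_x[records$snp_id], probe_y[records$probe_id],
           pch = 15, cex = 0.4, col = shade)
  } else {
    warning("no significant eQTL records: empty map plotted")
  }
  axis(1, at = off$mid, labels = names(off$mid), las = 2, cex.axis = 0.7)
  mtext("SNP position (chromosome)", side = 1, line = 2.8, cex = 0.8)

  # middle: per-SNP significant-probe counts
  counts <- table(records$snp_id)
  plot(NA, xlim = xlim, ylim = c(0, max(3, as.integer(counts), na.rm = TRUE)),
       xlab = "", ylab = "No. of genes", xaxt = "n")
  abline(v = off$bounds, col = "grey90")
  if (length(counts)) {
    cx <- snp_x[names(counts)]
    symbols(cx, as.integer(counts),
            circles = as.integer(counts) / max(as.integer(counts)),
            inches = 0.12, add = TRUE, fg = "grey30", bg = NA)
  }

  # top: enrichment score track
  top <- if (nrow(hotspots)) max(hotspots$enrichment_score, 1) else 1
  plot(NA, xlim = xlim, ylim = c(0, top * 1.1), xlab = "",
       ylab = "Enrichment score", xaxt = "n")
  abline(v = off$bounds, col = "grey90")
  if (nrow(hotspots))
    points(snp_x[hotspots$snp_id], hotspots$enrichment_score,
           pch = 19, cex = 0.6, col = "grey20")
  mtext("eQTL map: associations, per-SNP gene counts, hotspot enrichment",
        side = 3, outer = TRUE, line = 0.3)
  invisible(path)
}

.chrom_offsets <- function(chroms) {
  chroms <- unique(chroms[!is.na(chroms)])
  num <- suppressWarnings(as.numeric(chroms))
  ord <- order(is.na(num), num, chroms)
  chroms <- chroms[ord]
  # offsets derived from the largest coordinate seen per chromosome
  len <- rep(2.6e8, length(chroms))
  names(len) <- chroms
  offset <- c(0, cumsum(len))[seq_along(len)]
  names(offset) <- chroms
  mid <- offset + len / 2
  list(offset = offset, mid = mid, bounds = c(offset, sum(len)),
       total = sum(len))
}

.p_to_gray <- function(p) {
  s <- -log10(pmax(p, 1e-30))
  s <- pmin(1, s / max(s))
  gray(0.8 * (1 - s))
}
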