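#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test: given the observed allele counts, every
#' attainable heterozygote count (same parity as the observed one) is
#' enumerated, its conditional probability under random mating computed,
#' and the p-value is the sum of the probabilities of all tables no more
#' probable than the observed one. This is the standard exact HWE
#' construction; the plain (not mid-) p-value is returned by default.
#'
#' @param n_ref_hom count of reference homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_alt_hom count of alternate homozygotes.
#' @param midp if TRUE, return the mid-p variant (half weight on tables
#'   exactly as probable as the observed one).
#' @return p-value in \[0, 1\]. Monomorphic sites return 1 (a single
#'   attainable table).
#' @export
#' @examples
#' hwe_exact_test(5, 0, 5)   # strong heterozygote deficit
#' hwe_exact_test(25, 50, 25)
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom, midp = FALSE) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  if (anyNA(counts) || any(counts < 0)) stop("genotype counts must be >= 0")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n == 0) stop("at least one genotyped sample is required")
  n_alt <- 2 * n_alt_hom + n_het          # minor/major labelling irrelevant
  tab <- hwe_het_distribution(n, n_alt)
  logp_obs <- tab$logp[tab$het == n_het]
  # tolerance guards ties hit through floating point
  sel <- tab$logp <= logp_obs + 1e-10
  p <- sum(exp(tab$logp[sel]))
  if (midp) {
    ties <- abs(tab$logp - logp_obs) <= 1e-10
    p <- p - 0.5 * sum(exp(tab$logp[ties]))
  }
  min(1, p)
}

# Conditional distribution of the heterozygote count given allele counts:
# log P(het = h) = log[ n! / (nAA! h! naa!) * 2^h ] - log[ (2n)! / (nA! na!) ]
hwe_het_distribution <- function(n, n_alt) {
  n_ref <- 2L * n - n_alt
  h_max <- min(n_alt, n_ref)
  h <- seq.int(n_alt %% 2L, h_max, by = 2L)
  n_alt_hom <- (n_alt - h) / 2
  n_ref_hom <- n - h - n_alt_hom
  logp <- lgamma(n + 1) - lgamma(n_ref_hom + 1) - lgamma(h + 1) -
    lgamma(n_alt_hom + 1) + h * log(2) -
    (lgamma(2 * n + 1) - lgamma(n_alt + 1) - lgamma(n_ref + 1))
  data.frame(het = h, logp = logp)
}

#' Chi-square test of Hardy-Weinberg proportions
#'
#' One-degree-of-freedom goodness-of-fit test against the expected
#' genotype proportions at the observed allele frequency; offered as the
#' asymptotic alternative to [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return p-value in \[0, 1\].
#' @export
hwe_chisq_test <- function(n_ref_hom, n_het, n_alt_hom) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  if (anyNA(counts) || any(counts < 0)) stop("genotype counts must be >= 0")
  n <- sum(counts)
  if (n == 0) stop("at least one genotyped sample is required")
  p_alt <- (2 * n_alt_hom + n_het) / (2 * n)
  if (p_alt == 0 || p_alt == 1) return(1)
  expd <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  stat <- sum((counts - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
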