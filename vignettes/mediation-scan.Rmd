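---
title: "Mediation scanning of SNP-transcript-phenotype trios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation scanning of SNP-transcript-phenotype trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

## The question trioscan answers

With genotype, expression-array and quantitative-phenotype data measured
on the same cohort (the motivating setting is hepatic CYP2D6 enzyme
activity with liver expression profiles), every SNP × transcript pair
can be asked: is the SNP's effect on the phenotype transmitted through
the transcript? A significant *trio* is evidence that the variant acts
on the trait via expression — particularly informative for trans-acting
SNPs, whose GWAS signals are otherwise hard to interpret.

## The mediation model

For gene dose $X \in \{0,1,2\}$, transcript $M$ and trait $Y$, the
classical four regression steps are

$$Y = \alpha_1 + \beta_1 X + \varepsilon_1, \qquad
  M = \alpha_2 + \beta_2 X + \varepsilon_2,$$
$$Y = \alpha_3 + \beta_3 M + \varepsilon_3, \qquad
  Y = \alpha_4 + \beta_4 M + \beta_5 X + \varepsilon_4,$$

with independent Gaussian errors. Steps 1 and 3 establish zero-order
relations; the causal-steps procedure built on them has low power and,
crucially, never tests the indirect pathway itself. The quantity of
interest is therefore the product $\beta_2\beta_4$: the effect of $X$
on $M$ times the effect of $M$ on $Y$ adjusted for $X$. `scan_trios()`
accordingly uses the indirect-effect test as the significance criterion
and does **not** gate on steps 1 and 3; a causal-steps gate is available
(`gate_steps = TRUE`) for users who want the stricter classical screen.
$\beta_5$ is reported as the direct effect (partial mediation when both
$\beta_4$ and $\beta_5$ are nonzero).

### The Sobel test

By the multivariate delta method,

$$\sigma_{\beta_2\beta_4} = \sqrt{\beta_2^2\sigma_4^2 +
  \beta_4^2\sigma_2^2},
  \qquad
  \Delta = \frac{\hat\beta_2\hat\beta_4}{\mathrm{se}(\hat\beta_2\hat\beta_4)}$$

referred to the standard normal, two-sided. This is the default and the
scan's p-value (`p_analytic`). It assumes approximate normality of the
product, which holds when at least one path is estimated precisely; under
a complete null the product distribution is more peaked than normal and
the test is conservative.

### The permutation test of the coefficient product

`permutation_null()` implements the permutation-of-raw-data test: per
iteration $Y$ is permuted and regressed on the unpermuted $(X, M)$ to
give $\beta_4^{+}$, $M$ is independently permuted and regressed on $X$
to give $\beta_2^{+}$, and the product $\beta_2^{+}\beta_4^{+}$ is
stored. The two-sided p-value uses the add-one rule
$p = (1 + \#\{|\beta_2^{+}\beta_4^{+}| \ge |\hat\beta_2\hat\beta_4|\})/(B+1)$,
so $p \ge 1/(B+1)$ always.

**The two tests are not interchangeable.** The permutation null is the
distribution of a product of two null coefficients — sharply peaked at
zero with heavy shoulders — whereas the Sobel test treats the observed
product as Gaussian. In the moderate-significance band the permutation
p-value is systematically smaller than the analytic one (this is exactly
why product-resampling tests have more power than the Sobel test, and it
is visible in this package's own cross-method test). They agree on the
extremes: overwhelming signals are minimal under both, and clear nulls
are non-significant under both. Users should pick one criterion and
state it; the genome-wide defaults use the analytic test, which is the
cheaper and the more conservative choice.

Published descriptions of this permutation scheme quote $B = 10^9$; that
is symbolic of a cluster-scale run. The package defaults to $B = 0$
(analytic only) and, when $B > 0$, permutes only trios that pass the
analytic screening cutoff (screen-then-permute). Permutation seeds are
derived per trio from the run seed and the SNP/probe indices, so results
are reproducible and independent of how the scan is chunked.

## By-chance FDR

For $S$ SNPs × $P$ probes scanned at per-test level $\alpha$ with
$n_{sig}$ significant trios,

$$\mathrm{FDR} = \frac{S \cdot P \cdot \alpha}{n_{sig}},$$

the expected count under a global null over the observed count. This is
deliberately simple — a ratio, not an adaptive procedure — and it is what
`summarize_scan()` attaches to the scan summary. With zero discoveries
and a positive expected count the ratio is reported as undefined rather
than zero. A permutation-based numerator (the median significant count
over phenotype permutations) can be substituted by users who distrust
the global-null expectation, at the cost of re-running the scan per
permutation.

## eQTL scan, hotspots, and the overlap

`eqtl_scan()` regresses each transcript on each gene dose (the identical
simple-regression kernel as the mediation step 2, so the p-values agree
by construction). Pairs with $p$ below the cutoff (default $10^{-5}$)
are significant. A SNP associated with at least 20 transcripts is a
candidate *hotspot* — a putative master regulator whose one polymorphism
moves many distant genes. Enrichment of a SNP with $k$ significant
probes out of $P$ is scored by the exact binomial upper tail
$P(K \ge k \mid P, p_0)$, Bonferroni-corrected by the number of SNPs in
the scan, and reported as $-\log_{10}$ of the corrected p. Finally,
`overlap_hotspots_with_mediation()` intersects hotspot SNPs with the
significant trios, giving the trio count, hotspot-SNP count and distinct
mediator count — the candidate master regulators whose downstream
transcripts mediate the phenotype.

Choices made where the procedure is underdetermined:

* **Binomial null $p_0$** defaults to the nominal pair-level cutoff
  ($10^{-5}$); a data-driven alternative (the global fraction of
  significant pairs) can be passed explicitly. With correlated probes
  the nominal choice is anti-conservative in principle, which is why the
  Bonferroni correction and the count floor are both kept.
* **Bonferroni family** is all SNPs in the scan, not merely the
  candidate hotspots.
* **cis/trans**: a pair is cis when on the same chromosome within 1 Mb
  (inclusive), else trans; the distance is probe-position minus
  SNP-position in 1-based coordinates. The window is a convention, not
  an estimate.
* The eQTL map figure plots $-\log_{10}$(Bonferroni-corrected binomial
  p) as its enrichment track and labels it as such.

## Quality control and normalization

Sample filter first, SNP filters second, with SNP statistics computed on
the post-sample-filter data:

1. samples with genotyping call rate **strictly below** 95% are removed;
2. SNPs are removed when call rate < 95%, the Hardy–Weinberg exact test
   has $p <$ 0.001, or MAF < 10% — all strict inequalities, matching the
   "less than" wording of the filters' usual statement.

The HWE test is the conditional exact test (enumerate all heterozygote
counts compatible with the observed allele counts; sum the
probabilities of tables no more probable than the observed one). An
asymptotic chi-square variant is provided; exact is the default because
it is well defined at every MAF and sample size in play. The plain (not
mid-) p-value is used, with a mid-p option on the function.

Phenotype and expression are corrected for age and sex by linear
regression, then rank-based inverse-normal transformed: rank $r$ of $n$
maps to $\Phi^{-1}((r-0.5)/n)$, ties averaged, missing kept missing (a
Blom offset is available). The adjust-then-normalize order is applied
exactly once to the phenotype and once per probe. "Quantile
normalization to the normal" is the reading adopted for the loosely
named rank-normalization step customary for enzyme-activity traits; a
literal four-bin quartile binning would discard information and is not
offered.

Missing data policy downstream: complete-case **per trio** — a sample
missing any of $(X, M, Y)$ for a given trio is dropped from that trio
only.

## The synthetic-data generator

`simulate_dataset()` emulates the shape of the motivating liver cohort
at desk scale: ~200 samples (the cohort's per-platform overlap of
genotype, expression and activity data was 167–180), hundreds of SNPs
standing in for two genotyping platforms, hundreds to thousands of
probes, one quantitative trait, and age (uniform 20–80 years) and sex
(Bernoulli 1/2) covariates with modest 0.2-SD effects so the adjustment
step is exercised non-trivially. Genotypes are drawn per SNP from
Hardy–Weinberg proportions at a MAF uniform in [0.1, 0.5] (matching the
post-QC universe), with 2% missing calls by default. Expression and
trait are linear-additive in the planted effects with unit Gaussian
noise — the model family the regressions assume.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, platform/batch artifacts, probe cross-hybridization, non-Gaussian
expression tails, or population structure. Passing tests on this
generator therefore validate the statistical machinery under its own
model assumptions; they do not certify performance on real array data,
where LD in particular will make hotspot SNPs come in correlated blocks
rather than as single markers.

The generator returns a full ground-truth record (planted trios,
hotspot architecture, direct and covariate effects), sufficient to score
any scan output for true/false positives — e.g. to compare the
by-chance FDR with the empirical FDR on simulated data.

## Numerical conventions

* OLS is computed from centered cross-products per SNP (vectorized
  across probes); standard errors use $n-2$ (one predictor) and $n-3$
  (two predictors) degrees of freedom. A design is declared
  rank-deficient when $S_{xx}S_{mm} - S_{xm}^2 \le 10^{-12}
  S_{xx}S_{mm}$.
* Scan arithmetic is strictly per SNP (never block-level matrix-matrix
  products), so trio output is bit-identical for any SNP-block size.
* Degenerate Sobel inputs: zero SE with zero product gives $z = 0$,
  $p = 1$; zero SE with nonzero product gives $z = \pm\infty$, $p = 0$.
* Tie handling: average ranks in the normal-score transform; the
  add-one rule in permutation p-values; HWE tables tied in probability
  with the observed one are included in the rejection sum (tolerance
  $10^{-10}$ on log-probabilities).
* Genotype TSVs accept `NA`, the empty string and `.` as missing; VCF
  doses count alternate alleles, treating `/` and `|` alike, and skip
  multi-allelic records with a warning. Coordinates are 1-based.

## Problem sizes used by the test suite

The packaged tests run the machinery at deliberately modest sizes chosen
to make every property measurable in minutes on one core: oracle
equivalence on 100 random regressions; Sobel null calibration on 2,000
replicates at $n = 200$; permutation cross-checks at $B$ up to 10,000;
planted-trio recovery on 50 × 50 grids over 100 seeds; hotspot detection
on 200–500 SNPs × 1,000 probes with 20 null replicates; and exact-HWE
enumeration over every genotype table up to 50 samples. These sizes are
the package's own validation design; the scan itself streams SNP blocks
and has no intrinsic size ceiling beyond memory for one block.

## Known limitations

* The mediation model is a single linear path; multiple mediators,
  interactions and non-linear effects are out of scope, and a
  significant trio is *consistent with* mediation, not proof of
  causality — the directionality assumption (genotype → expression →
  trait) is biological, not statistical.
* The Sobel test is conservative under complete nulls; the permutation
  test is better calibrated but costlier, and the two disagree by
  construction in the moderate band (see above).
* The by-chance FDR assumes independent tests under the global null;
  correlated probes and LD make it a rough summary rather than an error
  guarantee.
* Hotspot detection treats SNPs marginally; LD-aware merging of
  adjacent hotspot SNPs is not implemented.
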