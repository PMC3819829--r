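Package: trioscan
Title: Genome-Wide Mediation Scanning of SNP-Transcript-Phenotype Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genetic variants whose effect on a quantitative
    phenotype (such as hepatic CYP2D6 enzyme activity) is mediated by
    gene-expression levels. Implements the Baron-Kenny regression steps,
    the Sobel product-of-coefficients test of the indirect effect with an
    optional permutation null of the permuted-coefficient product, a
    by-chance false-discovery-rate estimate for the genome-wide trio scan,
    an eQTL scan with trans-hotspot detection by exact binomial enrichment,
    and the overlap of hotspots with mediating transcripts. Includes
    sample- and SNP-level quality control (call rate, exact
    Hardy-Weinberg test, minor allele frequency), covariate adjustment
    with rank-based inverse-normal transformation, a synthetic-data
    generator with planted mediation and hotspot architecture, and a
    file-based pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
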