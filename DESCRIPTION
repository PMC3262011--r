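Package: cotwin
Title: Integrative Methylation-Expression Analysis of Discordant Monozygotic Twin Pairs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Paired-design analysis of DNA methylation and gene expression in
    monozygotic twin pairs discordant for a disease phenotype. Provides paired
    differential statistics (per-feature paired t-tests, Benjamini-Hochberg FDR,
    exhaustive sign-flip permutation nulls, empirical-Bayes moderated t-tests),
    co-twin similarity diagnostics (per-pair correlations, technical versus
    biological difference contrasts with Kolmogorov-Smirnov tests), a per-gene
    integration of co-twin methylation differences (delta-beta) against
    expression log fold changes with Spearman correlation significance ranking,
    gene-set overrepresentation with hypergeometric tests, and a synthetic
    twin-cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
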