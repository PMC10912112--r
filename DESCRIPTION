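Package: mosaiscan
Title: Detection of Low-Level Parental Mosaicism in Ultra-Deep Targeted
    Trio Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting low-allele-fraction parental mosaicism
    of de novo variants from ultra-deep (UMI-deduplicated) targeted
    sequencing of parental blood samples. Parses samtools-mpileup output
    into per-sample allele counts at targeted positions, models the
    position-specific sequencing background from pooled control samples,
    tests each parent with a one-sided exact Poisson test under an
    experiment-wide Bonferroni-corrected significance level, computes
    per-position power curves and minimum detectable allele fractions for
    the exact test, and assembles cohort-level summary statistics
    (prevalence, variant-type and subgroup associations, paternal age
    comparison). Includes a calibrated synthetic-cohort generator (depth,
    position-specific noise, planted mosaics) so the whole pipeline is
    testable end-to-end without access to patient data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
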