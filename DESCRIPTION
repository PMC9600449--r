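Package: lymphpanel
Title: Targeted-Panel Genomic Profiling of Cutaneous Large B-Cell Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for targeted next-generation-sequencing panels in
    primary cutaneous diffuse large B-cell lymphoma, leg type (PCDLBCL-LT).
    Implements sample- and variant-level quality control for FFPE amplicon
    panels (read-count and Ts:Tv filters, pathogenicity-class and VAF filtering
    with a MYD88 L265P / CD79B Y196 hotspot exception), CDKN2A copy-number loss
    calling from amplicon read counts against a panel of normals with a
    consecutive-amplicon rule, paired primary/relapse clonal-stability
    classification (stable, lost, gained alterations and driver persistence),
    cohort summarization (gene frequencies, driver coverage, oncoprints,
    contingency comparisons), and survival analysis (Kaplan-Meier, log-rank,
    per-gene univariable Cox with Bonferroni correction). A seeded synthetic
    cohort generator emulates amplicon coverage with purity-diluted deletions,
    hotspot mutation frequencies, FFPE transition artefacts, paired clonal
    evolution, and covariate-driven survival, so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
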