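Package: varcoseg
Title: Pedigree Co-Segregation Variant Prioritization with Cohort Burden,
    Substitution Tolerance, and Somatic Recurrence Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate cancer-predisposition variants from small
    familial sequencing studies. Identifies rare non-silent variants shared by
    affected relatives within a pedigree, intersects them with a
    cancer-germline variant set derived by population allele-count table
    subtraction, classifies variants with an ACMG-AMP-style five-tier
    evidence-combination engine, tests gene-level case-control allele burden
    with Fisher's exact test on subtracted cohort counts, scores missense
    substitution tolerance against a PSI-BLAST position-specific scoring
    matrix with a Monte Carlo random-mutation null, and detects somatic
    recurrence signals (windowed binomial hotspot scan, 20/20
    oncogene/tumor-suppressor classification, per-cancer-type binomial
    enrichment). Ships a synthetic-data generator that plants ground truth in
    every input format the pipeline consumes, so the full workflow is testable
    end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
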