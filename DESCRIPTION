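Package: metintegrate
Title: Integrative Transcriptomic, Gene-Dependency and Pharmacogenomic
    Analysis of Cancer Metastasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for integrative reanalysis of
    metastasis genomics: signal-to-noise differential ranking with a
    label-permutation null, binomial over-representation analysis with
    Benjamini-Hochberg false-discovery control, a weighted running-sum
    gene-set enrichment score with leading-edge extraction, CRISPR
    gene-dependency aggregation and target/marker triage, and
    drug-response stratification with signature enrichment. Includes a
    synthetic-data module that generates every input the pipeline
    consumes, with recorded ground truth, so all stages are testable
    without external cohorts. Reads and writes GCT 1.2, GMT and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
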