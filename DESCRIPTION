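Package: surromark
Title: Surrogate-Marker Evaluation for Bimodal Gene Expression in Tumor
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates candidate surrogate markers of a reference gene's
    expression status in tumor transcriptome cohorts. Provides
    two-component Gaussian mixture fitting for bimodal low/high
    classification, an exclusion statistic at fixed reference
    specificity, RNA versus clinical status discordance, rescue
    cross-tabulation over alternative target genes, exact hypergeometric
    subtype enrichment with false discovery rate control, composite
    (Allred-style) immunohistochemistry scoring with kernel-density
    trough cut-offs, rank-based group comparisons with Dunn's post-hoc
    test, and a seeded synthetic tumor-cohort generator with latent
    regulator activities and full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
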