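Package: memscreen
Title: Membrane-Proteome Candidate Screening and Downstream Validation Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A label-free proteomics screening pipeline for membrane-associated
    candidate biomarkers in cancer versus benign control cell lines, together
    with the downstream validation statistics such a screen feeds into.
    Implements total-ion normalization of precursor peak areas to
    parts-per-10^6, per-protein replicate summaries (detection counts, mean,
    SD, percent CV), a candidate-selection cascade (detection calling,
    membrane-annotation refinement, cancer-versus-control exclusivity, CV
    filtering, Venn partitioning, ranked top-N tables), Pearson chi-square
    association analysis of immunohistochemistry-scored tissue-microarray
    cohorts, four-parameter logistic IC50 fitting for MTT viability assays
    with drug-combination shift testing and siRNA growth-curve comparison,
    and seeded synthetic-data generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
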