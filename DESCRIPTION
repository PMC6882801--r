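Package: stromascan
Title: Stroma-Corrected Association Analysis for Bulk Tumor Transcriptomics
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting associations between gene expression and
    tumor-infiltrating immune activity in bulk transcriptomic cohorts while
    accounting for stromal confounding. Provides single-sample gene-set
    enrichment scoring of stromal and immune content, partial Spearman
    correlation with confounder residualization, derivation of
    stroma-corrected transcription-factor-activated gene signatures by
    intersecting knockdown differential expression with co-expression and
    filtering on stroma-adjusted partial correlations, stroma-adjusted Cox
    proportional-hazards survival scans, and a synthetic bulk-mixture cohort
    generator with known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
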