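Package: strandmeth
Title: Strand-Resolved CpG Methylation Analysis for Promoter Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strand-resolved analysis of CpG island methylation
    from bisulfite-based assays: in-silico bisulfite conversion of either
    DNA strand, chromatogram peak-ratio classification of per-site
    methylation density calibrated against reconstituted standards,
    clone-level percent-methylation analysis, quantitative
    methylation-specific PCR (standard curves, copy-number calls with a
    limit of detection, input normalization), and biomarker evaluation
    (sensitivity/specificity, ROC with paired curve comparison, combined
    markers, clinicopathological group tests). Includes a synthetic-cohort
    generator emulating liver-specific antisense-biased promoter
    methylation so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
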