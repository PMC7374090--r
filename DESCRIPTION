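Package: screenomics
Title: Essentiality Screen Scoring and Multi-Omics Driver Signatures for
    Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns pooled shRNA dropout-screen count tables into gene-level
    essentiality scores and hit calls using a robust quantile null model,
    integrates copy-number, expression and mutation layers into oncogene and
    functional-druggable signatures, scores KEGG pathway essentialness on
    KGML-derived gene graphs with connectivity weighting, and estimates drug
    sensitivity (IC50 by four-parameter logistic or LOESS inversion, panel
    Z-scores on geometric-mean IC50s). Includes seeded synthetic generators
    for screens, omics stores, toy KGML pathways and dose-response curves,
    plus a command-line interface over every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
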