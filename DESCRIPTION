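Package: svgheatmap
Title: Publication-Quality SVG Heat Maps for Biological Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders rectangular biological data matrices (gene-expression
    probes by conditions, per-position amino-acid substitution effect scores)
    as self-contained, tooltip-annotated SVG heat maps. Provides a labeled
    matrix container with per-cell wildtype/missing flags, CSV and JSON
    readers and writers, diverging value-to-color mapping with a scale bar,
    automatic grid layout with a threshold-triggered zoom panel, categorical
    annotation tracks (exons, trans-membrane regions, secondary structure),
    deterministic fixture generators for expression and mutability-landscape
    demonstrations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
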