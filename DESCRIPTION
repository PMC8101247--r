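Package: k7quant
Title: Quantification of Cytokeratin-7 Immunohistochemistry in Liver Biopsies
Version: 0.1.0
Authors@R:
    person("K7quant", "Developers", email = "k7quant@example.org",
           role = c("aut", "cre"))
Description: Hierarchical (nested) segmentation of DAB/hematoxylin-stained
    liver biopsy images into tissue, portal, parenchyma and K7-positive
    hepatocyte layers using deterministic optical-density and morphology
    operators; computation of the K7%area statistic, periportal zonal
    distance analysis, automated ordinal K7 deposition scoring, per-layer
    segmentation validation metrics, and cohort-level correlation analysis.
    Includes a synthetic liver-biopsy image generator with ground-truth
    masks so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
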