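Package: tilhet
Title: Spatial and Temporal Heterogeneity of Tumor-Infiltrating Lymphocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-infiltrating lymphocyte densities from multiplex
    immunohistochemistry cell tables with tumor/stroma compartment assignment,
    simulates virtual tissue-microarray cores and biopsy-sized regions inside
    the tumor compartment, and measures how representative such regions are of
    their parent sample via a quartile-concordance (correct classification
    rate) statistic. Includes H-score based luminal/basal subtype calling,
    nonparametric cohort comparisons (Kruskal-Wallis with Dunn/Bonferroni
    post-hoc tests, Wilcoxon signed-rank), paired-change summaries for
    chemotherapy cohorts, and a synthetic-cohort generator (homogeneous
    Poisson, Thomas cluster and gradient point processes on polygonal tissue
    geometries) so the full pipeline is testable without patient data.
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
    jsonlite,
    polyclip,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
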