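Package: poolanchor
Title: Gene Anchoring on BAC Physical Maps by Three-Dimensional Pool Hybridisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Anchors genes onto a chromosome physical map from microarray
    hybridisations of three-dimensional (plate, row, column) BAC pools.
    Implements two-step median normalisation of probe-by-pool signal
    matrices, four complementary positive-pool scoring methods (iterative
    outlier thresholding, boxplot fences, semi-automated and manual
    coordinate completion), deconvolution of positive pools into BAC
    addresses using the physical-map overlap graph, repeat-probe filtering
    by local alignment, and downstream comparative genomics (synteny and
    collinearity against a related genetic map and an ortholog table) and
    gene-space analyses (deletion-bin gene densities, density gradients,
    gene-island detection, extrapolation). A synthetic-data generator
    reproduces the statistical structure of such experiments (minimal
    tiling path coverage, pool geometry, identity-dependent hybridisation
    attenuation, per-BAC abundance heterogeneity, centromere-to-telomere
    density gradients and distally enriched gene islands) for end-to-end
    recovery testing.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
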