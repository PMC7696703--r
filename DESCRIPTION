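Package: smartscan
Title: Subset Analysis of Matched Repeated Time Points for Early Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers when, relative to diagnosis, a multivariate molecular
    marker pattern becomes detectable in matched repeated case-control
    samples. Implements effect-projection OPLS (OPLS-EP) for dependent
    samples with cross-validated variable selection and CV-ANOVA model
    significance, a scanning engine over time-to-diagnosis and
    time-between-samples coordinates with weighted nearest-neighbour subsets
    and Hotelling T2 ellipses, loading-based variable significance with
    Benjamini-Hochberg control, hierarchical clustering of significant model
    loadings, simulation-based false-positive control of subset-density
    maps, latent-biomarker scoring of independent single-time-point cohorts
    with ROC/AUC evaluation, and a generator of synthetic matched cohorts
    with a planted pre-diagnostic effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    pROC,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
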