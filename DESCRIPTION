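Package: ctnetwb
Title: Cortical Thickness Similarity Networks and Well-Being
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-subject morphological similarity networks built from the
    distribution similarity of parcel-wise cortical thickness, sparsified
    with orthogonal minimal spanning trees (OMST) under a global
    cost-efficiency criterion, summarised with binary graph-topology
    measures (global, nodal and local efficiency, degree, betweenness,
    eigenvector and pagerank centrality), and related to Mental Health
    Continuum Short Form well-being scores through covariate-adjusted
    linear models with Benjamini-Hochberg false-discovery-rate control.
    Includes a synthetic-cohort generator with configurable planted
    topology-behaviour effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
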