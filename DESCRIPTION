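Package: econet
Title: Economic Network Structure and the Efficiency of Regional Health Care
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links the structure of an inter-regional economic network to
    regional health-care efficiency. Builds gravity-model attraction
    matrices from regional masses (GDP times population) and pairwise
    distances, binarizes them into directed networks by row-mean
    thresholding, and computes node-level structure (indegree, outdegree,
    clustering coefficient, eigenvector centrality). Health-care efficiency
    is measured by input-oriented data envelopment analysis chained into
    the Malmquist total-factor-productivity index with its full
    decomposition (efficiency, technical, pure-efficiency and
    scale-efficiency change). Network position is related to productivity
    change by pooled panel regressions with region and year controls, and
    regions are grouped into a typology by principal components and
    k-means with silhouette-based selection of the number of groups. A
    synthetic province-panel generator with planted ground truth (frontier,
    inefficiency, network effect, latent typology) supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    cluster,
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
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
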