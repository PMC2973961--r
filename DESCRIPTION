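Package: coexmod
Title: Consensus-Clustering Discovery of Coexpressed Gene Modules Across
    Heterogeneous Time-Series Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analytic consensus clustering for time-series gene
    expression measured under multiple conditions on heterogeneous
    platforms. A diverse clustering ensemble is run per condition and
    summarised as an agreement matrix whose entries estimate the
    confidence that two probesets (then two genes, then two genes across
    all conditions) are coexpressed. Iterative clusterable-subset
    selection and agreement-constrained agglomeration extract all
    candidate modules, a resampling null on cluster size filters trivial
    clusters, and an optional heuristic merges redundant patterns by
    maximising total homogeneity plus separation. Includes a synthetic
    multi-condition benchmark generator with known class labels,
    adjusted-Rand-index evaluation with a per-condition intersection
    baseline, and a promoter post-analysis that calls conserved regions
    from alignment score profiles and scans them for motifs such as the
    glucocorticoid response element TGTTCT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
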