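Package: aapdise
Title: Atom-Atom-Path Similarity and Directed Sphere Exclusion Clustering
    for Fragment Hit Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Atom-Atom-Path (AAP) molecular similarity, a
    graph-based metric that describes every heavy atom by the multiset of
    linear bond/atom paths originating from it, maps atoms between two
    molecules with either an exact Hungarian assignment or a fast greedy
    heuristic, and aggregates the mapped atom-pair similarities into a
    molecular similarity in [0, 1].  Couples the metric with Directed
    Sphere Exclusion (DISE) clustering, which sorts compounds by a
    non-structural quality property such as ligand efficiency before
    sphere-exclusion seed selection so that the best compounds found a
    screening campaign's first clusters.  Includes SDF (MDL V2000) input
    and output, ligand-efficiency and triage pre-scoring utilities, a
    cluster scatterplot coloured by similarity to the cluster seed, a
    deterministic fragment-like test-set generator, and a composable
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ggplot2,
    grDevices,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
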