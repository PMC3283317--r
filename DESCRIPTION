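Package: multidiltag
Title: Evolutionary Histories of Orthologous Tandemly Arrayed Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Infers most-parsimonious evolutionary histories for sets of
    orthologous tandemly arrayed gene (TAG) clusters in multiple species.
    The model covers tandem duplications of arbitrary size (direct or
    inverted), deletions, inversions and speciations.  Given a rooted binary
    gene tree, a species tree and one signed gene order per extant genome,
    the package reconciles the gene tree into the species tree by LCA
    mapping, runs a backward best-first search over the history graph on
    every species-tree branch (the DILTAG search), and glues the per-branch
    solution sets bottom-up with loss reinsertion and inversion+deletion
    distance labelled speciation edges (Multi-DILTAG).  A forward simulator
    of histories consistent with a species tree and the evaluation
    experiments used to validate the method are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
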