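Package: modalign
Title: Alignment, Mode Detection and Visualization of Replicate
    Mixed-Membership Clusterings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resolves label switching and genuine multimodality across
    replicate runs of mixed-membership clustering programs such as
    Structure and Admixture. Optimal pairwise cluster alignments,
    including many-to-one alignments between runs with different numbers
    of clusters, are found exactly by branch-and-bound integer
    programming. Replicates sharing a cluster number are partitioned into
    modes by Louvain community detection on an alignment-similarity
    graph, gated behind a permutation test of community structure. Modes
    are summarized by mean or representative consensus memberships,
    aligned across cluster numbers by direct or merge strategies, scored
    with weighted within-mode similarity statistics, and drawn as
    structure plots arranged in a multipartite graph.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
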