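Package: tripletree
Title: Species Tree Estimation from Gene Trees by Maximizing Triplet Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates a rooted species tree from a collection of rooted,
    binary, single-copy gene trees by maximizing the number of induced
    rooted triplets shared between the species tree and the gene trees.
    The optimization is a dynamic program over clades whose candidate
    splits are subtree-bipartitions, run either within the constrained
    search space spanned by the gene trees (polynomial time) or over all
    bipartitions (exact, exponential time). Because rooted three-taxon
    gene trees have no anomaly zone under the multi-species coalescent,
    the maximum-triplet-consistency tree is a statistically consistent
    estimator of the species tree; the package includes a multi-species
    coalescent gene-tree simulator and Robinson-Foulds utilities so the
    consistency guarantee can be checked end to end by simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
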