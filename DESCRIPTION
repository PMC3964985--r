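Package: phylomekit
Title: Phylome Analysis: Species-Overlap Orthology, Reconciliation and
    Alignment Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing collections of gene phylogenies
    (phylomes): Newick/NHX gene-tree and species-tree input/output,
    seed-relative rooting, duplication/speciation labeling by the
    species-overlap rule, phylostratigraphic relative ages, tree-based
    orthology and paralogy calls with close-to-seed filtering and
    cross-tree consistency scores, OrthoXML and tabular export, LCA
    reconciliation with duplication/loss counting and exhaustive
    gene-tree-parsimony species-tree search, Robinson-Foulds tree
    comparison, ortholog-set conservation between releases,
    consistency-based alignment column filtering across alternative
    alignments, and a duplication-loss simulator producing ground-truth
    event logs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
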