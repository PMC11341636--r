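Package: netpars
Title: Parsimony Scores and Bounds for Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small parsimony on rooted binary phylogenetic
    networks and their semi-directed and unrooted relatives. Computes
    exact softwired parsimony scores by switching enumeration, parental
    parsimony via the MUL-tree unfolding, and a polynomial (k+1)-factor
    approximation for level-k networks that scores an arbitrary displayed
    tree. Includes blob decomposition and blob reduction, informative-blob
    counts, switching and exact rSPR distances on small trees, extended
    Newick input/output, gap-free alignment readers, deterministic
    generators for a sharp level-k family and a parental-gap family, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    seqinr,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn
Config/testthat/edition: 3
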