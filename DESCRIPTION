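Package: phyloprof
Title: Phylogenetic Profiling and Whole-Proteome Linkage Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct phylogenetic profiles (presence/absence and BLAST
    bit-score matrices) from tabular homology search results, score protein
    pairs with co-occurrence measures (Jaccard, Pearson, mutual information,
    Lp-norm distances), tree-aware Dollo parsimony distances, and bit-score
    normalizations (NPP z-score profiles and truncated-SVD profiles), and
    predict whole-proteome functional linkages by per-protein top-rank
    selection with a positive-correlation filter. Includes reference-set
    construction from protein-complex tables, threshold-swept ROC/PR curves
    with AUC, hit-rate and gene-set coverage summaries, and a seeded
    synthetic-data generator with planted co-evolving modules for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
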