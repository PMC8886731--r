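Package: phosphokin
Title: Differential Phosphosite Calling, Kinase-Substrate Prediction and
    Kinase Activity Inference for Pooled TMT Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for pooled two-group TMT phosphoproteomics in
    which each phosphosite carries a single disease/control ratio. Calls
    up/down-regulated phosphosites by fold-change thresholds, summarises
    residue composition and per-protein site multiplicity (with a Pearson
    chi-squared comparison), performs position-specific flanking-motif
    enrichment around regulated sites, predicts site-specific
    kinase-substrate relations by short-linear-motif peptide similarity
    with per-kinase false-positive-rate calibration and protein-protein
    interaction filtering, infers kinase activities as normalized
    enrichment scores of substrate sets over the ranked sites
    (permutation-based GSEA), and assembles the weighted bipartite
    kinase-site regulatory network. Includes a synthetic-data generator
    with planted kinase motifs and activity shifts so the full pipeline is
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
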