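Package: chsLineage
Title: Ancestral Gene-Family Repertoires from Gene-Tree/Species-Tree
    Reconciliation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers ancestral gene-family repertoires from rooted gene
    trees interpreted against a dated species tree. Provides LCA
    (last-common-ancestor) reconciliation with duplication/speciation
    labelling, decomposition of a gene tree into ancestral gene lineages
    delimited by root-mapped duplications, Dollo parsimony loss
    inference, and retention/expansion summaries. Includes a gene-model
    annotation stage for chalcone-synthase-like two-exon genes
    (functional versus pseudogene classification by ORF integrity and
    family-signature detection, tandem T-index naming in chromosomal
    order), a birth-death gene gain/loss simulator along a dated species
    tree with ground-truth lineage labels for validation, and a
    canonical 12-species rosid chalcone synthase fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, Genetics, Annotation, GeneFamily
RoxygenNote: 7.3.3
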