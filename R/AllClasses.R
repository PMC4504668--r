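#' Annotation configuration for two-exon CHS-like gene models
#'
#' Holds the structural and motif expectations used by
#' [validateStructure()]: the admissible translated length of exon 1, the
#' expected translated length of exon 2 with a tolerance, and the two
#' amino-acid patterns (family signature and active-site motif, both
#' regular expressions) that must be present in the exon-2 translation.
#'
#' The default exon lengths follow the canonical chalcone synthase
#' architecture: a variable first exon of 37-64 residues and a conserved
#' second exon of about 340 residues.  The default motifs are placeholders
#' in the style of the family's conserved regions (a catalytic-cysteine
#' containing signature and a GFGPG-loop motif); analyses of real data
#' should set motifs appropriate to their alignment.
#'
#' @slot exon1Min,exon1Max integer, admissible translated length (aa) of
#'   exon 1.
#' @slot exon2Target integer, expected translated length (aa) of exon 2,
#'   excluding the stop codon.
#' @slot exon2Tol integer, tolerance (aa) around `exon2Target`.
#' @slot signaturePattern character, regular expression matched against the
#'   exon-2 amino-acid translation (family signature).
#' @slot activeSitePattern character, regular expression matched against
#'   the exon-2 amino-acid translation (active-site motif).
#'
#' @examples
#' AnnotationConfig()
#' AnnotationConfig(exon2Tol = 5L)
#' @export
setClass("AnnotationConfig",
  representation(
    exon1Min = "integer",
    exon1Max = "integer",
    exon2Target = "integer",
    exon2Tol = "integer",
    signaturePattern = "character",
    activeSitePattern = "character"
  ),
  prototype(
    exon1Min = 37L,
    exon1Max = 64L,
    exon2Target = 340L,
    exon2Tol = 10L,
    signaturePattern = "GCFAGGT",
    activeSitePattern = "GFGPG"
  )
)

setValidity("AnnotationConfig", function(object) {
  msg <- character(0)
  if (object@exon1Min > object@exon1Max)
    msg <- c(msg, "exon1Min must be <= exon1Max")
  if (object@exon2Tol < 0L)
    msg <- c(msg, "exon2Tol must be >= 0")
  if (!nzchar(object@signaturePattern) || !nzchar(object@activeSitePattern))
    msg <- c(msg, "motif patterns must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @param exon1Min,exon1Max,exon2Target,exon2Tol integers, see slots.
#' @param signaturePattern,activeSitePattern character regular expressions,
#'   see slots.
#' @rdname AnnotationConfig-class
#' @export
AnnotationConfig <- function(exon1Min = 37L, exon1Max = 64L,
                             exon2Target = 340L, exon2Tol = 10L,
                             signaturePattern = "GCFAGGT",
                             activeSitePattern = "GFGPG") {
  new("AnnotationConfig",
      exon1Min = as.integer(exon1Min), exon1Max = as.integer(exon1Max),
      exon2Target = as.integer(exon2Target), exon2Tol = as.integer(exon2Tol),
      signaturePattern = signaturePattern,
      activeSitePattern = activeSitePattern)
}

setMethod("show", "AnnotationConfig", function(object) {
  cat("AnnotationConfig\n",
      "  exon1 length (aa): [", object@exon1Min, ", ", object@exon1Max, "]\n",
      "  exon2 length (aa): ", object@exon2Target, " +/- ", object@exon2Tol, "\n",
      "  signature pattern:   ", object@signaturePattern, "\n",
      "  active-site pattern: ", object@activeSitePattern, "\n", sep = "")
})

#' Set of gene models with exon structure
#'
#' Container pairing one [GenomicRanges::GRanges] of gene spans (1-based
#' inclusive coordinates, one range per gene model, metadata columns
#' `gene_id` and `species`, plus `status`, `reasons` and `assigned_name`
#' once annotated) with a parallel [GenomicRanges::GRangesList] of exons.
#' Exons are stored sorted by genomic start; transcription order on the
#' minus strand is the reverse.
#'
#' @slot genes `GRanges`, one range per gene model.
#' @slot exons `GRangesList`, parallel to `genes`.
#'
#' @seealso [readGeneModels()], [annotateGenes()], [assignNames()]
#' @export
setClass("GeneModelSet",
  representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  g <- object@genes
  e <- object@exons
  msg <- character(0)
  if (length(g) != length(e))
    msg <- c(msg, "genes and exons must have equal length")
  mc <- S4Vectors::mcols(g)
  for (col in c("gene_id", "species"))
    if (!col %in% colnames(mc)) msg <- c(msg, paste0("missing mcols '", col, "'"))
  if ("gene_id" %in% colnames(mc) && anyDuplicated(mc$gene_id))
    msg <- c(msg, "gene_id values must be unique")
  if (length(g) == length(e) && length(g)) {
    for (i in seq_along(g)) {
      ex <- e[[i]]
      if (length(ex) == 0L) { msg <- c(msg, "every gene needs >= 1 exon"); break }
      if (any(GenomicRanges::start(ex) < GenomicRanges::start(g[i])) ||
          any(GenomicRanges::end(ex) > GenomicRanges::end(g[i]))) {
        msg <- c(msg, paste0("exons outside gene span for gene ", i)); break
      }
      st <- GenomicRanges::start(ex)
      if (is.unsorted(st, strictly = TRUE) && length(ex) > 1L) {
        msg <- c(msg, paste0("exons must be sorted by start for gene ", i)); break
      }
      if (length(ex) > 1L &&
          any(st[-1L] <= GenomicRanges::end(ex)[-length(ex)])) {
        msg <- c(msg, paste0("overlapping exons for gene ", i)); break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param genes,exons see slots.
#' @rdname GeneModelSet-class
#' @export
GeneModelSet <- function(genes, exons) {
  mc <- S4Vectors::mcols(genes)
  if (!"status" %in% colnames(mc)) genes$status <- NA_character_
  if (!"reasons" %in% colnames(mc)) genes$reasons <- NA_character_
  if (!"assigned_name" %in% colnames(mc)) genes$assigned_name <- NA_character_
  new("GeneModelSet", genes = genes, exons = exons)
}

setMethod("length", "GeneModelSet", function(x) length(x@genes))

setMethod("show", "GeneModelSet", function(object) {
  st <- object@genes$status
  cat("GeneModelSet with ", length(object), " gene models (",
      sum(st %in% "functional"), " functional, ",
      sum(st %in% "pseudogene"), " pseudogene, ",
      sum(st %in% "rejected"), " rejected, ",
      sum(is.na(st)), " unannotated)\n", sep = "")
  sp <- unique(object@genes$species)
  cat("  species: ", paste(head(sp, 6), collapse = ", "),
      if (length(sp) > 6) ", ..." else "", "\n", sep = "")
})

#' Reconciliation of a gene tree against a species tree
#'
#' Result of [reconcile()] (or [lcaMap()] + [labelEvents()]): the LCA
#' mapping `M(v)` from every gene-tree node to a species-tree node, and
#' the duplication/speciation label of every internal gene-tree node.
#'
#' @slot geneTree,speciesTree rooted binary `phylo` trees.
#' @slot speciesOf named character, gene tip label -> species tip label.
#' @slot mapping integer vector over gene-tree nodes (ape numbering);
#'   values are species-tree node numbers.
#' @slot event character vector over gene-tree nodes; `"speciation"` or
#'   `"duplication"` for internal nodes, `NA` for tips.
#'
#' @export
setClass("Reconciliation",
  representation(
    geneTree = "ANY",
    speciesTree = "ANY",
    speciesOf = "character",
    mapping = "integer",
    event = "character"
  ))

setValidity("Reconciliation", function(object) {
  msg <- character(0)
  n <- .nNode(object@geneTree)
  if (length(object@mapping) != n)
    msg <- c(msg, "mapping length must equal number of gene-tree nodes")
  if (length(object@event) != n)
    msg <- c(msg, "event length must equal number of gene-tree nodes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Reconciliation", function(object) {
  ev <- object@event
  cat("Reconciliation: ", .nTip(object@geneTree), " genes over ",
      .nTip(object@speciesTree), " species\n",
      "  duplications: ", sum(ev %in% "duplication"),
      "   speciations: ", sum(ev %in% "speciation"), "\n", sep = "")
})

#' One ancestral gene lineage
#'
#' A maximal gene-tree clade traced to the species-tree root: the genes
#' that descend from a single gene copy present in the last common
#' ancestor of the sampled species.  Produced by [decomposeLineages()].
#'
#' @slot lineageId character, `"lineage_<k>"` in pre-order of lineage roots.
#' @slot rootNode integer, gene-tree node at the lineage root.
#' @slot members character, gene tip labels in the lineage.
#' @slot speciesCounts named integer over all species (zeros kept).
#' @slot losses character, species-tree edges `"parent->child"` on which
#'   the lineage was lost under Dollo parsimony (root presence forced).
#' @slot lossEdges matrix, two columns of species-tree node numbers.
#'
#' @export
setClass("GeneLineage",
  representation(
    lineageId = "character",
    rootNode = "integer",
    members = "character",
    speciesCounts = "integer",
    losses = "character",
    lossEdges = "matrix"
  ))

setValidity("GeneLineage", function(object) {
  msg <- character(0)
  if (length(object@members) != sum(object@speciesCounts))
    msg <- c(msg, "sum of speciesCounts must equal number of members")
  if (sum(object@speciesCounts > 0L) < 1L)
    msg <- c(msg, "a lineage must cover at least one species")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneLineage", function(object) {
  cat(object@lineageId, ": ", nCopies(object), " copies in ",
      nSpecies(object), " species, ", nLosses(object), " Dollo losses\n",
      sep = "")
  sc <- object@speciesCounts[object@speciesCounts > 0L]
  cat("  ", paste0(names(sc), ":", sc, collapse = " "), "\n", sep = "")
})

#' Retention summary across species and lineages
#'
#' Species-by-lineage copy-count matrix plus derived tallies: how many
#' ancestral lineages each species retained, and how many species kept
#' two or more versus exactly one.
#'
#' @slot matrix integer matrix, rows = species, columns = lineages.
#' @slot lineagesPerSpecies named integer.
#' @slot nMulti integer, species retaining >= 2 lineages.
#' @slot nSingle integer, species retaining exactly 1 lineage.
#'
#' @export
setClass("RetentionSummary",
  representation(
    matrix = "matrix",
    lineagesPerSpecies = "integer",
    nMulti = "integer",
    nSingle = "integer"
  ))

setValidity("RetentionSummary", function(object) {
  nz <- sum(object@lineagesPerSpecies == 0L)
  if (object@nMulti + object@nSingle + nz != nrow(object@matrix))
    return("nMulti + nSingle + zero-lineage species must equal species count")
  TRUE
})

setMethod("show", "RetentionSummary", function(object) {
  cat("RetentionSummary: ", nrow(object@matrix), " species x ",
      ncol(object@matrix), " lineages\n",
      "  >= 2 lineages: ", object@nMulti,
      "   exactly 1: ", object@nSingle, "\n", sep = "")
})

#' Simulated gene family with ground truth
#'
#' Output of [simulateGeneFamily()]: the pruned gene tree (extinct copies
#' removed, unary nodes suppressed), plus the truth needed to validate
#' lineage recovery: how many of the root copies left extant descendants,
#' which root copy each extant gene descends from, and the per-species
#' gene census.
#'
#' @slot geneTree `phylo` or `NULL` when every copy went extinct.
#' @slot trueRootCopies integer, root copies with surviving descendants.
#' @slot trueLineageOf named character, gene tip label -> `"copy_<i>"`.
#' @slot perSpeciesCounts named integer over all species (zeros kept).
#'
#' @export
setClass("SimulationResult",
  representation(
    geneTree = "ANY",
    trueRootCopies = "integer",
    trueLineageOf = "character",
    perSpeciesCounts = "integer"
  ))

setValidity("SimulationResult", function(object) {
  # geneTree is NULL both for total extinction and for a single surviving
  # gene (a one-leaf tree has no phylo representation); the census is
  # authoritative either way
  nLeaf <- sum(object@perSpeciesCounts)
  if (!is.null(object@geneTree) && .nTip(object@geneTree) != nLeaf)
    return("perSpeciesCounts must sum to the gene-tree leaf count")
  if (length(object@trueLineageOf) != nLeaf)
    return("trueLineageOf must cover every extant gene")
  TRUE
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult: ", length(object@trueLineageOf), " extant genes from ",
      object@trueRootCopies, " surviving root copies\n", sep = "")
})
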