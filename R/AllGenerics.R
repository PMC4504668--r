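#' @name chsLineage-accessors
#' @title Accessors for chsLineage result objects
#'
#' @description Small accessor generics so that downstream code never
#' touches slots directly: copy / species / loss counts of a
#' [GeneLineage-class], the members and per-species counts of a lineage,
#' the node mapping and event labels of a [Reconciliation-class], the
#' retention matrix of a [RetentionSummary-class], and the gene table of
#' a [GeneModelSet-class].
#'
#' @param x a chsLineage object.
#' @return Atomic vectors or matrices; see each method.
NULL

#' @rdname chsLineage-accessors
#' @export
setGeneric("nCopies", function(x) standardGeneric("nCopies"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("nLosses", function(x) standardGeneric("nLosses"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("lineageMembers", function(x) standardGeneric("lineageMembers"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("speciesCounts", function(x) standardGeneric("speciesCounts"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("lossEdges", function(x) standardGeneric("lossEdges"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("nodeMapping", function(x) standardGeneric("nodeMapping"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("retentionMatrix", function(x) standardGeneric("retentionMatrix"))

#' @rdname chsLineage-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname chsLineage-accessors
#' @export
setMethod("nCopies", "GeneLineage", function(x) length(x@members))

#' @rdname chsLineage-accessors
#' @export
setMethod("nSpecies", "GeneLineage", function(x) sum(x@speciesCounts > 0L))

#' @rdname chsLineage-accessors
#' @export
setMethod("nLosses", "GeneLineage", function(x) nrow(x@lossEdges))

#' @rdname chsLineage-accessors
#' @export
setMethod("lineageMembers", "GeneLineage", function(x) x@members)

#' @rdname chsLineage-accessors
#' @export
setMethod("speciesCounts", "GeneLineage", function(x) x@speciesCounts)

#' @rdname chsLineage-accessors
#' @export
setMethod("lossEdges", "GeneLineage", function(x) x@losses)

#' @rdname chsLineage-accessors
#' @export
setMethod("nodeMapping", "Reconciliation", function(x) x@mapping)

#' @rdname chsLineage-accessors
#' @export
setMethod("eventLabels", "Reconciliation", function(x) x@event)

#' @rdname chsLineage-accessors
#' @export
setMethod("retentionMatrix", "RetentionSummary", function(x) x@matrix)

#' @rdname chsLineage-accessors
#' @export
setMethod("geneTable", "GeneModelSet", function(x) {
  g <- x@genes
  data.frame(
    gene_id = g$gene_id,
    species = g$species,
    chromosome = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    n_exons = lengths(x@exons),
    status = g$status,
    reasons = g$reasons,
    assigned_name = g$assigned_name,
    stringsAsFactors = FALSE
  )
})
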