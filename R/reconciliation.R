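# Core inference: LCA mapping, event labelling, lineage decomposition,
# Dollo losses, retention summaries.  Everything here is deterministic.

# Per-node descendant-species incidence matrix of the species tree
# (nodes x species tips); the LCA of a species set is the node whose
# clade is the smallest superset of the set.
.speciesIncidence <- function(sphy) {
  nt <- .nTip(sphy)
  ch <- .childrenList(sphy)
  m <- matrix(FALSE, .nNode(sphy), nt)
  for (v in .postorderNodes(sphy)) {
    if (v <= nt) m[v, v] <- TRUE
    else for (c in ch[[v]]) m[v, ] <- m[v, ] | m[c, ]
  }
  m
}

#' LCA mapping of a gene tree onto a species tree
#'
#' Computes, bottom-up, the standard last-common-ancestor reconciliation
#' map `M`: each gene-tree leaf maps to its species-tree leaf, and each
#' internal gene-tree node maps to the species-tree LCA of its children's
#' images.  The image of an internal node is found as the smallest
#' species-tree clade containing every species below the node.
#'
#' @param geneTree rooted binary `phylo`, leaves are gene identifiers.
#' @param speciesTree rooted binary `phylo`, leaves are species.
#' @param speciesOf named character, gene leaf label -> species leaf
#'   label; see [speciesOfLeaf()].
#' @return A [Reconciliation-class] with the mapping filled in and all
#'   events `NA` (see [labelEvents()]).
#' @seealso [reconcile()] for mapping + labelling in one call.
#' @export
lcaMap <- function(geneTree, speciesTree, speciesOf) {
  .assertRootedBinary(geneTree, "gene tree")
  .assertRootedBinary(speciesTree, "species tree")
  labs <- geneTree$tip.label
  missing <- setdiff(labs, names(speciesOf))
  if (length(missing))
    stop("unmapped gene leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  spIdx <- match(speciesOf[labs], speciesTree$tip.label)
  if (anyNA(spIdx))
    stop("species not in species tree: ",
         paste(unique(speciesOf[labs][is.na(spIdx)]), collapse = ", "),
         call. = FALSE)

  inc <- .speciesIncidence(speciesTree)
  cladeSize <- rowSums(inc)
  ch <- .childrenList(geneTree)
  nt <- .nTip(geneTree)
  M <- integer(.nNode(geneTree))
  M[seq_len(nt)] <- spIdx
  for (v in .postorderNodes(geneTree)) {
    if (v <= nt) next
    kids <- M[ch[[v]]]
    need <- colSums(inc[kids, , drop = FALSE]) > 0
    covers <- which(inc[, need, drop = FALSE] %*% rep(1L, sum(need)) ==
                      sum(need))
    M[v] <- covers[which.min(cladeSize[covers])]
  }
  new("Reconciliation", geneTree = geneTree, speciesTree = speciesTree,
      speciesOf = speciesOf[labs], mapping = M,
      event = rep(NA_character_, .nNode(geneTree)))
}

#' Label gene-tree nodes as duplications or speciations
#'
#' An internal node `v` is a duplication iff its image `M(v)` equals the
#' image of at least one of its children; otherwise it is a speciation.
#'
#' @param recon a [Reconciliation-class] from [lcaMap()].
#' @return The same object with the `event` slot filled.
#' @export
labelEvents <- function(recon) {
  stopifnot(is(recon, "Reconciliation"))
  gphy <- recon@geneTree
  ch <- .childrenList(gphy)
  nt <- .nTip(gphy)
  M <- recon@mapping
  ev <- rep(NA_character_, .nNode(gphy))
  for (v in (nt + 1L):.nNode(gphy)) {
    ev[v] <- if (M[v] %in% M[ch[[v]]]) "duplication" else "speciation"
  }
  recon@event <- ev
  validObject(recon)
  recon
}

#' Reconcile a gene tree against a species tree
#'
#' Convenience wrapper: [lcaMap()] followed by [labelEvents()].
#'
#' @inheritParams lcaMap
#' @return A fully labelled [Reconciliation-class].
#' @examples
#' st <- parseNewick("((A,B),(C,D));")
#' gt <- parseNewick("((A_g1,B_g1),(A_g2,(C_g1,D_g1)));")
#' reconcile(gt, st, speciesOfLeaf(gt$tip.label))
#' @export
reconcile <- function(geneTree, speciesTree, speciesOf) {
  labelEvents(lcaMap(geneTree, speciesTree, speciesOf))
}

#' Decompose a gene tree into ancestral gene lineages
#'
#' Ancestral lineages are the maximal gene-tree clades that trace back to
#' distinct gene copies in the species-tree root: let `D` be the set of
#' internal gene-tree nodes that are duplications mapping to the species
#' root.  Lineage roots are the gene-tree root if it is not in `D`, plus
#' every node outside `D` whose parent is in `D`.  Every leaf belongs to
#' exactly one lineage.  For each lineage, Dollo losses are inferred with
#' presence forced at the species root (see [dolloLosses()]).
#'
#' @param recon a labelled [Reconciliation-class] (from [reconcile()]).
#' @return List of [GeneLineage-class] objects, ids `lineage_1`,
#'   `lineage_2`, ... in pre-order of their root nodes.
#' @export
decomposeLineages <- function(recon) {
  stopifnot(is(recon, "Reconciliation"))
  if (all(is.na(recon@event)))
    stop("events not labelled; run labelEvents() first", call. = FALSE)
  gphy <- recon@geneTree
  sphy <- recon@speciesTree
  nt <- .nTip(gphy)
  M <- recon@mapping
  sroot <- .rootNode(sphy)
  groot <- .rootNode(gphy)
  inD <- which(recon@event %in% "duplication" & M == sroot)

  parent <- .parentVec(gphy)
  roots <- integer(0)
  if (!groot %in% inD) roots <- groot
  cand <- setdiff(seq_len(.nNode(gphy)), inD)
  roots <- c(roots, cand[parent[cand] %in% inD])
  # pre-order rank of lineage roots
  pre <- .preorderNodes(gphy)
  roots <- roots[order(match(roots, pre))]

  desc <- .descendantTips(gphy)
  species <- sphy$tip.label
  lapply(seq_along(roots), function(k) {
    tips <- desc[[roots[k]]]
    members <- gphy$tip.label[tips]
    counts <- table(factor(unname(recon@speciesOf[members]),
                           levels = species))
    counts <- setNames(as.integer(counts), species)
    dl <- dolloLosses(species[counts > 0L], sphy)
    new("GeneLineage",
        lineageId = paste0("lineage_", k),
        rootNode = roots[k],
        members = members,
        speciesCounts = counts,
        losses = dl$labels,
        lossEdges = dl$edges)
  })
}

#' Dollo-parsimony losses for one lineage
#'
#' Under Dollo parsimony with a single origin forced at the species-tree
#' root, a node is "present" iff it is the root or an ancestor-or-self of
#' a species carrying the lineage; losses are the edges from a present
#' parent to an absent child.  This is the minimum loss count compatible
#' with root presence and no regain.  For comparison the unconstrained
#' minimum (origin allowed at the MRCA of the carrying species) is also
#' returned.
#'
#' @param presentSpecies character, species (tip labels) carrying the
#'   lineage.
#' @param speciesTree rooted binary `phylo`.
#' @return List with `edges` (two-column matrix of species-tree node
#'   numbers, parent then child), `labels` (`"parent->child"` using node
#'   labels where available), `nLosses`, and `nLossesUnconstrained`.
#' @examples
#' st <- parseNewick("((A,B),(C,D));")
#' dolloLosses("A", st)$nLosses  # lost on the B edge and the (C,D) edge
#' @export
dolloLosses <- function(presentSpecies, speciesTree) {
  .assertRootedBinary(speciesTree, "species tree")
  sphy <- speciesTree
  bad <- setdiff(presentSpecies, sphy$tip.label)
  if (length(bad))
    stop("species absent from species tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(presentSpecies) == 0L)
    stop("lineage must be present in at least one species", call. = FALSE)
  nt <- .nTip(sphy)
  tipIdx <- match(unique(presentSpecies), sphy$tip.label)
  ch <- .childrenList(sphy)
  # present[v]: v is ancestor-or-self of a carrying tip
  present <- logical(.nNode(sphy))
  present[tipIdx] <- TRUE
  for (v in .postorderNodes(sphy)) {
    if (v > nt) present[v] <- any(present[ch[[v]]])
  }
  root <- .rootNode(sphy)
  present[root] <- TRUE
  lossRows <- which(present[sphy$edge[, 1L]] & !present[sphy$edge[, 2L]])
  # under the unconstrained origin (MRCA of carriers) the losses above the
  # MRCA vanish: drop loss edges not descending from the MRCA
  mrca <- if (length(tipIdx) == 1L) tipIdx else {
    anc <- root
    repeat {
      kids <- ch[[anc]]
      below <- vapply(kids, function(k)
        all(tipIdx %in% .subtreeNodes(sphy, k)), logical(1))
      if (sum(below) == 1L) anc <- kids[below] else break
    }
    anc
  }
  inMrca <- .subtreeNodes(sphy, mrca)
  uncRows <- lossRows[sphy$edge[lossRows, 1L] %in% inMrca]
  edges <- sphy$edge[lossRows, , drop = FALSE]
  labels <- vapply(seq_len(nrow(edges)), function(i)
    paste0(.nodeLabel(sphy, edges[i, 1L]), "->",
           .nodeLabel(sphy, edges[i, 2L])), character(1))
  list(edges = edges, labels = labels, nLosses = nrow(edges),
       nLossesUnconstrained = length(uncRows))
}

#' Retention summary over species and lineages
#'
#' Builds the species-by-lineage copy-count matrix and counts how many
#' species retained two or more lineages versus exactly one.
#'
#' @param lineages list of [GeneLineage-class] from [decomposeLineages()].
#' @param species character, the full species list (matrix rows); default
#'   is the species covered by the lineages.
#' @return A [RetentionSummary-class].
#' @export
retentionSummary <- function(lineages, species = NULL) {
  if (!length(lineages)) {
    species <- if (is.null(species)) character(0) else species
    m <- matrix(0L, nrow = length(species), ncol = 0L,
                dimnames = list(species, NULL))
    return(new("RetentionSummary", matrix = m,
               lineagesPerSpecies = setNames(integer(length(species)),
                                             species),
               nMulti = 0L, nSingle = 0L))
  }
  if (is.null(species)) species <- names(speciesCounts(lineages[[1]]))
  m <- vapply(lineages, function(l) speciesCounts(l)[species],
              integer(length(species)))
  m <- matrix(m, nrow = length(species),
              dimnames = list(species,
                              vapply(lineages, function(l) l@lineageId,
                                     character(1))))
  lps <- setNames(as.integer(rowSums(m > 0L)), species)
  new("RetentionSummary", matrix = m, lineagesPerSpecies = lps,
      nMulti = sum(lps >= 2L), nSingle = sum(lps == 1L))
}

#' Per-species copy counts inside the paralog sub-clades of a lineage
#'
#' Splits a lineage at the duplication node whose LCA image is a given
#' species-tree ancestor (e.g. the Fabales crown) and tabulates per-species
#' copy counts in the two resulting paralog sub-clades.  Used to quantify
#' differential expansion of the two paralogs a shared ancestral
#' duplication produced.
#'
#' @param recon a labelled [Reconciliation-class].
#' @param lineage a [GeneLineage-class] from the same reconciliation.
#' @param ancestorSpecies character, species tip labels whose MRCA in the
#'   species tree identifies the duplication of interest.
#' @return Integer matrix, species x 2 sub-clades (columns `subclade_A`,
#'   `subclade_B` in gene-tree child order).
#' @export
paralogSubcladeCounts <- function(recon, lineage, ancestorSpecies) {
  stopifnot(is(recon, "Reconciliation"), is(lineage, "GeneLineage"))
  sphy <- recon@speciesTree
  gphy <- recon@geneTree
  target <- if (length(ancestorSpecies) == 1L)
    match(ancestorSpecies, sphy$tip.label)
  else ape::getMRCA(sphy, ancestorSpecies)
  sub <- .subtreeNodes(gphy, lineage@rootNode)
  dupNodes <- sub[recon@event[sub] %in% "duplication" &
                    recon@mapping[sub] == target]
  if (!length(dupNodes))
    stop("no duplication mapping to the requested ancestor in this lineage",
         call. = FALSE)
  # the apical such duplication: the one not descending from another
  pre <- .preorderNodes(gphy)
  dupNode <- dupNodes[which.min(match(dupNodes, pre))]
  ch <- .childrenList(gphy)[[dupNode]]
  desc <- .descendantTips(gphy)
  species <- sphy$tip.label
  cols <- lapply(ch, function(k) {
    mem <- gphy$tip.label[desc[[k]]]
    tab <- table(factor(unname(recon@speciesOf[mem]), levels = species))
    setNames(as.integer(tab), species)
  })
  out <- cbind(subclade_A = cols[[1]], subclade_B = cols[[2]])
  rownames(out) <- species
  out
}
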