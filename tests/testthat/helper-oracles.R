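# Independent brute-force oracles used across the suite.  These never call
# package internals: they work directly on ape 'phylo' edge matrices and,
# for translation, on seqinr.

.oracleRoot <- function(phy) length(phy$tip.label) + 1L

.oracleChildren <- function(phy, v) phy$edge[phy$edge[, 1] == v, 2]

.oracleParent <- function(phy, v) {
  p <- phy$edge[phy$edge[, 2] == v, 1]
  if (length(p)) p else NA_integer_
}

# path from the root to node v (inclusive), via repeated parent lookup
.oraclePathToRoot <- function(phy, v) {
  path <- v
  while (!is.na(p <- .oracleParent(phy, v))) {
    path <- c(p, path)
    v <- p
  }
  path
}

# LCA of a set of species-tree tip indices by root-path intersection:
# the last node shared by all root paths
oracleSpeciesLca <- function(sphy, tipIdx) {
  paths <- lapply(unique(tipIdx), function(t) .oraclePathToRoot(sphy, t))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# tips below each gene-tree node, by walking the edge matrix
.oracleTipsBelow <- function(phy, v) {
  nt <- length(phy$tip.label)
  if (v <= nt) return(v)
  unlist(lapply(.oracleChildren(phy, v), .oracleTipsBelow, phy = phy))
}

# brute-force LCA map: for every gene-tree node, intersect the species-tree
# root paths of all species below it
oracleLcaMap <- function(geneTree, speciesTree, speciesOf) {
  nt <- length(geneTree$tip.label)
  nn <- nt + geneTree$Nnode
  vapply(seq_len(nn), function(v) {
    tips <- .oracleTipsBelow(geneTree, v)
    spIdx <- match(speciesOf[geneTree$tip.label[tips]],
                   speciesTree$tip.label)
    oracleSpeciesLca(speciesTree, spIdx)
  }, integer(1))
}

oracleEvents <- function(geneTree, M) {
  nt <- length(geneTree$tip.label)
  ev <- rep(NA_character_, nt + geneTree$Nnode)
  for (v in (nt + 1L):(nt + geneTree$Nnode)) {
    ev[v] <- if (M[v] %in% M[.oracleChildren(geneTree, v)])
      "duplication" else "speciation"
  }
  ev
}

# brute-force minimal Dollo losses: enumerate every presence labeling of
# the internal nodes (root forced present, tips fixed by the carriers,
# child-present => parent-present), count present->absent edges, minimize
oracleDolloLosses <- function(speciesTree, presentSpecies) {
  nt <- length(speciesTree$tip.label)
  nn <- nt + speciesTree$Nnode
  root <- nt + 1L
  tipState <- speciesTree$tip.label %in% presentSpecies
  free <- setdiff((nt + 1L):nn, root)
  best <- Inf
  for (mask in 0:(2^length(free) - 1L)) {
    present <- logical(nn)
    present[seq_len(nt)] <- tipState
    present[root] <- TRUE
    if (length(free))
      present[free] <- bitwAnd(mask, 2^(seq_along(free) - 1L)) > 0
    e <- speciesTree$edge
    # Dollo: no regain below an absent node
    if (any(!present[e[, 1]] & present[e[, 2]])) next
    losses <- sum(present[e[, 1]] & !present[e[, 2]])
    if (losses < best) best <- losses
  }
  best
}

# six-frame ORF scan with seqinr: is there a frame (either strand) whose
# translation is stop-free over n codons ending right before a stop?
oracleSixFrameOrf <- function(cdsChar) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  strands <- c(cdsChar, revcomp(cdsChar))
  for (s in strands) for (f in 0:2) {
    aa <- seqinr::translate(strsplit(s, "")[[1]], frame = f)
    n <- length(aa)
    if (n < 2) next
    if (aa[n] == "*" && !any(aa[-n] == "*")) return(TRUE)
  }
  FALSE
}

oracleTranslate <- function(ntChar, frame = 0L) {
  paste(seqinr::translate(strsplit(ntChar, "")[[1]], frame = frame),
        collapse = "")
}

# --- exhaustive rooted binary tree enumeration -------------------------

# all rooted binary topologies over the given leaf labels, as nested lists
.allTopologies <- function(leaves) {
  insertAll <- function(t, x) {
    res <- list(list(t, x))
    if (is.list(t)) {
      for (i in 1:2) {
        for (s in insertAll(t[[i]], x)) {
          nt <- t
          nt[[i]] <- s
          res <- c(res, list(nt))
        }
      }
    }
    res
  }
  trees <- list(leaves[[1]])
  for (x in leaves[-1]) {
    trees <- unlist(lapply(trees, insertAll, x = x), recursive = FALSE)
  }
  trees
}

.topoToNewick <- function(t) {
  if (!is.list(t)) return(t)
  paste0("(", .topoToNewick(t[[1]]), ",", .topoToNewick(t[[2]]), ")")
}

allGeneTreeNewicks <- function(nLeaves) {
  vapply(.allTopologies(paste0("g", seq_len(nLeaves))),
         function(t) paste0(.topoToNewick(t), ";"), character(1))
}

# fixed 4-species tree used by the oracle-equivalence suites
oracleSpeciesTree4 <- function() {
  chsLineage::parseNewick("((A:10,B:10):5,(C:8,D:8):7);")
}
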