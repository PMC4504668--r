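# Internal helpers over ape "phylo" objects.  Node numbering follows ape:
# tips 1..Ntip, root Ntip+1, internal nodes Ntip+1 .. Ntip+Nnode.

.nTip <- function(phy) length(phy$tip.label)

.nNode <- function(phy) .nTip(phy) + phy$Nnode

.rootNode <- function(phy) .nTip(phy) + 1L

.parentVec <- function(phy) {
  p <- integer(.nNode(phy))
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

.childrenList <- function(phy) {
  ch <- vector("list", .nNode(phy))
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]
    ch[[a]] <- c(ch[[a]], phy$edge[i, 2L])
  }
  ch
}

# Nodes in postorder (every node after all its descendants); root last.
.postorderNodes <- function(phy) {
  e <- stats::reorder(phy, "postorder")$edge
  c(e[, 2L][!duplicated(e[, 2L])], .rootNode(phy))
}

# Nodes in preorder (root first, every node before its descendants).
.preorderNodes <- function(phy) rev(.postorderNodes(phy))

# List: node -> integer vector of descendant tip indices (self for tips).
.descendantTips <- function(phy) {
  nt <- .nTip(phy)
  ch <- .childrenList(phy)
  out <- vector("list", .nNode(phy))
  for (v in .postorderNodes(phy)) {
    out[[v]] <- if (v <= nt) v else sort(unlist(out[ch[[v]]], use.names = FALSE))
  }
  out
}

# All nodes (incl. tips and v itself) in the subtree rooted at v.
.subtreeNodes <- function(phy, v) {
  ch <- .childrenList(phy)
  acc <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    acc <- c(acc, x)
    stack <- c(stack, ch[[x]])
  }
  acc
}

# Label for a species-tree node: tip label, node label if present, else "node<i>".
.nodeLabel <- function(phy, v) {
  nt <- .nTip(phy)
  if (v <= nt) return(phy$tip.label[v])
  lab <- phy$node.label[v - nt]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) paste0("node", v) else lab
}

.assertRootedBinary <- function(phy, what) {
  if (!inherits(phy, "phylo"))
    stop(what, " must be a 'phylo' object", call. = FALSE)
  if (!ape::is.rooted(phy))
    stop(what, " must be rooted", call. = FALSE)
  if (!ape::is.binary(phy))
    stop(what, " must be binary (resolve polytomies first)", call. = FALSE)
  invisible(TRUE)
}
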