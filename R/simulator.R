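# Birth-death gene gain/loss simulation along a dated species tree.
# Each of k independent root copies evolves down the tree: on a branch of
# length t a copy duplicates at rate lam and dies at rate mu (exponential
# waiting times); at speciation nodes every live copy is transmitted to
# both children.  Extinct subtrees are pruned and unary nodes suppressed
# during construction, so the returned gene tree contains only surviving
# copies.

# Recursive simulation.  Returns NULL on extinction, else
# list(stem = <length from the entry point to the apex>, nwk = <newick
# fragment without stem length>, leaves = <character leaf labels>).
.simBranch <- function(sphy, ch, node, t, lam, mu, counter) {
  total <- lam + mu
  wait <- if (total > 0) stats::rexp(1L, total) else Inf
  if (wait < t) {
    if (stats::runif(1L) < lam / total) {   # duplication
      a <- .simBranch(sphy, ch, node, t - wait, lam, mu, counter)
      b <- .simBranch(sphy, ch, node, t - wait, lam, mu, counter)
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(b)) { a$stem <- a$stem + wait; return(a) }
      if (is.null(a)) { b$stem <- b$stem + wait; return(b) }
      return(list(stem = wait,
                  nwk = sprintf("(%s:%g,%s:%g)", a$nwk, a$stem,
                                b$nwk, b$stem),
                  leaves = c(a$leaves, b$leaves)))
    }
    return(NULL)                            # loss
  }
  .simAtNode(sphy, ch, node, t, lam, mu, counter)
}

# A copy arriving at species-tree `node` after surviving a stem of length t.
.simAtNode <- function(sphy, ch, node, stem, lam, mu, counter) {
  nt <- .nTip(sphy)
  if (node <= nt) {
    sp <- sphy$tip.label[node]
    counter[[sp]] <- counter[[sp]] + 1L
    lab <- sprintf("%s_%d", sp, counter[[sp]])
    return(list(stem = stem, nwk = lab, leaves = lab))
  }
  kids <- ch[[node]]
  res <- lapply(kids, function(k) {
    row <- which(sphy$edge[, 2L] == k)
    .simBranch(sphy, ch, k, sphy$edge.length[row], lam, mu, counter)
  })
  res <- Filter(Negate(is.null), res)
  if (length(res) == 0L) return(NULL)
  if (length(res) == 1L) {
    res[[1]]$stem <- res[[1]]$stem + stem
    return(res[[1]])
  }
  list(stem = stem,
       nwk = sprintf("(%s:%g,%s:%g)", res[[1]]$nwk, res[[1]]$stem,
                     res[[2]]$nwk, res[[2]]$stem),
       leaves = c(res[[1]]$leaves, res[[2]]$leaves))
}

#' Simulate a gene family under a birth-death process
#'
#' Evolves `k` independent gene copies from the species-tree root down a
#' dated species tree.  On a branch of length `t` (same time units as the
#' branch lengths, typically million years) each live copy duplicates at
#' rate `lam` per copy and is lost at rate `mu` per copy; at speciations
#' every live copy is transmitted to both descendant species.  Extinct
#' subtrees are pruned and unary nodes suppressed.  Surviving root copies
#' are joined at the root by zero-length edges, representing duplications
#' that predate the root ancestor, so the result is a single rooted
#' binary gene tree whose root-mapped duplication nodes delimit the true
#' lineages.  Leaves are labelled `<species>_<index>`.
#'
#' Replicates where every copy goes extinct are reported (gene tree
#' `NULL`, zero counts), never silently resampled, so downstream
#' estimators stay unbiased.
#'
#' @param speciesTree rooted binary `phylo` with positive branch lengths.
#' @param lam,mu duplication and loss rates per gene copy per time unit.
#' @param k integer >= 1, copy number at the species-tree root.
#' @param seed integer seed; identical seeds give identical results.
#' @return A [SimulationResult-class].
#' @examples
#' st <- parseNewick("((A:10,B:10):5,C:15);")
#' simulateGeneFamily(st, lam = 0, mu = 0, k = 3, seed = 1)
#' @export
simulateGeneFamily <- function(speciesTree, lam, mu, k, seed = NULL) {
  .assertRootedBinary(speciesTree, "species tree")
  if (is.null(speciesTree$edge.length) ||
      any(!is.finite(speciesTree$edge.length)) ||
      any(speciesTree$edge.length <= 0))
    stop("species tree must have positive branch lengths", call. = FALSE)
  if (lam < 0 || mu < 0) stop("rates must be >= 0", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  ch <- .childrenList(speciesTree)
  species <- speciesTree$tip.label
  counter <- new.env(parent = emptyenv())
  for (sp in species) counter[[sp]] <- 0L

  copies <- vector("list", k)
  lineageOf <- character(0)
  for (i in seq_len(k)) {
    r <- .simAtNode(speciesTree, ch, .rootNode(speciesTree), 0, lam, mu,
                    counter)
    copies[[i]] <- r
    if (!is.null(r))
      lineageOf[r$leaves] <- sprintf("copy_%d", i)
  }
  alive <- Filter(Negate(is.null), copies)
  counts <- setNames(vapply(species, function(s) counter[[s]], integer(1)),
                     species)
  if (length(alive) == 0L)
    return(new("SimulationResult", geneTree = NULL, trueRootCopies = 0L,
               trueLineageOf = character(0), perSpeciesCounts = counts))
  # caterpillar join at the root with zero-length edges
  nwk <- alive[[1]]$nwk
  stem <- alive[[1]]$stem
  if (length(alive) > 1L) {
    for (i in 2L:length(alive)) {
      nwk <- sprintf("(%s:%g,%s:%g)", alive[[i]]$nwk, alive[[i]]$stem,
                     nwk, stem)
      stem <- 0
    }
  }
  nLeaf <- sum(counts)
  gt <- if (nLeaf >= 2L) ape::read.tree(text = paste0(nwk, ";")) else {
    # single surviving gene: a one-leaf "tree" is not a phylo; keep NULL
    NULL
  }
  if (nLeaf == 1L) {
    return(new("SimulationResult", geneTree = NULL,
               trueRootCopies = length(alive),
               trueLineageOf = lineageOf, perSpeciesCounts = counts))
  }
  new("SimulationResult", geneTree = gt,
      trueRootCopies = length(alive),
      trueLineageOf = lineageOf[gt$tip.label],
      perSpeciesCounts = counts)
}

#' Lineage-recovery experiment over simulated replicates
#'
#' For each replicate: simulate a gene family ([simulateGeneFamily()]),
#' run the reconciliation pipeline ([reconcile()] +
#' [decomposeLineages()]) on the true gene tree, and tabulate recovered
#' lineage count against the true number of surviving root copies.  Also
#' records whether every surviving root copy has extant members on both
#' sides of the species-root bipartition, the condition under which the
#' parsimony decomposition is exact.
#'
#' Per-replicate random streams are derived deterministically from
#' `seed`.
#'
#' @inheritParams simulateGeneFamily
#' @param nReplicates number of replicates.
#' @return `data.frame` with columns `replicate`, `n_genes`,
#'   `true_surviving_copies`, `recovered_lineages`, `all_copies_span_root`.
#' @export
recoveryExperiment <- function(speciesTree, lam, mu, k, nReplicates,
                               seed = 1L) {
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
  inc <- .speciesIncidence(speciesTree)
  root <- .rootNode(speciesTree)
  kids <- .childrenList(speciesTree)[[root]]
  leftSp <- speciesTree$tip.label[inc[kids[1L], ]]

  rows <- lapply(seq_len(nReplicates), function(i) {
    sim <- simulateGeneFamily(speciesTree, lam, mu, k, seed = repSeeds[i])
    nGenes <- sum(sim@perSpeciesCounts)
    if (is.null(sim@geneTree)) {
      return(data.frame(replicate = i, n_genes = nGenes,
                        true_surviving_copies = sim@trueRootCopies,
                        recovered_lineages = as.integer(nGenes > 0L),
                        all_copies_span_root = NA))
    }
    so <- speciesOfLeaf(sim@geneTree$tip.label)
    rec <- reconcile(sim@geneTree, speciesTree, so)
    lin <- decomposeLineages(rec)
    spans <- vapply(split(so[names(sim@trueLineageOf)],
                          sim@trueLineageOf),
                    function(sp) any(sp %in% leftSp) && any(!sp %in% leftSp),
                    logical(1))
    data.frame(replicate = i, n_genes = nGenes,
               true_surviving_copies = sim@trueRootCopies,
               recovered_lineages = length(lin),
               all_copies_span_root = all(spans))
  })
  do.call(rbind, rows)
}
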