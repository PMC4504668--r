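test_that("leaf mapping and same-species cherries behave as forced", {
  st <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  gt <- parseNewick("((A_g1,A_g2),(B_g1,C_g1));")
  rec <- reconcile(gt, st, speciesOfLeaf(gt$tip.label))
  M <- nodeMapping(rec)
  expect_equal(M[1], match("A", st$tip.label))  # leaf case
  # cherry of two A genes is a duplication mapped to the A leaf
  cherry <- ape::getMRCA(gt, c("A_g1", "A_g2"))
  expect_equal(M[cherry], match("A", st$tip.label))
  expect_equal(eventLabels(rec)[cherry], "duplication")
  expect_error(lcaMap(gt, st, c(A_g1 = "A")), "unmapped")
})

test_that("fixture events match the clade structure of the worked example", {
  st <- rosidSpeciesTree()
  gt <- rosidGeneTree()
  rec <- reconcile(gt, st, speciesOfLeaf(gt$tip.label))
  lin <- decomposeLineages(rec)
  colors <- lineageColorMap(lin)
  sroot <- length(st$tip.label) + 1L

  # pink lineage root maps to the Fabales ancestor and is a duplication
  pink <- lin[[which(colors == "pink")]]
  fab <- ape::getMRCA(st, c("Gmax", "Mtruncatula", "Ljaponicus"))
  expect_equal(nodeMapping(rec)[pink@rootNode], fab)
  expect_equal(eventLabels(rec)[pink@rootNode], "duplication")

  # green lineage root joins Brassicales and Fabales subtrees: a
  # speciation mapped to the species root
  green <- lin[[which(colors == "green")]]
  expect_equal(nodeMapping(rec)[green@rootNode], sroot)
  expect_equal(eventLabels(rec)[green@rootNode], "speciation")

  # every lineage root's parent is a duplication mapped to the species root
  parents <- integer(0)
  for (l in lin) {
    p <- gt$edge[gt$edge[, 2] == l@rootNode, 1]
    if (length(p)) parents <- c(parents, p)
  }
  expect_true(all(eventLabels(rec)[parents] == "duplication"))
  expect_true(all(nodeMapping(rec)[parents] == sroot))
})

test_that("decomposition yields one lineage when no root-mapped duplication", {
  st <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  gt <- parseNewick("((A_g1,B_g1),(C_g1,D_g1));")
  rec <- reconcile(gt, st, speciesOfLeaf(gt$tip.label))
  lin <- decomposeLineages(rec)
  expect_length(lin, 1L)
  expect_equal(nCopies(lin[[1]]), 4L)
  expect_equal(nLosses(lin[[1]]), 0L)
})

test_that("Dollo losses match the worked example and the brute force", {
  st <- rosidSpeciesTree()
  # blue lineage: cassava only -> 4 losses (malvids; Rosales+Fabales
  # clade; poplar; castor bean)
  blue <- dolloLosses("Mesculenta", st)
  expect_equal(blue$nLosses, 4L)
  expect_setequal(blue$labels,
                  c("rosids->malvids", "fabids->NFixing",
                    "Malpighiales->Ptrichocarpa", "MesRco->Rcommunis"))
  expect_equal(blue$nLosses, oracleDolloLosses(st, "Mesculenta"))
  # green lineage: 3 Brassicales + 3 Fabales -> 3 losses
  green <- dolloLosses(c("Athaliana", "Alyrata", "Brapa", "Gmax",
                         "Mtruncatula", "Ljaponicus"), st)
  expect_equal(green$nLosses, 3L)
  expect_setequal(green$labels,
                  c("malvids->Tcacao", "fabids->Malpighiales",
                    "NFixing->Rosales"))
  # present everywhere -> no losses
  expect_equal(dolloLosses(st$tip.label, st)$nLosses, 0L)
  # single-species lineages: the unconstrained origin needs no losses
  expect_equal(blue$nLossesUnconstrained, 0L)
  expect_error(dolloLosses("NotASpecies", st), "absent")
})

test_that("exhaustive small trees agree with brute-force oracles", {
  st4 <- oracleSpeciesTree4()
  species <- st4$tip.label
  nCases <- 0L
  mismatches <- 0L
  for (n in 2:4) {
    newicks <- allGeneTreeNewicks(n)
    assignments <- as.matrix(expand.grid(rep(list(species), n),
                                         stringsAsFactors = FALSE))
    for (nwk in newicks) {
      gt <- parseNewick(nwk)
      leafOrder <- match(gt$tip.label, paste0("g", 1:n))
      for (r in seq_len(nrow(assignments))) {
        so <- setNames(assignments[r, leafOrder], gt$tip.label)
        rec <- reconcile(gt, st4, so)
        Moracle <- oracleLcaMap(gt, st4, so)
        ok <- identical(nodeMapping(rec), Moracle) &&
          identical(eventLabels(rec), oracleEvents(gt, Moracle))
        if (ok) for (l in decomposeLineages(rec)) {
          carriers <- names(speciesCounts(l))[speciesCounts(l) > 0]
          if (!identical(nLosses(l), oracleDolloLosses(st4, carriers))) {
            ok <- FALSE
            break
          }
        }
        nCases <- nCases + 1L
        if (!ok) mismatches <- mismatches + 1L
      }
    }
  }
  expect_equal(nCases, 16L + 192L + 3840L)
  expect_equal(mismatches, 0L)
})

test_that("random simulated trees agree with brute-force oracles", {
  st4 <- oracleSpeciesTree4()
  checked <- 0L
  i <- 0L
  while (checked < 60L) {
    i <- i + 1L
    sim <- simulateGeneFamily(st4, lam = 0.06, mu = 0.03,
                              k = sample(1:3, 1), seed = 1000L + i)
    if (is.null(sim@geneTree)) next
    checked <- checked + 1L
    gt <- sim@geneTree
    so <- speciesOfLeaf(gt$tip.label)
    rec <- reconcile(gt, st4, so)
    Moracle <- oracleLcaMap(gt, st4, so)
    expect_identical(nodeMapping(rec), Moracle)
    expect_identical(eventLabels(rec), oracleEvents(gt, Moracle))
  }
})

test_that("lineage copies are conserved and decomposition is deterministic", {
  st <- rosidSpeciesTree()
  gt <- rosidGeneTree()
  so <- speciesOfLeaf(gt$tip.label)
  rec <- reconcile(gt, st, so)
  lin <- decomposeLineages(rec)
  # conservation: lineage members partition the ingroup leaves
  members <- unlist(lapply(lin, lineageMembers))
  expect_setequal(members, gt$tip.label)
  expect_equal(sum(vapply(lin, nCopies, integer(1))),
               length(gt$tip.label))
  # matrix row/col sums agree with lineage and species censuses
  ret <- retentionSummary(lin, st$tip.label)
  m <- retentionMatrix(ret)
  expect_equal(unname(colSums(m)), vapply(lin, nCopies, integer(1)))
  expect_equal(rowSums(m)[names(table(so))],
               setNames(as.numeric(table(so)), names(table(so))))
  # determinism
  lin2 <- decomposeLineages(reconcile(gt, st, so))
  expect_identical(lapply(lin, lineageMembers),
                   lapply(lin2, lineageMembers))
})

test_that("retention summary counts multi- and single-lineage species", {
  st <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  gt <- parseNewick("((A_g1,B_g1),(C_g1,D_g1));")
  lin <- decomposeLineages(reconcile(gt, st, speciesOfLeaf(gt$tip.label)))
  ret <- retentionSummary(lin, st$tip.label)
  expect_equal(ret@nMulti, 0L)
  expect_equal(ret@nSingle, 4L)
  empty <- retentionSummary(list(), species = st$tip.label)
  expect_equal(empty@nMulti + empty@nSingle, 0L)
})
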