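test_that("the species tree matches the study clade structure", {
  st <- rosidSpeciesTree()
  expect_equal(length(st$tip.label), 12L)
  expect_true(ape::is.ultrametric(st))
  expect_equal(max(ape::node.depth.edgelength(st)), 107)
  # barrel medic + Lotus japonicus form a clade excluding soybean
  ml <- ape::getMRCA(st, c("Mtruncatula", "Ljaponicus"))
  below <- ape::extract.clade(st, ml)$tip.label
  expect_setequal(below, c("Mtruncatula", "Ljaponicus"))
  # Fabales crown age inside the 97-57 my calibration window
  depths <- ape::node.depth.edgelength(st)
  fab <- ape::getMRCA(st, c("Gmax", "Mtruncatula", "Ljaponicus"))
  fabAge <- max(depths) - depths[fab]
  expect_gt(fabAge, 57)
  expect_lt(fabAge, 97)
})

test_that("the inventory reproduces the per-species gene censuses", {
  inv <- rosidGeneInventory()
  fun <- table(inv$species[inv$status == "functional"])
  expect_equal(fun[["Athaliana"]], 1L)
  expect_equal(fun[["Alyrata"]], 1L)
  expect_equal(fun[["Brapa"]], 4L)
  expect_equal(fun[["Tcacao"]], 2L)
  expect_equal(fun[["Mesculenta"]], 5L)
  expect_equal(fun[["Rcommunis"]], 1L)
  expect_equal(fun[["Ptrichocarpa"]], 4L)
  expect_equal(fun[["Mdomestica"]], 2L)
  expect_equal(fun[["Fvesca"]], 4L)
  expect_equal(fun[["Mtruncatula"]], 17L)
  expect_equal(fun[["Ljaponicus"]], 14L)
  expect_equal(fun[["Gmax"]], 15L)
  ps <- table(inv$species[inv$status == "pseudogene"])
  expect_equal(as.integer(ps[c("Mtruncatula", "Ljaponicus", "Brapa")]),
               c(2L, 2L, 3L))
})

test_that("the gene tree carries every functional gene exactly once", {
  inv <- rosidGeneInventory()
  gt <- rosidGeneTree()
  expect_setequal(gt$tip.label,
                  inv$gene_id[inv$status == "functional"])
  expect_true(ape::is.binary(gt) && ape::is.rooted(gt))
  # lineage colour census: the pink lineage totals 42 copies
  expect_equal(sum(inv$lineage %in% c("pinkA", "pinkB")), 42L)
  expect_equal(sum(inv$lineage %in% c("green", "greenX")), 10L)
  expect_equal(sum(inv$lineage %in% "brown"), 9L)
})

test_that("sequence generation is deterministic and classifies cleanly", {
  fxA <- generateFixtureSequences(seed = 1)
  fxB <- generateFixtureSequences(seed = 1)
  expect_identical(as.character(fxA$genome), as.character(fxB$genome))
  fxC <- generateFixtureSequences(seed = 2)
  expect_false(identical(as.character(fxA$genome),
                         as.character(fxC$genome)))
  # closed loop: planted statuses are recovered by the classifier
  tab <- geneTable(assignNames(annotateGenes(fxA$models, fxA$genome)))
  inv <- rosidGeneInventory()
  expect_equal(tab$status[match(inv$gene_id, tab$gene_id)], inv$status)
  # and tandem names reproduce the planted linkage order
  expected <- sprintf("%s-T%d%s", inv$chromosome, inv$t_index,
                      ifelse(inv$status == "pseudogene", "ps", ""))
  expect_equal(tab$assigned_name[match(inv$gene_id, tab$gene_id)],
               expected)
})

test_that("writeFixture emits a consistent bundle of files", {
  dir <- tempfile()
  files <- writeFixture(dir, seed = 3)
  expect_true(all(file.exists(files)))
  st <- parseNewick(file = files[["species_tree"]])
  gt <- parseNewick(file = files[["gene_tree"]])
  expect_equal(length(st$tip.label), 12L)
  expect_true(ape::all.equal.phylo(gt, rosidGeneTree(),
                                   use.edge.length = FALSE))
  map <- readSpeciesMap(files[["species_map"]])
  expect_setequal(names(map), gt$tip.label)
  ann <- read.table(files[["annotation"]], header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(sum(ann$status == "functional"), length(gt$tip.label))
})
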