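# The annotation tests build genes with the fixture generator's planted
# motifs and check the classifier against independent translation oracles.

.miniInventory <- function(statuses, species = "Sp", chrom = "c1") {
  data.frame(gene_id = sprintf("%s_%s_T%d", species, chrom,
                               seq_along(statuses)),
             species = species, chromosome = chrom,
             t_index = seq_along(statuses), status = statuses,
             lineage = NA_character_, stringsAsFactors = FALSE)
}

test_that("intact two-exon genes classify functional; oracle agrees", {
  fx <- generateFixtureSequences(.miniInventory(rep("functional", 4)),
                                 seed = 11)
  ann <- annotateGenes(fx$models, fx$genome)
  tab <- geneTable(ann)
  expect_true(all(tab$status == "functional"))
  # independent six-frame check: each functional CDS has a stop-free ORF
  for (i in seq_len(4)) {
    cds <- as.character(spliceCds(ann, fx$genome, i))
    expect_true(oracleSixFrameOrf(cds))
    expect_true(startsWith(cds, "ATG"))
  }
})

test_that("an internal stop turns a functional gene into a pseudogene", {
  cfg <- AnnotationConfig()
  fx <- generateFixtureSequences(.miniInventory("functional"), seed = 3)
  cds <- as.character(spliceCds(fx$models, fx$genome, 1))
  w <- GenomicRanges::width(fx$models@exons[[1]])
  if (as.character(GenomicRanges::strand(fx$models@genes[1])) == "-")
    w <- rev(w)
  expect_equal(validateStructure(w, cds, cfg)$status, "functional")
  # edit one internal codon of exon 2 (upstream of the signature) to TAA
  pos <- w[1] + 31L
  substr(cds, pos, pos + 2L) <- "TAA"
  v <- validateStructure(w, cds, cfg)
  expect_equal(v$status, "pseudogene")
  expect_true("internal_stop" %in% v$reasons)
})

test_that("an intact gene with a 30-aa first exon is rejected", {
  cfg <- AnnotationConfig()
  fx <- generateFixtureSequences(.miniInventory("functional"), seed = 5)
  cds <- as.character(spliceCds(fx$models, fx$genome, 1))
  w <- GenomicRanges::width(fx$models@exons[[1]])
  if (as.character(GenomicRanges::strand(fx$models@genes[1])) == "-")
    w <- rev(w)
  # truncate exon 1 to 30 codons: still ATG-led and in frame
  cut <- w[1] - 90L
  cds2 <- paste0(substr(cds, 1, 3), substr(cds, 4 + cut, nchar(cds)))
  v <- validateStructure(c(w[1] - cut, w[2]), cds2, cfg)
  expect_equal(v$status, "rejected")
  expect_true("exon1_length" %in% v$reasons)
})

test_that("reason codes enumerate every failed check and errors are raised", {
  cfg <- AnnotationConfig(signaturePattern = "WWWWW",
                          activeSitePattern = "HHHHH")
  # a 3-exon model fails exon_count and both motifs at least
  v <- validateStructure(c(120L, 120L, 120L),
                         paste(rep("ATG", 120), collapse = ""), cfg)
  expect_equal(v$status, "rejected")
  expect_true(all(c("exon_count", "signature_missing") %in% v$reasons))
  expect_error(validateStructure(integer(0), "", cfg), "empty")
  expect_error(validateStructure(c(10L), "ATGATG", cfg), "does not match")
})

test_that("classification is invariant under strand flip", {
  fx <- generateFixtureSequences(
    .miniInventory(c("functional", "pseudogene", "functional",
                     "pseudogene")), seed = 9)
  # generator alternates strands; build the opposite-strand version of the
  # whole chromosome and mirror all coordinates
  chrom <- fx$genome[[1]]
  L <- length(chrom)
  g <- fx$models@genes
  flipped <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(g)),
    IRanges::IRanges(L - GenomicRanges::end(g) + 1L,
                     L - GenomicRanges::start(g) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(g)) == "+",
                    "-", "+"))
  flipped$gene_id <- g$gene_id
  flipped$species <- g$species
  fex <- GenomicRanges::GRangesList(lapply(seq_along(g), function(i) {
    e <- fx$models@exons[[i]]
    r <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(e)),
      IRanges::IRanges(L - GenomicRanges::end(e) + 1L,
                       L - GenomicRanges::start(e) + 1L),
      strand = ifelse(as.character(GenomicRanges::strand(e)) == "+",
                      "-", "+"))
    r[order(GenomicRanges::start(r))]
  }))
  rcGenome <- Biostrings::DNAStringSet(
    setNames(as.character(Biostrings::reverseComplement(chrom)),
             names(fx$genome)[1]))
  a1 <- geneTable(annotateGenes(fx$models, fx$genome))
  a2 <- geneTable(annotateGenes(GeneModelSet(flipped, fex), rcGenome))
  expect_equal(a2$status[match(a1$gene_id, a2$gene_id)], a1$status)
})

test_that("T-index naming is ordered, suffixed, unique and idempotent", {
  fx <- generateFixtureSequences(
    .miniInventory(c("functional", "pseudogene", "functional")), seed = 2)
  ann <- assignNames(annotateGenes(fx$models, fx$genome))
  tab <- geneTable(ann)
  ord <- order(tab$start)
  expect_equal(tab$assigned_name[ord], c("c1-T1", "c1-T2ps", "c1-T3"))
  # bijection within the group and idempotence
  expect_false(anyDuplicated(tab$assigned_name) > 0)
  again <- geneTable(assignNames(ann))
  expect_identical(again$assigned_name, tab$assigned_name)

  # duplicate start coordinates are an ambiguous linkage order
  g2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1L, 1L),
                                                      c(90L, 90L)),
                               strand = "+")
  g2$gene_id <- c("a", "b"); g2$species <- "Sp"
  g2$status <- "functional"
  e2 <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("c1", IRanges::IRanges(1L, 90L), strand = "+"),
    GenomicRanges::GRanges("c1", IRanges::IRanges(1L, 90L), strand = "+"))
  expect_error(assignNames(GeneModelSet(g2, e2)), "duplicate start")
})

test_that("single genes and separate chromosomes each start at T1", {
  inv <- rbind(.miniInventory("functional", chrom = "cA"),
               .miniInventory(c("functional", "functional"), chrom = "cB"))
  inv$gene_id <- sprintf("Sp_%s_T%d", inv$chromosome, inv$t_index)
  fx <- generateFixtureSequences(inv, seed = 4)
  tab <- geneTable(assignNames(annotateGenes(fx$models, fx$genome)))
  expect_equal(tab$assigned_name[tab$chromosome == "cA"], "cA-T1")
  expect_setequal(tab$assigned_name[tab$chromosome == "cB"],
                  c("cB-T1", "cB-T2"))
})

test_that("GFF3 + FASTA round-trip reproduces the gene models", {
  fx <- generateFixtureSequences(
    .miniInventory(c("functional", "pseudogene")), seed = 6)
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "g.fasta"); gff <- file.path(dir, "g.gff3")
  Biostrings::writeXStringSet(fx$genome, fa)
  chsLineage:::.writeGff3(fx$models, gff)
  back <- readGeneModels(gff)
  genome <- Biostrings::readDNAStringSet(fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  t1 <- geneTable(annotateGenes(fx$models, fx$genome))
  t2 <- geneTable(annotateGenes(back, genome))
  expect_equal(t2$status[match(t1$gene_id, t2$gene_id)], t1$status)
  expect_equal(t2$start[match(t1$gene_id, t2$gene_id)], t1$start)
})
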