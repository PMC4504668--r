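# Canonical rosid CHS fixture: a 12-species dated tree, a gene tree whose
# decomposition yields six ancestral lineages, a matching annotation
# inventory, and a deterministic two-exon sequence generator.

.FIXTURE_SPECIES <- c("Athaliana", "Alyrata", "Brapa", "Tcacao",
                      "Mesculenta", "Rcommunis", "Ptrichocarpa",
                      "Mdomestica", "Fvesca", "Mtruncatula",
                      "Ljaponicus", "Gmax")

#' Canonical 12-species rosid species tree
#'
#' Ultrametric, dated in million years: root (rosid crown) at 107 my,
#' Fabales crown at 75 my (inside the 97-57 my calibration window for
#' the legume crown), with three Brassicales, cacao, three Malpighiales,
#' two Rosales and three Fabales.  Internal nodes are labelled with
#' clade names so that loss edges are human-readable.
#'
#' @return A rooted binary ultrametric `phylo` with 12 tips.
#' @examples
#' rosidSpeciesTree()
#' @export
rosidSpeciesTree <- function() {
  nwk <- paste0(
    "((((Athaliana:10,Alyrata:10)Arabidopsis:33,Brapa:43)Brassicales:57,",
    "Tcacao:100)malvids:7,",
    "((Ptrichocarpa:90,(Mesculenta:70,Rcommunis:70)MesRco:20)",
    "Malpighiales:14,",
    "((Mdomestica:80,Fvesca:80)Rosales:21,",
    "(Gmax:75,(Mtruncatula:50,Ljaponicus:50)MedLot:25)Fabales:26)",
    "NFixing:3)fabids:3)rosids;")
  parseNewick(nwk)
}

# Gene inventory: per species, per chromosome, the ordered tandem array.
# Entries are lineage tags for functional genes ("greenX" is the
# Brassicales-ancestor duplicate retained only by field mustard) and
# "ps" for pseudogenes.  T indices follow this order.
.fixtureLayout <- function() {
  list(
    Athaliana   = list(At5  = c("green")),
    Alyrata     = list(Al7  = c("green")),
    Brapa       = list(Br3  = c("greenX", "ps", "green"),
                       Br9  = c("green", "green", "ps", "ps")),
    Tcacao      = list(Tc1  = c("red"),
                       Tc5  = c("brown")),
    Mesculenta  = list(Me2  = rep("blue", 4),
                       Me6  = c("brown")),
    Rcommunis   = list(Rc30 = c("brown")),
    Ptrichocarpa = list(Pt1 = c("yellow"),
                        Pt3 = c("red"),
                        Pt14 = rep("brown", 2)),
    Mdomestica  = list(Md4  = rep("brown", 2)),
    Fvesca      = list(Fv2  = rep("red", 2),
                       Fv7  = rep("brown", 2)),
    Mtruncatula = list(Mt1  = c(rep("pinkA", 4), "ps", rep("pinkA", 4)),
                       Mt4  = c(rep("pinkA", 3), "ps", rep("pinkA", 3)),
                       Mt7  = rep("pinkB", 2),
                       Mt8  = c("green")),
    Ljaponicus  = list(Lj2  = c(rep("pinkA", 3), "ps", rep("pinkA", 3)),
                       Lj5  = c("pinkA", "pinkA", "ps", rep("pinkA", 3)),
                       Lj6  = c("green", "pinkB", "pinkB")),
    Gmax        = list(Gm01 = rep("pinkB", 2),
                       Gm02 = rep("pinkB", 2),
                       Gm05 = c("pinkA", "pinkB"),
                       Gm08 = rep("pinkB", 6),
                       Gm09 = c("green"),
                       Gm11 = c("green"),
                       Gm13 = c("pinkA"))
  )
}

#' Fixture gene inventory
#'
#' One row per gene model of the canonical fixture: identifier, species,
#' chromosome, tandem index, status and (for functional genes) the
#' ancestral-lineage colour it belongs to.  Per-species functional
#' totals are 1, 1, 4, 2, 5, 1, 4, 2, 4, 17, 14 and 15 (barrel medic 17,
#' soybean 15), with 2 + 2 + 3 pseudogenes in barrel medic, *Lotus
#' japonicus* and field mustard.
#'
#' @return `data.frame` with columns `gene_id`, `species`, `chromosome`,
#'   `t_index`, `status`, `lineage`.
#' @export
rosidGeneInventory <- function() {
  layout <- .fixtureLayout()
  rows <- list()
  for (sp in names(layout)) {
    for (chr in names(layout[[sp]])) {
      tags <- layout[[sp]][[chr]]
      for (i in seq_along(tags)) {
        tag <- tags[i]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("%s_%s_T%d", sp, chr, i),
          species = sp, chromosome = chr, t_index = i,
          status = if (tag == "ps") "pseudogene" else "functional",
          lineage = if (tag == "ps") NA_character_ else tag,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# right-caterpillar newick fragment over leaf ids
.cater <- function(ids) {
  if (length(ids) == 1L) return(ids)
  paste0("(", ids[1L], ",", .cater(ids[-1L]), ")")
}

#' Canonical fixture gene tree
#'
#' The ingroup gene tree over the 55 functional genes of the fixture
#' inventory.  Six lineage subtrees (yellow: 1 poplar gene; blue: 4
#' cassava genes; red: cacao + poplar + 2 strawberry; green: 3
#' Brassicales species + 3 Fabales species; brown: 6 species; pink: the
#' Fabales-restricted lineage, two paralog sub-clades joined by a
#' duplication mapping to the Fabales crown, 42 genes) hang off a
#' backbone ladder whose five internal nodes are duplications mapping to
#' the species root.  Within-lineage topologies are congruent with the
#' species tree, with serial within-species duplications for expanded
#' tandem arrays.
#'
#' @param withOutgroup logical; if `TRUE` a stilbene-synthase-like
#'   outgroup leaf (`STS_outgroup`) is attached below the ingroup root.
#' @return A rooted binary `phylo` (55 ingroup tips).
#' @export
rosidGeneTree <- function(withOutgroup = FALSE) {
  inv <- rosidGeneInventory()
  ids <- function(sp, lin)
    inv$gene_id[inv$species == sp & !is.na(inv$lineage) & inv$lineage == lin]

  yellow <- ids("Ptrichocarpa", "yellow")
  blue <- .cater(ids("Mesculenta", "blue"))
  red <- sprintf("(%s,(%s,%s))",
                 ids("Tcacao", "red"), ids("Ptrichocarpa", "red"),
                 .cater(ids("Fvesca", "red")))
  brown <- sprintf("(%s,((%s,(%s,%s)),(%s,%s)))",
                   ids("Tcacao", "brown"),
                   .cater(ids("Ptrichocarpa", "brown")),
                   ids("Mesculenta", "brown"), ids("Rcommunis", "brown"),
                   .cater(ids("Mdomestica", "brown")),
                   .cater(ids("Fvesca", "brown")))
  brassicales <- sprintf("(%s,((%s,%s),%s))",
                         ids("Brapa", "greenX"),
                         ids("Athaliana", "green"), ids("Alyrata", "green"),
                         .cater(ids("Brapa", "green")))
  greenFab <- sprintf("(%s,(%s,%s))",
                      .cater(ids("Gmax", "green")),
                      ids("Mtruncatula", "green"), ids("Ljaponicus", "green"))
  green <- sprintf("(%s,%s)", brassicales, greenFab)
  pinkA <- sprintf("(%s,(%s,%s))",
                   .cater(ids("Gmax", "pinkA")),
                   .cater(ids("Mtruncatula", "pinkA")),
                   .cater(ids("Ljaponicus", "pinkA")))
  pinkB <- sprintf("(%s,(%s,%s))",
                   .cater(ids("Gmax", "pinkB")),
                   .cater(ids("Mtruncatula", "pinkB")),
                   .cater(ids("Ljaponicus", "pinkB")))
  pink <- sprintf("(%s,%s)", pinkA, pinkB)

  ingroup <- sprintf("(%s,(%s,(%s,(%s,(%s,%s)))))",
                     red, yellow, brown, blue, green, pink)
  nwk <- if (withOutgroup) sprintf("(%s,STS_outgroup);", ingroup)
         else paste0(ingroup, ";")
  parseNewick(nwk)
}

#' Colour labels for the fixture lineages
#'
#' Identifies each decomposed lineage of the fixture by its species
#' composition and returns the presentation colour used throughout the
#' worked example (yellow, blue, red, green, brown, pink).
#'
#' @param lineages list of [GeneLineage-class] from the fixture
#'   decomposition.
#' @return Named character vector, lineage id -> colour.
#' @export
lineageColorMap <- function(lineages) {
  vapply(lineages, function(l) {
    sc <- speciesCounts(l)
    on <- names(sc)[sc > 0L]
    col <-
      if (identical(on, "Mesculenta")) "blue"
      else if (identical(on, "Ptrichocarpa")) "yellow"
      else if ("Athaliana" %in% on) "green"
      else if (setequal(on, c("Gmax", "Mtruncatula", "Ljaponicus"))) "pink"
      else if ("Mdomestica" %in% on) "brown"
      else "red"
    setNames(col, l@lineageId)
  }, character(1))
}

# fixed reverse-translation table (one codon per amino acid, no stops)
.CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.revTranslate <- function(aa) {
  paste(.CODON_OF[strsplit(aa, "")[[1]]], collapse = "")
}

.randomAA <- function(n) paste(sample(names(.CODON_OF), n, replace = TRUE),
                               collapse = "")

.randomNT <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Generate two-exon CHS-like sequences for the fixture inventory
#'
#' For every functional record, builds a random two-exon gene: exon 1
#' encodes `M` plus 36-63 random residues (translated length drawn
#' uniformly from 37-64 aa), exon 2 encodes 340 residues carrying the
#' configured active-site motif (amino-acid offset 55) and family
#' signature (offset 160) plus a stop codon, separated by a 100-bp
#' `GT..AG` intron.  Pseudogene records reuse the same scaffold with a
#' planted disruption, alternating between an internal stop codon
#' (exon-2 codon 20) and a 1-bp deletion early in exon 2; both leave the
#' signature region detectable by a three-frame scan.  Strands alternate
#' along each chromosome.  Deterministic given `seed`.
#'
#' Motif patterns in `config` are planted literally, so the generator
#' requires them to be plain amino-acid strings (no regex
#' metacharacters).
#'
#' @param inventory `data.frame` as from [rosidGeneInventory()] (columns
#'   `gene_id`, `species`, `chromosome`, `status`).
#' @param config an [AnnotationConfig-class].
#' @param seed integer seed.
#' @param intronLength intron length in bp (>= 4).
#' @return List with `genome` (chromosome `DNAStringSet`) and `models`
#'   (an unannotated [GeneModelSet-class]).
#' @export
generateFixtureSequences <- function(inventory = rosidGeneInventory(),
                                     config = AnnotationConfig(),
                                     seed = 1L, intronLength = 100L) {
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", config@signaturePattern) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWY]", config@activeSitePattern))
    stop("generator motifs must be literal amino-acid strings",
         call. = FALSE)
  set.seed(seed)
  chromKey <- paste(inventory$species, inventory$chromosome, sep = "\r")
  chromSeqs <- character(0)
  rows <- list()
  exRows <- list()
  psCounter <- 0L

  for (ck in unique(chromKey)) {
    sel <- which(chromKey == ck)
    chrom <- inventory$chromosome[sel[1L]]
    cursor <- 0L
    seqParts <- .randomNT(50L)
    cursor <- 50L
    for (j in seq_along(sel)) {
      i <- sel[j]
      # transcript-orientation pieces
      L1 <- sample(37:64, 1L)
      aa1 <- paste0("M", .randomAA(L1 - 1L))
      aa2 <- .randomAA(340L)
      substr(aa2, 55L, 54L + nchar(config@activeSitePattern)) <-
        config@activeSitePattern
      substr(aa2, 160L, 159L + nchar(config@signaturePattern)) <-
        config@signaturePattern
      exon1 <- .revTranslate(aa1)
      exon2 <- paste0(.revTranslate(aa2), "TAA")
      if (inventory$status[i] == "pseudogene") {
        psCounter <- psCounter + 1L
        if (psCounter %% 2L == 1L) {
          substr(exon2, 58L, 60L) <- "TAA"        # internal stop, codon 20
        } else {
          exon2 <- paste0(substr(exon2, 1L, 89L), # 1-bp deletion
                          substr(exon2, 91L, nchar(exon2)))
        }
      }
      intron <- paste0("GT", .randomNT(intronLength - 4L), "AG")
      minus <- j %% 2L == 0L
      locus <- paste0(exon1, intron, exon2)
      genomic <- if (minus)
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(locus)))
      else locus
      gStart <- cursor + 1L
      gEnd <- cursor + nchar(locus)
      w1 <- nchar(exon1); w2 <- nchar(exon2)
      if (minus) {
        ex <- cbind(c(gStart, gStart + w2 + nchar(intron)),
                    c(gStart + w2 - 1L, gEnd))
      } else {
        ex <- cbind(c(gStart, gStart + w1 + nchar(intron)),
                    c(gStart + w1 - 1L, gEnd))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = inventory$gene_id[i], species = inventory$species[i],
        chromosome = chrom, start = gStart, end = gEnd,
        strand = if (minus) "-" else "+", stringsAsFactors = FALSE)
      exRows[[length(exRows) + 1L]] <- ex
      seqParts <- c(seqParts, genomic, .randomNT(100L))
      cursor <- gEnd + 100L
    }
    chromSeqs[chrom] <- paste(seqParts, collapse = "")
  }

  tab <- do.call(rbind, rows)
  genes <- GenomicRanges::GRanges(
    tab$chromosome, IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  genes$gene_id <- tab$gene_id
  genes$species <- tab$species
  exons <- GenomicRanges::GRangesList(lapply(seq_along(exRows), function(i)
    GenomicRanges::GRanges(tab$chromosome[i],
                           IRanges::IRanges(exRows[[i]][, 1L],
                                            exRows[[i]][, 2L]),
                           strand = tab$strand[i])))
  list(genome = Biostrings::DNAStringSet(chromSeqs),
       models = GeneModelSet(genes, exons))
}

#' Write the complete fixture to disk
#'
#' Builds the canonical fixture and writes: `species_tree.nwk`,
#' `gene_tree.nwk` (ingroup) and `gene_tree_outgroup.nwk`,
#' `species_map.tsv`, `genome.fasta`, `genes.gff3` and `annotation.tsv`
#' (the generated models annotated and named by the package's own
#' annotation stage).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the sequence generator.
#' @param config an [AnnotationConfig-class].
#' @return Named character vector of file paths, invisibly.
#' @export
writeFixture <- function(dir, seed = 1L, config = AnnotationConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeNewick(rosidSpeciesTree(), p("species_tree.nwk"))
  gt <- rosidGeneTree()
  writeNewick(gt, p("gene_tree.nwk"))
  writeNewick(rosidGeneTree(withOutgroup = TRUE),
              p("gene_tree_outgroup.nwk"))
  writeSpeciesMap(speciesOfLeaf(gt$tip.label), p("species_map.tsv"))
  fx <- generateFixtureSequences(config = config, seed = seed)
  Biostrings::writeXStringSet(fx$genome, p("genome.fasta"))
  .writeGff3(fx$models, p("genes.gff3"))
  ann <- assignNames(annotateGenes(fx$models, fx$genome, config))
  writeAnnotationTable(ann, p("annotation.tsv"))
  out <- c(species_tree = p("species_tree.nwk"),
           gene_tree = p("gene_tree.nwk"),
           gene_tree_outgroup = p("gene_tree_outgroup.nwk"),
           species_map = p("species_map.tsv"),
           genome = p("genome.fasta"),
           gff = p("genes.gff3"),
           annotation = p("annotation.tsv"))
  invisible(out)
}

# GFF3 writer for a GeneModelSet (gene + exon features, species attribute)
.writeGff3 <- function(models, file) {
  g <- models@genes
  rows <- list()
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    chr <- as.character(GenomicRanges::seqnames(g))[i]
    str <- as.character(GenomicRanges::strand(g))[i]
    ex <- models@exons[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = chr, start = GenomicRanges::start(g)[i],
      end = GenomicRanges::end(g)[i], strand = str, type = "gene",
      ID = gid, Parent = NA_character_, species = g$species[i],
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = chr, start = GenomicRanges::start(ex),
      end = GenomicRanges::end(ex), strand = str, type = "exon",
      ID = sprintf("%s.exon%d", gid, seq_along(ex)), Parent = gid,
      species = g$species[i], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$source <- "chsLineage"
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr$species <- df$species
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}
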