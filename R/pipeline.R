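# End-to-end orchestration: annotate -> trees -> reconcile -> summarize,
# with plain-text intermediates so every stage can be re-run in isolation.

#' Count chromosomes bearing functional genes, per species
#'
#' @param annotation `data.frame` with columns `species`, `chromosome`,
#'   `status` (e.g. from [geneTable()]).
#' @return Named integer vector, species -> number of distinct
#'   chromosomes carrying at least one functional gene.
#' @export
chromosomesWithGenes <- function(annotation) {
  fun <- annotation[annotation$status == "functional", , drop = FALSE]
  vapply(split(fun$chromosome, fun$species),
         function(ch) length(unique(ch)), integer(1))
}

#' Run the full repertoire-inference pipeline
#'
#' Stages: (1) annotation — when `fasta` + `gff` are given, gene models
#' are read, classified and named; alternatively a pre-computed
#' `annotationTable` may be supplied; (2) trees — gene and species trees
#' are parsed, the outgroup (if any) is removed, and gene leaves are
#' mapped to species (explicit map file wins over the delimiter rule);
#' (3) reconciliation — LCA mapping, event labelling, lineage
#' decomposition, Dollo losses; (4) summary — retention matrix,
#' per-species counts, chromosome counts and the loss table.  Pseudogene
#' and rejected leaves present in the gene tree are dropped before
#' reconciliation unless `includePseudogenes = TRUE`.
#'
#' Each stage failure aborts with the stage name and cause.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `gene_tree`, `species_tree` (paths, required); `species_map`
#'   (path, optional); `fasta`, `gff` (paths, optional);
#'   `annotation_table` (path, optional); `outgroup` (character,
#'   optional); `include_pseudogenes` (logical, default `FALSE`);
#'   `out_dir` (optional; when set, report files are written);
#'   `annotation` (list of [AnnotationConfig()] arguments, optional).
#' @return A report list: `n_lineages`, `lineages` (list of
#'   [GeneLineage-class]), `lineage_table` (`data.frame`), `retention`
#'   ([RetentionSummary-class]), `per_species_functional`,
#'   `per_species_pseudogenes`, `chromosomes_with_genes`, `loss_table`,
#'   `annotation` (`data.frame` or `NULL`), `reconciliation`.
#' @examples
#' \donttest{
#' dir <- tempfile(); files <- writeFixture(dir, seed = 1)
#' rep <- runPipeline(list(gene_tree = files[["gene_tree"]],
#'                         species_tree = files[["species_tree"]],
#'                         species_map = files[["species_map"]],
#'                         annotation_table = files[["annotation"]]))
#' rep$n_lineages
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  getc <- function(key, default = NULL)
    if (!is.null(config[[key]])) config[[key]] else default

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- annotation stage -------------------------------------------------
  annTab <- NULL
  annCfg <- do.call(AnnotationConfig, as.list(getc("annotation", list())))
  if (!is.null(getc("fasta")) && !is.null(getc("gff"))) {
    annTab <- stage("annotate", {
      models <- readGeneModels(getc("gff"))
      genome <- Biostrings::readDNAStringSet(getc("fasta"))
      names(genome) <- sub("\\s.*$", "", names(genome))
      geneTable(assignNames(annotateGenes(models, genome, annCfg)))
    })
  } else if (!is.null(getc("annotation_table"))) {
    annTab <- stage("annotate", utils::read.table(
      getc("annotation_table"), header = TRUE, sep = "\t",
      stringsAsFactors = FALSE))
  }

  # --- tree stage -------------------------------------------------------
  trees <- stage("trees", {
    st <- parseNewick(file = getc("species_tree"))
    gt <- parseNewick(file = getc("gene_tree"),
                      requireRootedBinary = FALSE)
    og <- getc("outgroup")
    if (!is.null(og) && length(intersect(og, gt$tip.label)))
      gt <- rootWithOutgroup(gt, intersect(og, gt$tip.label))
    .assertRootedBinary(gt, "gene tree")
    if (!is.null(annTab) && !isTRUE(getc("include_pseudogenes"))) {
      drop <- annTab$gene_id[annTab$status != "functional"]
      drop <- intersect(drop, gt$tip.label)
      if (length(drop) == length(gt$tip.label)) {
        gt <- NULL                       # no functional genes left
      } else if (length(drop) == length(gt$tip.label) - 1L) {
        lab <- setdiff(gt$tip.label, drop)
        gt <- structure(list(singleton = lab), class = "singletonGene")
      } else if (length(drop)) {
        gt <- ape::drop.tip(gt, drop)
      }
    }
    map <- if (!is.null(getc("species_map")))
      readSpeciesMap(getc("species_map")) else NULL
    labs <- if (is.null(gt)) character(0)
            else if (inherits(gt, "singletonGene")) gt$singleton
            else gt$tip.label
    so <- if (length(labs))
      speciesOfLeaf(labs, table = map, speciesTree = st)
    else setNames(character(0), character(0))
    list(gt = gt, st = st, so = so)
  })

  # --- reconciliation stage --------------------------------------------
  if (is.null(trees$gt)) {
    lineages <- list()
    recon <- NULL
  } else if (inherits(trees$gt, "singletonGene")) {
    # a single functional gene: one trivial lineage, no reconciliation
    recon <- NULL
    lab <- trees$gt$singleton
    sp <- unname(trees$so[lab])
    counts <- setNames(integer(.nTip(trees$st)), trees$st$tip.label)
    counts[sp] <- 1L
    dl <- dolloLosses(sp, trees$st)
    lineages <- list(new("GeneLineage", lineageId = "lineage_1",
                         rootNode = NA_integer_, members = lab,
                         speciesCounts = counts, losses = dl$labels,
                         lossEdges = dl$edges))
  } else {
    recon <- stage("reconcile",
                   reconcile(trees$gt, trees$st, trees$so))
    lineages <- stage("reconcile", decomposeLineages(recon))
  }

  # --- summary stage ----------------------------------------------------
  report <- stage("summarize", {
    ret <- retentionSummary(lineages, species = trees$st$tip.label)
    linTab <- if (length(lineages)) data.frame(
      lineage_id = vapply(lineages, function(l) l@lineageId, character(1)),
      n_copies = vapply(lineages, nCopies, integer(1)),
      n_species = vapply(lineages, nSpecies, integer(1)),
      n_losses = vapply(lineages, nLosses, integer(1)),
      members = vapply(lineages, function(l)
        paste(lineageMembers(l), collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    else data.frame(lineage_id = character(0), n_copies = integer(0),
                    n_species = integer(0), n_losses = integer(0),
                    members = character(0))
    lossTab <- if (length(lineages)) do.call(rbind, lapply(
      lineages, function(l) if (nLosses(l) == 0L) NULL else data.frame(
        lineage_id = l@lineageId, loss_edge = l@losses,
        stringsAsFactors = FALSE)))
    else NULL
    perSpFun <- if (!is.null(annTab))
      vapply(split(annTab$status, annTab$species),
             function(s) sum(s == "functional"), integer(1))
    else setNames(as.integer(rowSums(retentionMatrix(ret))),
                  rownames(retentionMatrix(ret)))
    perSpPs <- if (!is.null(annTab))
      vapply(split(annTab$status, annTab$species),
             function(s) sum(s == "pseudogene"), integer(1))
    else NULL
    list(n_lineages = length(lineages),
         lineages = lineages,
         lineage_table = linTab,
         retention = ret,
         per_species_functional = perSpFun,
         per_species_pseudogenes = perSpPs,
         chromosomes_with_genes = if (!is.null(annTab))
           chromosomesWithGenes(annTab) else NULL,
         loss_table = lossTab,
         annotation = annTab,
         reconciliation = recon)
  })

  outDir <- getc("out_dir")
  if (!is.null(outDir)) stage("write", writeReport(report, outDir))
  report
}

#' Write pipeline report files
#'
#' Writes `lineage_table.tsv`, `retention_matrix.tsv`, `loss_table.tsv`,
#' `summary.json` (machine-readable tallies) and `report.txt`
#' (human-readable) into `dir`.
#'
#' @param report list from [runPipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(report$lineage_table, p("lineage_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rm <- retentionMatrix(report$retention)
  utils::write.table(data.frame(species = rownames(rm), rm,
                                check.names = FALSE),
                     p("retention_matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(report$loss_table))
    utils::write.table(report$loss_table, p("loss_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  summ <- list(
    n_lineages = report$n_lineages,
    n_multi = report$retention@nMulti,
    n_single = report$retention@nSingle,
    per_species_functional = as.list(report$per_species_functional),
    per_species_pseudogenes = as.list(report$per_species_pseudogenes),
    chromosomes_with_genes = as.list(report$chromosomes_with_genes))
  jsonlite::write_json(summ, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  txt <- c(
    sprintf("Ancestral lineages: %d", report$n_lineages),
    sprintf("Species retaining >= 2 lineages: %d",
            report$retention@nMulti),
    sprintf("Species retaining exactly 1 lineage: %d",
            report$retention@nSingle),
    "",
    "Per-lineage summary:",
    sprintf("  %s: %d copies, %d species, %d losses",
            report$lineage_table$lineage_id,
            report$lineage_table$n_copies,
            report$lineage_table$n_species,
            report$lineage_table$n_losses))
  writeLines(txt, p("report.txt"))
  invisible(dir)
}
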