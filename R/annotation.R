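# Gene-model validation, functional/pseudogene classification, and tandem
# T-index naming for CHS-like two-exon genes.

.STOP_AA <- "*"

# Translate a DNAString in frame `frame` (1..3), truncated to whole codons.
.translateFrame <- function(dna, frame = 1L) {
  n <- length(dna)
  if (n < frame + 2L) return("")
  sub <- Biostrings::subseq(dna, frame, frame + ((n - frame + 1L) %/% 3L) * 3L - 1L)
  if (length(sub) < 3L) return("")
  as.character(suppressWarnings(
    Biostrings::translate(sub, if.fuzzy.codon = "solve")))
}

#' Splice the coding sequence of one gene model
#'
#' Extracts the exon subsequences of gene `i` from its chromosome and
#' concatenates them in transcription order (reverse-complemented,
#' highest-coordinate exon first, on the minus strand).
#'
#' @param models a [GeneModelSet-class].
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param i gene index.
#' @return A `DNAString`, the spliced CDS.
#' @export
spliceCds <- function(models, genome, i) {
  g <- models@genes[i]
  ex <- models@exons[[i]]
  chr <- as.character(GenomicRanges::seqnames(g))
  if (!chr %in% names(genome))
    stop("chromosome '", chr, "' absent from genome sequences", call. = FALSE)
  chrSeq <- genome[[chr]]
  if (GenomicRanges::end(g) > length(chrSeq))
    stop("gene span exceeds chromosome '", chr, "' length", call. = FALSE)
  pieces <- lapply(seq_along(ex), function(j)
    Biostrings::subseq(chrSeq, GenomicRanges::start(ex)[j],
                       GenomicRanges::end(ex)[j]))
  # concatenating in ascending genomic order and reverse-complementing the
  # whole gives the transcript: rc(seg1 + seg2) = rc(seg2) + rc(seg1)
  cds <- if (length(pieces) == 1L) pieces[[1]] else
    do.call(Biostrings::xscat, pieces)
  if (as.character(GenomicRanges::strand(g)) == "-")
    cds <- Biostrings::reverseComplement(cds)
  cds
}

#' Validate one gene model against the canonical two-exon architecture
#'
#' Classifies a candidate gene as `functional`, `pseudogene` or
#' `rejected`, with reason codes for every failed check.
#'
#' A model is *functional* iff it has exactly 2 exons, the translated
#' exon-1 length lies in `[exon1Min, exon1Max]`, the translated exon-2
#' length (excluding the stop codon) lies within `exon2Target +/-
#' exon2Tol`, the ORF is intact (starts with ATG, ends with a stop codon,
#' no internal stop, length a multiple of 3), and both the family
#' signature and the active-site motif match the exon-2 translation.  A
#' model whose ORF is disrupted (frameshift-length CDS, missing start,
#' internal or missing stop) but whose exon-2 region still carries the
#' family signature in at least one of the three forward reading frames
#' is a *pseudogene*.  Anything else is *rejected*.
#'
#' @param exonWidths integer vector of exon widths (bp) in transcription
#'   order.
#' @param cds the spliced coding sequence (`DNAString` or character), in
#'   transcript orientation.
#' @param config an [AnnotationConfig-class].
#' @return List with `status` and `reasons` (character vector of codes:
#'   `exon_count`, `exon1_length`, `exon2_length`, `no_start_codon`,
#'   `internal_stop`, `no_stop_codon`, `frameshift_length`,
#'   `signature_missing`, `active_site_missing`).
#' @examples
#' cfg <- AnnotationConfig(signaturePattern = "WWW", activeSitePattern = "HHH")
#' @export
validateStructure <- function(exonWidths, cds, config = AnnotationConfig()) {
  if (is.character(cds)) cds <- Biostrings::DNAString(cds)
  if (length(cds) == 0L) stop("empty coding sequence", call. = FALSE)
  if (sum(exonWidths) != length(cds))
    stop("CDS length (", length(cds), ") does not match exon widths (",
         sum(exonWidths), ")", call. = FALSE)
  reasons <- character(0)

  twoExons <- length(exonWidths) == 2L
  if (!twoExons) reasons <- c(reasons, "exon_count")

  # ORF integrity of the full spliced CDS
  inFrame <- length(cds) %% 3L == 0L
  if (!inFrame) reasons <- c(reasons, "frameshift_length")
  aaFull <- .translateFrame(cds, 1L)
  hasStart <- startsWith(as.character(Biostrings::subseq(cds, 1L,
                           min(3L, length(cds)))), "ATG")
  if (!hasStart) reasons <- c(reasons, "no_start_codon")
  nAA <- nchar(aaFull)
  endsStop <- inFrame && nAA > 0L &&
    substr(aaFull, nAA, nAA) == .STOP_AA
  if (!endsStop) reasons <- c(reasons, "no_stop_codon")
  body <- if (nAA > 1L) substr(aaFull, 1L, nAA - 1L) else ""
  internalStop <- grepl(.STOP_AA, body, fixed = TRUE)
  if (internalStop) reasons <- c(reasons, "internal_stop")
  orfIntact <- inFrame && hasStart && endsStop && !internalStop

  exon2aa <- ""
  if (twoExons) {
    aa1 <- exonWidths[1L] %/% 3L
    if (aa1 < config@exon1Min || aa1 > config@exon1Max)
      reasons <- c(reasons, "exon1_length")
    aa2 <- exonWidths[2L] %/% 3L - 1L  # excluding the stop codon
    if (abs(aa2 - config@exon2Target) > config@exon2Tol)
      reasons <- c(reasons, "exon2_length")
    exon2 <- Biostrings::subseq(cds, exonWidths[1L] + 1L, length(cds))
    exon2aa <- .translateFrame(exon2, 1L)
    if (!grepl(config@signaturePattern, exon2aa))
      reasons <- c(reasons, "signature_missing")
    if (!grepl(config@activeSitePattern, exon2aa))
      reasons <- c(reasons, "active_site_missing")
  } else {
    reasons <- c(reasons, "signature_missing", "active_site_missing")
  }

  if (length(reasons) == 0L)
    return(list(status = "functional", reasons = character(0)))

  # pseudogene: disrupted ORF but family signature still detectable in
  # one of the three forward frames of the exon-2 region
  if (!orfIntact && twoExons) {
    exon2 <- Biostrings::subseq(cds, exonWidths[1L] + 1L, length(cds))
    sigSomewhere <- any(vapply(1:3, function(f)
      grepl(config@signaturePattern, .translateFrame(exon2, f)),
      logical(1)))
    if (sigSomewhere)
      return(list(status = "pseudogene", reasons = reasons))
  }
  list(status = "rejected", reasons = reasons)
}

#' Annotate every gene model in a set
#'
#' Splices each model's CDS from the genome and runs
#' [validateStructure()], filling the `status` and `reasons` metadata
#' columns.
#'
#' @param models a [GeneModelSet-class].
#' @param genome a `DNAStringSet` named by chromosome.
#' @param config an [AnnotationConfig-class].
#' @return The annotated [GeneModelSet-class].
#' @export
annotateGenes <- function(models, genome, config = AnnotationConfig()) {
  stopifnot(is(models, "GeneModelSet"))
  n <- length(models)
  status <- character(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    cds <- spliceCds(models, genome, i)
    ex <- models@exons[[i]]
    w <- GenomicRanges::width(ex)
    if (as.character(GenomicRanges::strand(models@genes[i])) == "-")
      w <- rev(w)
    v <- validateStructure(w, cds, config)
    status[i] <- v$status
    reasons[i] <- paste(v$reasons, collapse = ",")
  }
  models@genes$status <- status
  models@genes$reasons <- reasons
  validObject(models)
  models
}

#' Assign tandem T-index names in chromosomal order
#'
#' Within each (species, chromosome) group, functional genes and
#' pseudogenes are indexed `T1..Tn` by ascending chromosome start
#' coordinate (chromosome forward orientation, regardless of gene
#' strand); pseudogenes receive the `ps` suffix and still consume an
#' index.  Names follow `<chromosome>-T<k>[ps]`.  Rejected models get no
#' name and consume no index.  Ties on the start coordinate are an error
#' (ambiguous linkage order).  Re-running is idempotent.
#'
#' @param models an annotated [GeneModelSet-class].
#' @return The [GeneModelSet-class] with `assigned_name` filled.
#' @export
assignNames <- function(models) {
  stopifnot(is(models, "GeneModelSet"))
  g <- models@genes
  if (anyNA(g$status))
    stop("models must be annotated before naming", call. = FALSE)
  name <- rep(NA_character_, length(g))
  keep <- which(g$status %in% c("functional", "pseudogene"))
  chrom <- as.character(GenomicRanges::seqnames(g))
  groups <- split(keep, paste(g$species[keep], chrom[keep], sep = "\r"))
  for (idx in groups) {
    st <- GenomicRanges::start(g)[idx]
    if (anyDuplicated(st))
      stop("ambiguous linkage order: duplicate start coordinates on ",
           chrom[idx[1L]], " (", g$species[idx[1L]], ")", call. = FALSE)
    ord <- idx[order(st)]
    name[ord] <- sprintf("%s-T%d%s", chrom[ord], seq_along(ord),
                         ifelse(g$status[ord] == "pseudogene", "ps", ""))
  }
  models@genes$assigned_name <- name
  models
}

#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` features (exons are linked to genes through
#' their `Parent`/`ID` chain via an intermediate mRNA when present) into
#' a [GeneModelSet-class].  Gene features need `ID` and a `species`
#' attribute (or a constant `species` argument).
#'
#' @param gff path to a GFF3 file.
#' @param species optional constant species identifier used when the GFF
#'   carries no `species` attribute.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(gff, species = NULL) {
  gr <- rtracklayer::import(gff, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop("no gene features in ", gff, call. = FALSE)
  geneId <- genes$ID
  sp <- if (!is.null(species)) rep(species, length(genes))
        else if ("species" %in% colnames(S4Vectors::mcols(genes)))
          genes$species
        else stop("GFF has no species attribute; pass species=",
                  call. = FALSE)
  mrna <- gr[gr$type == "mRNA"]
  exons <- gr[gr$type == "exon"]
  # resolve exon Parent to gene (directly or through one mRNA level)
  toGene <- setNames(geneId, geneId)
  if (length(mrna)) {
    mp <- vapply(mrna$Parent, function(p) p[[1]], character(1))
    toGene <- c(toGene, setNames(mp, mrna$ID))
  }
  exParentRaw <- vapply(exons$Parent, function(p) p[[1]], character(1))
  exGene <- unname(toGene[exParentRaw])
  if (anyNA(exGene)) stop("exon with unresolvable Parent", call. = FALSE)
  exList <- GenomicRanges::GRangesList(lapply(geneId, function(id) {
    e <- exons[exGene == id]
    e[order(GenomicRanges::start(e))]
  }))
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(GenomicRanges::start(genes),
                     GenomicRanges::end(genes)),
    strand = GenomicRanges::strand(genes))
  out$gene_id <- geneId
  out$species <- sp
  GeneModelSet(out, exList)
}

#' Write the annotation table as TSV
#'
#' @param models an annotated [GeneModelSet-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAnnotationTable <- function(models, file) {
  utils::write.table(geneTable(models), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
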