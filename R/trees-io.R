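#' Parse a newick string or file into a validated tree
#'
#' Thin, strict wrapper around [ape::read.tree()]: parses a single newick
#' tree and rejects inputs ape would silently accept but the pipeline
#' cannot use (duplicate leaf labels, unrooted or non-binary trees when
#' `requireRootedBinary = TRUE`).  Polytomies are rejected by default;
#' with `resolvePolytomies = TRUE` they are resolved deterministically
#' (ladderized after sorting child clades by their smallest leaf label,
#' zero-length internal edges).
#'
#' @param text character, a newick string (ignored when `file` is given).
#' @param file optional path to a newick file.
#' @param requireRootedBinary logical, validate rootedness and binarity.
#' @param resolvePolytomies logical, deterministically resolve polytomies
#'   instead of rejecting them.
#' @return A `phylo` object.
#' @examples
#' parseNewick("((A:1,B:1):2,C:3);")
#' @export
parseNewick <- function(text, file = NULL, requireRootedBinary = TRUE,
                        resolvePolytomies = FALSE) {
  if (!is.null(file)) {
    phy <- tryCatch(ape::read.tree(file), error = function(e)
      stop("newick parse error in '", file, "': ", conditionMessage(e),
           call. = FALSE))
  } else {
    if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
      stop("'text' must be a single non-empty newick string", call. = FALSE)
    bal <- sum(strsplit(text, "")[[1]] == "(") -
           sum(strsplit(text, "")[[1]] == ")")
    if (bal != 0L)
      stop("unbalanced parentheses in newick input (", abs(bal),
           if (bal > 0) " unclosed '('" else " unmatched ')'", ")",
           call. = FALSE)
    phy <- tryCatch(ape::read.tree(text = text), error = function(e)
      stop("newick parse error: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("newick parse error: input did not yield a tree", call. = FALSE)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!ape::is.binary(phy)) {
    if (!resolvePolytomies)
      stop("tree contains polytomies; set resolvePolytomies = TRUE ",
           "for deterministic resolution", call. = FALSE)
    phy <- .resolveDeterministic(phy)
  }
  if (requireRootedBinary) .assertRootedBinary(phy, "tree")
  phy
}

# Deterministic polytomy resolution: rotate children into the order of
# their smallest leaf label, then ladderize each polytomy.
.resolveDeterministic <- function(phy) {
  phy <- ape::rotateConstr(phy, sort(phy$tip.label))
  ape::multi2di(phy, random = FALSE)
}

#' Write a tree as newick
#'
#' @param phy a `phylo` object.
#' @param file optional output path; if `NULL` the newick string is
#'   returned.
#' @return The newick string, invisibly when written to a file.
#' @export
writeNewick <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root a gene tree with an outgroup and drop the outgroup
#'
#' Roots the tree on the edge separating the ingroup from the outgroup
#' leaves, then removes the outgroup and suppresses the unary node this
#' leaves behind.  The outgroup must be a single leaf or a monophyletic
#' group in the unrooted tree; otherwise the conflicting placement is
#' reported.
#'
#' @param phy a `phylo` gene tree (rooted or not).
#' @param outgroup character, leaf labels of the outgroup.
#' @return The rooted ingroup `phylo`.
#' @examples
#' tr <- parseNewick("((in1,in2),OUT);", requireRootedBinary = FALSE)
#' rootWithOutgroup(tr, "OUT")
#' @export
rootWithOutgroup <- function(phy, outgroup) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  missing <- setdiff(outgroup, phy$tip.label)
  if (length(missing))
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(setdiff(phy$tip.label, outgroup)) < 2L)
    stop("fewer than two ingroup leaves remain after outgroup removal",
         call. = FALSE)
  un <- ape::unroot(phy)
  if (length(outgroup) > 1L &&
      !ape::is.monophyletic(un, outgroup)) {
    stop("outgroup is not monophyletic; conflicting leaves: ",
         paste(outgroup, collapse = ", "), call. = FALSE)
  }
  rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  ing <- ape::drop.tip(rooted, outgroup, collapse.singles = TRUE)
  if (!ape::is.rooted(ing)) ing <- ape::multi2di(ing, random = FALSE)
  ing
}

#' Map gene-tree leaf labels to species
#'
#' Deterministic extraction of the species identifier from each leaf
#' label.  An explicit lookup `table` (named character, leaf -> species)
#' always wins; remaining labels fall back to the delimiter rule: split
#' on `delim` and take field `field` (default: first underscore-delimited
#' field, so `"Gmax_Gm09_T1"` maps to `"Gmax"`).
#'
#' @param labels character, leaf labels.
#' @param table optional named character vector, explicit leaf -> species.
#' @param delim delimiter for the fallback rule.
#' @param field 1-based field index for the fallback rule.
#' @param speciesTree optional `phylo`; when given, every mapped species
#'   must be one of its tip labels.
#' @return Named character vector, leaf label -> species.
#' @examples
#' speciesOfLeaf(c("Mtruncatula_Mt1_T5", "Gmax_Gm09_T1"))
#' @export
speciesOfLeaf <- function(labels, table = NULL, delim = "_", field = 1L,
                          speciesTree = NULL) {
  out <- setNames(rep(NA_character_, length(labels)), labels)
  if (!is.null(table)) {
    hit <- labels %in% names(table)
    out[hit] <- unname(table[labels[hit]])
  }
  todo <- is.na(out)
  if (any(todo)) {
    parts <- strsplit(labels[todo], delim, fixed = TRUE)
    got <- vapply(parts, function(p)
      if (length(p) >= field) p[[field]] else NA_character_, character(1))
    out[todo] <- got
  }
  if (anyNA(out))
    stop("could not map leaves to species: ",
         paste(labels[is.na(out)], collapse = ", "), call. = FALSE)
  if (!is.null(speciesTree)) {
    bad <- setdiff(unique(out), speciesTree$tip.label)
    if (length(bad))
      stop("mapped species absent from species tree: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read / write a two-column species map
#'
#' TSV with columns `leaf_label` and `species`.
#'
#' @param file path.
#' @return `readSpeciesMap`: named character vector leaf -> species.
#' @export
readSpeciesMap <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("leaf_label", "species") %in% colnames(df)))
    stop("species map needs columns 'leaf_label' and 'species'")
  setNames(df$species, df$leaf_label)
}

#' @param map named character vector leaf -> species.
#' @rdname readSpeciesMap
#' @export
writeSpeciesMap <- function(map, file) {
  utils::write.table(
    data.frame(leaf_label = names(map), species = unname(map)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
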