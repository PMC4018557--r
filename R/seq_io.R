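#' Read per-gene ortholog CDS from FASTA
#'
#' One file per gene, one record per species; the first whitespace-separated
#' token of each header is the species name and must match a tree tip name
#' verbatim (no fuzzy matching — silent species mismatches are the most
#' common pipeline bug). Terminal stop codons are stripped on load (RefSeq
#' CDS convention). Records whose length is not a multiple of 3, that
#' contain an internal stop, or that use letters outside `ACGTN-` are
#' rejected, with machine-readable reasons in the `rejected` attribute.
#'
#' @param path FASTA file.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @param code A [genetic_code()].
#' @return A `gene_records` object: data.frame with columns `gene_id`,
#'   `species`, `cds`, plus attribute `rejected` (data.frame `species`,
#'   `reason`).
#' @export
read_gene_fasta <- function(path, gene_id = NULL, code = genetic_code()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(gene_id)) {
    gene_id <- sub("\\.(codon\\.)?(fa|fasta|fna)$", "",
                   basename(path), ignore.case = TRUE)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  species <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  cds <- toupper(as.character(seqs))
  gene_records(gene_id, species, cds, code = code)
}

# Validate raw (species, cds) pairs into a gene_records object.
gene_records <- function(gene_id, species, cds, code = genetic_code()) {
  reasons <- character(length(cds))
  bad_alpha <- grepl("[^ACGTN-]", cds)
  reasons[bad_alpha] <- "invalid_alphabet"
  ok <- !bad_alpha
  nontriplet <- ok & (nchar(cds) %% 3L != 0L)
  reasons[nontriplet] <- "length_not_multiple_of_3"
  ok <- ok & !nontriplet
  # strip one terminal stop codon where present
  for (i in which(ok)) {
    last <- substr(cds[i], nchar(cds[i]) - 2L, nchar(cds[i]))
    if (!is.na(code$codon_to_aa[last]) && code$codon_to_aa[[last]] == "*") {
      cds[i] <- substr(cds[i], 1L, nchar(cds[i]) - 3L)
    }
  }
  internal_stop <- ok & vapply(cds, function(s) {
    aa <- code$codon_to_aa[split_codons(s)]
    any(!is.na(aa) & aa == "*")
  }, logical(1L), USE.NAMES = FALSE)
  reasons[internal_stop] <- "internal_stop_codon"
  ok <- ok & !internal_stop
  empty <- ok & nchar(cds) == 0L
  reasons[empty] <- "empty_after_stop_strip"
  ok <- ok & !empty
  out <- data.frame(gene_id = gene_id, species = species[ok],
                    cds = cds[ok], stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(
    species = species[!ok], reason = reasons[!ok], stringsAsFactors = FALSE)
  class(out) <- c("gene_records", "data.frame")
  out
}

#' Write gene records (or any named sequence set) as FASTA
#'
#' Round-trips byte-stably with [read_gene_fasta()] for canonical input
#' (sequences without terminal stops, one header token).
#'
#' @param x A `gene_records` data.frame, or a named character vector of
#'   sequences.
#' @param path Output file.
#' @param width Line-wrap width; default 60.
#' @export
write_gene_fasta <- function(x, path, width = 60L) {
  if (is.data.frame(x)) x <- stats::setNames(x$cds, x$species)
  stopifnot(!is.null(names(x)))
  con <- file(path, open = "wb")   # binary: enforce Unix newlines
  on.exit(close(con))
  for (i in seq_along(x)) {
    s <- x[[i]]
    lines <- substring(s, seq(1L, max(nchar(s), 1L), by = width),
                       pmin(seq(width, nchar(s) + width - 1L, by = width),
                            nchar(s)))
    if (nchar(s) == 0L) lines <- character(0L)
    writeLines(c(paste0(">", names(x)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Species tree with named branch sets
#'
#' Wraps an `ape::phylo` tree with a set of named branch tags (foreground
#' clades such as `CATARRHINI` or `CETACEA`). A tag names a set of tip
#' labels; it covers the terminal branches of those tips, all internal
#' branches of the clade they span, and the clade's stem branch.
#'
#' @param phy An `ape::phylo` object with unique tip labels.
#' @param tags Named list; each element a character vector of tip labels.
#' @return An object of class `species_tree`: list with elements `phy` and
#'   `tags`.
#' @export
species_tree <- function(phy, tags = list()) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip names in tree")
  for (tg in names(tags)) {
    missing <- setdiff(tags[[tg]], phy$tip.label)
    if (length(missing) > 0L) {
      stop("tag ", tg, " names unknown tips: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(phy = phy, tags = tags), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("<species_tree>", length(x$phy$tip.label), "tips")
  if (length(x$tags) > 0L) {
    cat("; tags:", paste(sprintf("%s(%d)", names(x$tags),
                                 lengths(x$tags)), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Read a species tree from Newick
#'
#' @param text Newick string, or `NULL` to read from `file`.
#' @param file Path to a Newick file.
#' @param tags Optional named list of tip-label sets (see [species_tree()]).
#' @return A [species_tree()].
#' @export
read_species_tree <- function(text = NULL, file = NULL, tags = list()) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse Newick input")
  species_tree(phy, tags)
}

#' Write a species tree as Newick
#' @param tree A [species_tree()] or `phylo`.
#' @param file Output path, or `NULL` to return the Newick string.
#' @export
write_species_tree <- function(tree, file = NULL) {
  phy <- if (inherits(tree, "species_tree")) tree$phy else tree
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

# Edge indices (rows of phy$edge) covered by a tag: the spanned clade's
# internal + terminal branches plus its stem branch.
tag_edges <- function(tree, tips) {
  phy <- tree$phy
  tips <- intersect(tips, phy$tip.label)
  if (length(tips) == 0L) return(integer(0L))
  tipno <- match(tips, phy$tip.label)
  if (length(tipno) == 1L) {
    return(which(phy$edge[, 2L] == tipno))
  }
  mrca <- ape::getMRCA(phy, tipno)
  desc <- clade_nodes(phy, mrca)
  inside <- which(phy$edge[, 2L] %in% desc)          # stem edge: child == mrca
  # restrict terminal edges to the tagged tips (clade may contain others if
  # the tag set is non-monophyletic on this tree)
  keep <- phy$edge[inside, 2L] > length(phy$tip.label) |
    phy$edge[inside, 2L] %in% tipno
  inside[keep]
}

# All node numbers in the clade rooted at `node`, including `node` itself.
clade_nodes <- function(phy, node) {
  out <- node
  frontier <- node
  while (length(frontier) > 0L) {
    kids <- phy$edge[phy$edge[, 1L] %in% frontier, 2L]
    out <- c(out, kids)
    frontier <- kids[kids > length(phy$tip.label)]
  }
  out
}

#' Prune a species tree to a species subset
#'
#' Used per gene when some species lack an ortholog: the tree is reduced to
#' the species present and the branch tags recomputed on the reduced tree.
#' Collapsed branches are implicit in the reduced topology; the number of
#' tips dropped is recorded in the `dropped` attribute.
#'
#' @param tree A [species_tree()].
#' @param keep Character vector of tip labels to retain.
#' @return A [species_tree()] on the subset.
#' @export
prune_species_tree <- function(tree, keep) {
  keep <- intersect(tree$phy$tip.label, keep)
  if (length(keep) < 2L) stop("cannot prune tree below 2 tips")
  phy <- ape::keep.tip(tree$phy, keep)
  tags <- lapply(tree$tags, intersect, keep)
  tags <- tags[lengths(tags) > 0L]
  out <- species_tree(phy, tags)
  attr(out, "dropped") <- setdiff(tree$phy$tip.label, keep)
  out
}

#' Load a gene-to-class table
#'
#' TSV with header columns `gene_id` and `class_label`; a gene may carry
#' several class labels (one row per label). Duplicate pairs are dropped
#' with a warning.
#'
#' @param path TSV file.
#' @return A `gene_class_map` data.frame with columns `gene_id`,
#'   `class_label`.
#' @export
load_gene_class_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_class_map(tab)
}

#' @rdname load_gene_class_table
#' @param tab A data.frame with columns `gene_id`, `class_label`.
#' @export
gene_class_map <- function(tab) {
  if (!all(c("gene_id", "class_label") %in% names(tab))) {
    stop("gene-class table must have columns gene_id, class_label; got: ",
         paste(names(tab), collapse = ", "))
  }
  tab <- tab[, c("gene_id", "class_label"), drop = FALSE]
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sum(dup), " duplicate (gene_id, class_label) pairs dropped")
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("gene_class_map", "data.frame")
  tab
}

#' Count genes per class label
#' @param classes A `gene_class_map`.
#' @return Named integer vector.
#' @export
class_counts <- function(classes) {
  if (nrow(classes) == 0L) return(stats::setNames(integer(0L), character(0L)))
  vapply(split(classes$gene_id, classes$class_label),
         function(g) length(unique(g)), integer(1L))
}
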