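#' Global pairwise protein alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gap costs, delegated
#' to [Biostrings::pairwiseAlignment()]. A gap run of length L costs
#' `gap_open + L * gap_extend` (Biostrings convention). Defaults are the
#' community BLOSUM62 / 11 / 1 settings.
#'
#' @param a,b Amino-acid strings (no gaps).
#' @param matrix Substitution matrix name, e.g. `"BLOSUM62"`.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A `protein_alignment` with two rows.
#' @export
align_protein_pair <- function(a, b, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  protein_alignment(
    rows = c(a = as.character(Biostrings::pattern(pa)),
             b = as.character(Biostrings::subject(pa))),
    score = Biostrings::score(pa))
}

#' Protein alignment container
#'
#' @param rows Named character vector of equal-length gapped rows.
#' @param score Alignment objective value (optional).
#' @return Object of class `protein_alignment`.
#' @export
protein_alignment <- function(rows, score = NA_real_) {
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows have unequal lengths")
  }
  structure(list(species = names(rows), rows = rows, score = score),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment>", length(x$rows), "rows x",
      nchar(x$rows[[1L]]), "columns\n")
  invisible(x)
}

#' Read an externally produced protein alignment (aligned FASTA)
#'
#' Escape hatch for real-data use where a dedicated aligner (CLUSTALW,
#' MAFFT, ...) has already been run; rows are taken verbatim.
#' @param path Aligned FASTA.
#' @return A [protein_alignment()].
#' @export
read_protein_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  sp <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  protein_alignment(stats::setNames(toupper(as.character(seqs)), sp))
}

#' Center-star multiple protein alignment
#'
#' The center is the sequence maximizing its summed pairwise alignment score
#' to all others (ties: first in input order). Every other sequence is
#' aligned to the center and the pairwise alignments merged under the
#' "once a gap, always a gap" rule. Adequate for the high-identity ortholog
#' sets this pipeline targets; not a progressive MSA.
#'
#' @param proteins Named character vector, species -> protein.
#' @inheritParams align_protein_pair
#' @return A [protein_alignment()] whose `score` is the center's summed
#'   pairwise score and with attribute `center` naming the center species.
#' @export
center_star_msa <- function(proteins, matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  n <- length(proteins)
  if (n < 2L) stop("center-star MSA needs at least 2 sequences")
  stopifnot(!is.null(names(proteins)))
  pairs <- utils::combn(n, 2L)
  scores <- matrix(0, n, n)
  alns <- vector("list", n * n)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    al <- align_protein_pair(proteins[[i]], proteins[[j]],
                             matrix, gap_open, gap_extend)
    scores[i, j] <- scores[j, i] <- al$score
    alns[[(i - 1L) * n + j]] <- al
  }
  center <- which.max(rowSums(scores))
  m <- nchar(proteins[[center]])
  others <- setdiff(seq_len(n), center)
  # ins[[i]][k+1]: residues of sequence i inserted before center residue k+1
  ins <- matrix(0L, nrow = n, ncol = m + 1L)
  aligned <- vector("list", n)
  for (i in others) {
    al <- if (i > center) alns[[(center - 1L) * n + i]] else {
      a <- alns[[(i - 1L) * n + center]]
      protein_alignment(a$rows[c(2L, 1L)], a$score)   # swap so center first
    }
    crow <- strsplit(al$rows[[1L]], "")[[1L]]
    srow <- strsplit(al$rows[[2L]], "")[[1L]]
    pos <- 0L
    for (t in seq_along(crow)) {
      if (crow[t] == "-") ins[i, pos + 1L] <- ins[i, pos + 1L] + 1L
      else pos <- pos + 1L
    }
    aligned[[i]] <- list(crow = crow, srow = srow)
  }
  master <- apply(ins, 2L, max)
  cres <- strsplit(proteins[[center]], "")[[1L]]
  # rebuild each row on the master gapping
  build_center <- function() {
    out <- character(0L)
    for (k in 0:m) {
      out <- c(out, rep("-", master[k + 1L]),
               if (k < m) cres[k + 1L] else character(0L))
    }
    paste0(out, collapse = "")
  }
  build_other <- function(i) {
    crow <- aligned[[i]]$crow; srow <- aligned[[i]]$srow
    out <- character(0L)
    t <- 1L
    for (k in 0:m) {
      block <- character(0L)
      while (t <= length(crow) && crow[t] == "-") {
        block <- c(block, srow[t]); t <- t + 1L
      }
      out <- c(out, block, rep("-", master[k + 1L] - length(block)))
      if (k < m) {
        out <- c(out, srow[t]); t <- t + 1L
      }
    }
    paste0(out, collapse = "")
  }
  rows <- character(n)
  rows[center] <- build_center()
  for (i in others) rows[i] <- build_other(i)
  names(rows) <- names(proteins)
  out <- protein_alignment(rows, score = sum(scores[center, ]))
  attr(out, "center") <- names(proteins)[center]
  out
}

#' Thread coding sequences through a protein alignment
#'
#' Each amino-acid gap becomes a `---` codon gap and each residue is
#' replaced by its source codon, in order, so the codon alignment is exactly
#' in frame. The protein rows must be the translations of the supplied CDS.
#'
#' @param pa A [protein_alignment()].
#' @param cds_by_species Named character vector, species -> CDS.
#' @param gene_id Gene identifier attached to the alignment.
#' @param code A [genetic_code()].
#' @return A `codon_alignment`: list with `species`, `rows` (named gapped
#'   CDS strings), `gene_id`.
#' @export
backtranslate <- function(pa, cds_by_species, gene_id = "gene",
                          code = genetic_code()) {
  rows <- character(length(pa$rows))
  for (i in seq_along(pa$rows)) {
    sp <- pa$species[i]
    cds <- cds_by_species[[sp]]
    if (is.null(cds)) stop("no CDS supplied for species ", sp)
    prot <- translate_cds(cds, code)
    res <- strsplit(pa$rows[[i]], "")[[1L]]
    cod <- split_codons(cds)
    ungapped <- res[res != "-"]
    if (length(ungapped) != length(cod)) {
      stop("protein row for ", sp, " has ", length(ungapped),
           " residues but CDS has ", length(cod), " codons")
    }
    paa <- strsplit(prot, "")[[1L]]
    mismatch <- which(ungapped != paa)
    if (length(mismatch) > 0L) {
      stop("protein row for ", sp, " does not match translate(cds) at residue ",
           mismatch[1L])
    }
    out <- rep("---", length(res))
    out[res != "-"] <- cod
    rows[i] <- paste0(out, collapse = "")
  }
  names(rows) <- pa$species
  codon_alignment(rows, gene_id)
}

#' Codon alignment container
#'
#' @param rows Named character vector of equal-length gapped CDS strings;
#'   gaps occur only as whole `---` codons.
#' @param gene_id Gene identifier.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(rows, gene_id = "gene") {
  if (length(unique(nchar(rows))) != 1L) {
    stop("codon alignment rows have unequal lengths")
  }
  if (nchar(rows[[1L]]) %% 3L != 0L) {
    stop("codon alignment width not divisible by 3")
  }
  structure(list(species = names(rows), rows = rows, gene_id = gene_id),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", x$gene_id, "-", length(x$rows), "species x",
      nchar(x$rows[[1L]]) / 3L, "codon columns\n")
  invisible(x)
}

#' Number of codon columns in a codon alignment
#' @param aln A [codon_alignment()].
#' @export
n_codon_columns <- function(aln) nchar(aln$rows[[1L]]) %/% 3L

#' Write / read codon alignments as aligned FASTA
#' @param aln A [codon_alignment()].
#' @param path File path (convention: `<gene_id>.codon.fasta`).
#' @export
write_codon_alignment <- function(aln, path) {
  write_gene_fasta(aln$rows, path)
}

#' @rdname write_codon_alignment
#' @param gene_id Gene id; default from file name.
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  if (is.null(gene_id)) {
    gene_id <- sub("\\.codon\\.(fa|fasta)$", "", basename(path),
                   ignore.case = TRUE)
  }
  seqs <- Biostrings::readBStringSet(path)
  sp <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  codon_alignment(stats::setNames(toupper(as.character(seqs)), sp), gene_id)
}

# Integer codon-state matrix: species x codon columns; 1..61 sense-codon
# index, 0 for gap/ambiguous/stop (treated as missing data downstream).
codon_state_matrix <- function(aln, code = genetic_code()) {
  mat <- matrix(0L, nrow = length(aln$rows), ncol = n_codon_columns(aln))
  for (i in seq_along(aln$rows)) {
    idx <- code$codon_index[split_codons(aln$rows[[i]])]
    idx[is.na(idx)] <- 0L
    mat[i, ] <- as.integer(idx)
  }
  rownames(mat) <- aln$species
  mat
}

#' Align one ortholog set: translate, center-star MSA, back-translate
#'
#' Convenience wrapper running the full per-gene alignment stage on a
#' `gene_records` set. With a single species the "alignment" is the
#' sequence itself.
#'
#' @param records A `gene_records` data.frame (see [read_gene_fasta()]).
#' @inheritParams align_protein_pair
#' @param code A [genetic_code()].
#' @return A [codon_alignment()].
#' @export
align_gene <- function(records, matrix = "BLOSUM62", gap_open = 11,
                       gap_extend = 1, code = genetic_code()) {
  cds <- stats::setNames(records$cds, records$species)
  gene_id <- records$gene_id[1L]
  prots <- vapply(cds, translate_cds, "", code = code)
  pa <- if (length(cds) >= 2L) {
    center_star_msa(prots, matrix, gap_open, gap_extend)
  } else {
    protein_alignment(prots)
  }
  backtranslate(pa, cds, gene_id, code)
}

#' Best-hit ortholog assignment by global alignment score
#'
#' Lightweight stand-in for a BLAST best-hit search, adequate at desk
#' scale: every candidate is globally aligned to the reference protein and
#' the highest-scoring candidate wins. Ties are broken by lexicographically
#' smallest candidate id and recorded in the `tie` attribute.
#'
#' @param reference Reference protein (e.g. the human sequence).
#' @param candidates Named character vector of candidate proteins.
#' @inheritParams align_protein_pair
#' @return List with `id`, `score`, and logical attribute `tie`.
#' @export
assign_ortholog <- function(reference, candidates, matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  if (length(candidates) == 0L) stop("empty candidate set")
  stopifnot(!is.null(names(candidates)))
  sc <- vapply(candidates, function(cand) {
    align_protein_pair(reference, cand, matrix, gap_open, gap_extend)$score
  }, numeric(1L))
  best <- sc == max(sc)
  ids <- sort(names(candidates)[best])
  out <- list(id = ids[1L], score = max(sc))
  attr(out, "tie") <- sum(best) > 1L
  out
}
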