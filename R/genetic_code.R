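#' Genetic code tables for codon-level analysis
#'
#' Builds the codon translation table used throughout the package. Codons are
#' ordered lexicographically over the nucleotide order T, C, A, G (TTT, TTC,
#' TTA, TTG, TCT, ...), the conventional ordering of codon-model rate
#' matrices, so that matrix indices are stable and reproducible across runs.
#' Stop codons are excluded from the sense-codon set that indexes all rate
#' matrices and site-count tables.
#'
#' @param table_id Identifier of the code. Only `"universal"` (the standard
#'   nuclear code) is shipped.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector over all 64 codons,
#'   `"*"` marks stop), `sense_codons` (ordered character vector, 61 codons
#'   for the universal code), and `codon_index` (named integer vector mapping
#'   sense codons to their matrix row).
#' @examples
#' gc <- genetic_code()
#' gc$codon_to_aa[["ATG"]]   # "M"
#' length(gc$sense_codons)   # 61
#' @export
genetic_code <- function(table_id = "universal") {
  if (!identical(table_id, "universal")) {
    stop("unsupported genetic code table: ", table_id)
  }
  nt <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(p3 = nt, p2 = nt, p1 = nt,
                              stringsAsFactors = FALSE)[, c("p1", "p2", "p3")],
                  1L, paste0, collapse = "")
  # Biostrings ships the standard code; reorder it to the T,C,A,G convention
  aa <- Biostrings::GENETIC_CODE[codons]
  names(aa) <- codons
  sense <- codons[aa != "*"]
  structure(
    list(
      table_id = table_id,
      codon_to_aa = aa,
      stop_codons = codons[aa == "*"],
      sense_codons = sense,
      codon_index = stats::setNames(seq_along(sense), sense)
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code>", x$table_id, "-", length(x$sense_codons),
      "sense codons,", length(x$stop_codons), "stop codons\n")
  invisible(x)
}

# Split a CDS string into codons. Returns character vector; no validation.
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0L))
  substring(cds, seq(1L, n, by = 3L), pmin(seq(3L, n + 2L, by = 3L), n))
}

#' Translate an in-frame coding sequence
#'
#' Codons containing `N` (ambiguity) translate to `X`; all-gap codons
#' (`---`) translate to `-` so that gap columns survive into protein space.
#' An internal stop codon is an error: downstream counting and likelihood
#' machinery is defined on sense codons only.
#'
#' @param cds Nucleotide string, length divisible by 3, alphabet `ACGTN-`.
#' @param code A [genetic_code()].
#' @return Amino-acid string of length `nchar(cds)/3`.
#' @examples
#' translate_cds("ATGTTT")     # "MF"
#' translate_cds("ATG---TTT")  # "M-F"
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length not divisible by 3 (", nchar(cds), " nt)")
  }
  cod <- split_codons(toupper(cds))
  aa <- code$codon_to_aa[cod]
  gap <- cod == "---"
  amb <- is.na(aa) & !gap
  aa[gap] <- "-"
  aa[amb] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) {
    stop("internal STOP codon ", cod[stop_at[1L]], " at codon index ",
         stop_at[1L])
  }
  paste0(aa, collapse = "")
}
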