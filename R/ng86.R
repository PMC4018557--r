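# Nei-Gojobori (1986) counting method: degeneracy-based site counts,
# pathway-averaged difference counts, Jukes-Cantor correction.

.ng86_cache <- new.env(parent = emptyenv())

# Lazily built lookup tables for a genetic code:
#  $s       numeric[61]        synonymous sites per sense codon
#  $Sd,$Nd  numeric[61 x 61]   path-averaged syn/nonsyn differences
#  $ndiff   integer[61 x 61]   differing codon positions
#  $valid   logical[61 x 61]   at least one stop-free substitution path
ng86_tables <- function(code = genetic_code()) {
  key <- code$table_id
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  sense <- code$sense_codons
  n <- length(sense)
  nt <- c("T", "C", "A", "G")
  aa_of <- function(cod) code$codon_to_aa[[cod]]
  is_stop <- function(cod) aa_of(cod) == "*"

  s <- vapply(sense, function(cod) {
    chars <- strsplit(cod, "")[[1L]]
    total <- 0
    for (p in 1:3) {
      muts <- vapply(setdiff(nt, chars[p]), function(b) {
        m <- chars; m[p] <- b; paste0(m, collapse = "")
      }, "")
      keep <- !vapply(muts, is_stop, logical(1L))
      if (any(keep)) {
        syn <- vapply(muts[keep], function(m) aa_of(m) == aa_of(cod),
                      logical(1L))
        total <- total + sum(syn) / sum(keep)
      }
    }
    total
  }, numeric(1L))

  Sd <- Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  ndiff <- matrix(0L, n, n, dimnames = list(sense, sense))
  valid <- matrix(TRUE, n, n, dimnames = list(sense, sense))
  chars <- strsplit(sense, "")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- chars[[i]]; b <- chars[[j]]
      pos <- which(a != b)
      k <- length(pos)
      ndiff[i, j] <- ndiff[j, i] <- k
      if (k == 0L) next
      perms <- if (k == 1L) list(pos) else
        if (k == 2L) list(pos, pos[2:1]) else
          lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                      c(3,1,2), c(3,2,1)), function(o) pos[o])
      sd_tot <- nd_tot <- 0; n_ok <- 0L
      for (ord in perms) {
        cur <- a; sd <- nd <- 0; ok <- TRUE
        for (p in ord) {
          nxt <- cur; nxt[p] <- b[p]
          ccod <- paste0(cur, collapse = ""); ncod <- paste0(nxt, collapse = "")
          if (is_stop(ncod)) { ok <- FALSE; break }
          if (aa_of(ccod) == aa_of(ncod)) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
      }
      if (n_ok == 0L) {
        valid[i, j] <- valid[j, i] <- FALSE
      } else {
        Sd[i, j] <- Sd[j, i] <- sd_tot / n_ok
        Nd[i, j] <- Nd[j, i] <- nd_tot / n_ok
      }
    }
  }
  out <- list(s = s, Sd = Sd, Nd = Nd, ndiff = ndiff, valid = valid)
  .ng86_cache[[key]] <- out
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position the synonymous fraction is the number of
#' synonymous single-base mutants divided by the number of single-base
#' mutants that do not create a stop codon; the codon's synonymous site
#' count is the sum of the three fractions and the nonsynonymous count is
#' its complement to 3.
#'
#' @param codon Sense codon string.
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(s = , n = )` with `s + n == 3`.
#' @examples
#' ng86_codon_sites("TTT")  # s = 1/3
#' ng86_codon_sites("ATG")  # s = 0
#' @export
ng86_codon_sites <- function(codon, code = genetic_code()) {
  idx <- unname(code$codon_index[toupper(codon)])
  if (is.na(idx)) stop("not a sense codon: ", codon)
  tab <- ng86_tables(code)
  c(s = unname(tab$s[idx]), n = 3 - unname(tab$s[idx]))
}

#' Pathway-averaged substitution differences between two codons
#'
#' All minimal substitution orderings between the codons (1, 2 or 6 paths)
#' are enumerated; paths passing through a stop codon are excluded; each
#' step is classified synonymous/nonsynonymous and the counts averaged over
#' the surviving paths. If every path crosses a stop codon the pair is
#' unresolvable and `c(NA, NA)` is returned with attribute
#' `no_valid_path = TRUE` (callers treat the column as missing).
#'
#' @param a,b Sense codon strings.
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(sd = , nd = )` with
#'   `sd + nd == number of differing positions` when resolvable.
#' @examples
#' ng86_codon_differences("TTT", "TTA")  # c(sd = 0, nd = 1)
#' ng86_codon_differences("TTT", "GTA")  # c(sd = 0.5, nd = 1.5)
#' @export
ng86_codon_differences <- function(a, b, code = genetic_code()) {
  ia <- unname(code$codon_index[toupper(a)])
  ib <- unname(code$codon_index[toupper(b)])
  if (is.na(ia)) stop("not a sense codon: ", a)
  if (is.na(ib)) stop("not a sense codon: ", b)
  tab <- ng86_tables(code)
  if (!tab$valid[ia, ib]) {
    return(structure(c(sd = NA_real_, nd = NA_real_), no_valid_path = TRUE))
  }
  c(sd = tab$Sd[ia, ib], nd = tab$Nd[ia, ib])
}

jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise dN/dS by the Nei-Gojobori counting method
#'
#' Columns where either row carries a gap, an ambiguous codon, or where no
#' stop-free substitution path exists are skipped (pairwise deletion); the
#' number of codons actually compared is reported so the site totals stay
#' interpretable. Site counts are averaged between the two sequences;
#' proportions are Jukes-Cantor corrected. Saturation (p >= 3/4) yields
#' `NA` distances with an explicit `saturated_*` flag rather than a silent
#' `NaN`; `omega` is `NA` with `omega_defined = FALSE` whenever `dS == 0`.
#'
#' @param a,b Aligned gapped CDS strings of equal length (codon-sized gaps).
#' @param code A [genetic_code()].
#' @return Object of class `pairwise_dnds`: list with fields `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `n_codons_compared`, `n_codons_skipped`, `saturated_s`, `saturated_n`,
#'   `omega_defined`.
#' @export
ng86_pairwise <- function(a, b, code = genetic_code()) {
  if (nchar(a) != nchar(b)) stop("aligned rows have unequal length")
  tab <- ng86_tables(code)
  ia <- unname(code$codon_index[split_codons(toupper(a))])
  ib <- unname(code$codon_index[split_codons(toupper(b))])
  ok <- !is.na(ia) & !is.na(ib)
  ok[ok] <- tab$valid[cbind(ia[ok], ib[ok])]
  n_cmp <- sum(ok)
  S <- N <- Sd <- Nd <- 0
  if (n_cmp > 0L) {
    S <- (sum(tab$s[ia[ok]]) + sum(tab$s[ib[ok]])) / 2
    N <- 3 * n_cmp - S
    Sd <- sum(tab$Sd[cbind(ia[ok], ib[ok])])
    Nd <- sum(tab$Nd[cbind(ia[ok], ib[ok])])
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  saturated_s <- is.na(dS)
  saturated_n <- is.na(dN)
  omega_defined <- !saturated_s && !saturated_n && dS > 0
  omega <- if (omega_defined) dN / dS else NA_real_
  structure(
    list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         dS = dS, dN = dN, omega = omega,
         n_codons_compared = n_cmp,
         n_codons_skipped = length(ia) - n_cmp,
         saturated_s = saturated_s, saturated_n = saturated_n,
         omega_defined = omega_defined),
    class = "pairwise_dnds")
}

#' @export
print.pairwise_dnds <- function(x, ...) {
  cat(sprintf("<pairwise_dnds> %d codons: dN=%.4g dS=%.4g omega=%s\n",
              x$n_codons_compared, x$dN, x$dS,
              if (x$omega_defined) sprintf("%.4g", x$omega) else "undefined"))
  invisible(x)
}

#' All-pairs NG86 table for one codon alignment
#'
#' @param aln A [codon_alignment()].
#' @param code A [genetic_code()].
#' @return data.frame with one row per unordered species pair: `gene_id`,
#'   `species_a`, `species_b`, `S_sites`, `N_sites`, `Sd`, `Nd`, `dS`,
#'   `dN`, `omega`, `n_codons_compared` (TSV-ready).
#' @export
ng86_gene_table <- function(aln, code = genetic_code()) {
  sp <- aln$species
  if (length(sp) < 2L) {
    return(data.frame(gene_id = character(0L), species_a = character(0L),
                      species_b = character(0L), S_sites = numeric(0L),
                      N_sites = numeric(0L), Sd = numeric(0L), Nd = numeric(0L),
                      dS = numeric(0L), dN = numeric(0L), omega = numeric(0L),
                      n_codons_compared = integer(0L)))
  }
  pairs <- utils::combn(length(sp), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    r <- ng86_pairwise(aln$rows[[i]], aln$rows[[j]], code)
    data.frame(gene_id = aln$gene_id, species_a = sp[i], species_b = sp[j],
               S_sites = r$S_sites, N_sites = r$N_sites, Sd = r$Sd, Nd = r$Nd,
               dS = r$dS, dN = r$dN, omega = r$omega,
               n_codons_compared = r$n_codons_compared,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
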