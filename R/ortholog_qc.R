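# Ortholog QC: flag putative orthologs whose synonymous divergence from the
# reference species is an extreme outlier (paralog / contamination screen).

#' Reference-vs-species synonymous divergence table
#'
#' Computes NG86 `dS` between the reference species (typically human) and
#' every other species, per gene. Genes lacking the reference are skipped
#' and listed in the `skipped` attribute; missing or saturated entries are
#' absent from the table, never zero-filled.
#'
#' @param alignments List of [codon_alignment()] objects.
#' @param reference Reference species name.
#' @param code A [genetic_code()].
#' @return data.frame `gene_id`, `species`, `ds`, `n_codons_compared`.
#' @export
ds_to_reference <- function(alignments, reference, code = genetic_code()) {
  skipped <- character(0L)
  rows <- list()
  for (aln in alignments) {
    if (!reference %in% aln$species) {
      skipped <- c(skipped, aln$gene_id)
      next
    }
    ref_row <- aln$rows[[match(reference, aln$species)]]
    for (sp in setdiff(aln$species, reference)) {
      r <- ng86_pairwise(ref_row, aln$rows[[match(sp, aln$species)]], code)
      if (r$n_codons_compared == 0L || r$saturated_s) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = aln$gene_id, species = sp, ds = r$dS,
        n_codons_compared = r$n_codons_compared, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(0L), species = character(0L),
               ds = numeric(0L), n_codons_compared = integer(0L))
  attr(out, "skipped") <- skipped
  out
}

#' Flag dS outliers per species
#'
#' For each species column the median and a dispersion estimate of the
#' finite `ds` values are computed and genes with
#' `ds > median + k * dispersion` (strict inequality) are flagged. The
#' default reads "k standard deviations from the median" literally: the
#' ordinary sample standard deviation about the mean, added to the median;
#' `dispersion = "mad"` substitutes the (consistency-scaled) median
#' absolute deviation for a robust variant.
#'
#' Note that with few genes a single outlier mathematically cannot be
#' flagged: a lone extreme value among `n - 1` identical ones sits exactly
#' `sqrt(n)` sample standard deviations above the median, so columns with
#' `n <= k^2` genes (16 at the default `k = 4`) never flag it. This is a
#' property of the filter, not a bug, and is covered by the test suite;
#' it guards against false confidence from small gene sets.
#'
#' @param ds_table Output of [ds_to_reference()].
#' @param k Multiplier on the dispersion (default 4).
#' @param dispersion `"sd"` (default) or `"mad"`.
#' @return List of per-species reports, each of class `ds_outlier_report`:
#'   list with `species`, `median_ds`, `sd_ds`, `threshold`, `flagged`
#'   (data.frame `gene_id`, `ds`), `n_genes`.
#' @export
flag_ds_outliers <- function(ds_table, k = 4, dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  reports <- list()
  for (sp in unique(ds_table$species)) {
    sub <- ds_table[ds_table$species == sp, , drop = FALSE]
    ds <- sub$ds[is.finite(sub$ds)]
    sub <- sub[is.finite(sub$ds), , drop = FALSE]
    if (length(ds) < 2L) {
      warning("species ", sp, " has <2 finite ds values; nothing flagged")
      reports[[sp]] <- structure(
        list(species = sp, median_ds = NA_real_, sd_ds = NA_real_,
             threshold = NA_real_,
             flagged = data.frame(gene_id = character(0L), ds = numeric(0L)),
             n_genes = length(ds)),
        class = "ds_outlier_report")
      next
    }
    med <- stats::median(ds)
    disp <- if (dispersion == "sd") stats::sd(ds) else stats::mad(ds)
    thr <- med + k * disp
    hit <- sub$ds > thr
    reports[[sp]] <- structure(
      list(species = sp, median_ds = med, sd_ds = disp, threshold = thr,
           flagged = data.frame(gene_id = sub$gene_id[hit], ds = sub$ds[hit],
                                stringsAsFactors = FALSE),
           n_genes = length(ds)),
      class = "ds_outlier_report")
  }
  reports
}

#' @export
print.ds_outlier_report <- function(x, ...) {
  cat(sprintf("<ds_outlier_report> %s: n=%d median=%.4g sd=%.4g thr=%.4g flagged=%d\n",
              x$species, x$n_genes, x$median_ds, x$sd_ds, x$threshold,
              nrow(x$flagged)))
  invisible(x)
}

#' Collapse outlier reports to a flat removal-log table
#' @param reports Output of [flag_ds_outliers()].
#' @param action Action string recorded per row.
#' @return data.frame `gene_id`, `species`, `ds`, `threshold`, `action`.
#' @export
ds_outlier_log <- function(reports, action = "flag") {
  rows <- lapply(reports, function(r) {
    if (nrow(r$flagged) == 0L) return(NULL)
    data.frame(gene_id = r$flagged$gene_id, species = r$species,
               ds = r$flagged$ds, threshold = r$threshold, action = action,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0L), species = character(0L),
                      ds = numeric(0L), threshold = numeric(0L),
                      action = character(0L)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Apply the dS-outlier filter to a set of alignments
#'
#' Default policy is `"flag_only"` (human-in-the-loop curation: alignments
#' are returned unchanged and the log records the flags).
#' `"remove_species"` drops the flagged species' row from that gene's
#' alignment only; `"remove_gene"` drops the whole gene wherever any
#' species is flagged.
#'
#' @param alignments Named list of [codon_alignment()] (names = gene ids).
#' @param reports Output of [flag_ds_outliers()].
#' @param policy Removal policy.
#' @return List with `alignments` (filtered) and `log` (removal-log
#'   data.frame, one row per flagged (gene, species)).
#' @export
apply_ds_filter <- function(alignments, reports,
                            policy = c("flag_only", "remove_species",
                                       "remove_gene")) {
  policy <- match.arg(policy)
  log <- ds_outlier_log(reports, action = switch(policy,
    flag_only = "flag", remove_species = "remove_species",
    remove_gene = "remove_gene"))
  if (policy == "flag_only" || nrow(log) == 0L) {
    return(list(alignments = alignments, log = log))
  }
  if (is.null(names(alignments))) {
    names(alignments) <- vapply(alignments, `[[`, "", "gene_id")
  }
  if (policy == "remove_gene") {
    alignments <- alignments[setdiff(names(alignments), unique(log$gene_id))]
  } else {
    for (i in seq_len(nrow(log))) {
      g <- log$gene_id[i]
      aln <- alignments[[g]]
      if (is.null(aln)) next
      keep <- setdiff(aln$species, log$species[i])
      alignments[[g]] <- if (length(keep) >= 2L) {
        codon_alignment(aln$rows[keep], aln$gene_id)
      } else NULL
    }
    alignments <- alignments[!vapply(alignments, is.null, logical(1L))]
  }
  list(alignments = alignments, log = log)
}
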