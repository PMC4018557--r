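# End-to-end orchestration: align -> QC -> model fits -> per-branch dN/dS
# -> class summaries -> lineage contrasts, with flat TSV/JSON stage outputs
# so any stage can be audited or re-run in isolation.

#' Pipeline configuration
#'
#' @param genes_dir Directory of per-gene FASTA files (`<gene_id>.fasta`).
#' @param tree_file Newick species tree.
#' @param class_table TSV with `gene_id`, `class_label`.
#' @param out_dir Output directory.
#' @param reference Reference species for ortholog QC (default `"human"`).
#' @param tags Named list of branch tags (tip-label sets).
#' @param qc List: `k` (default 4), `dispersion` (`"sd"`/`"mad"`),
#'   `policy` (`"flag_only"` default, `"remove_species"`, `"remove_gene"`).
#' @param models Character vector of [model_spec()] names to fit, in
#'   order; nested fits are chained as warm starts.
#' @param stats List: `lineages` (default: all terminal non-reference
#'   species), `exclude` (lineages to drop, e.g. an armadillo-like taxon
#'   without an intra-ordinal comparison), `ds_floor` (default 1e-6),
#'   `bootstrap_B` (default 0 = skip CIs), `omega_source`
#'   (`"free_ratio"` default, or `"ng86"` for the fast counting-based
#'   per-gene omega table).
#' @param fit_opts Passed to [fit_codon_model()] (e.g. `n_starts`).
#' @param seed Seed for all stochastic steps.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(genes_dir = NULL, tree_file = NULL,
                            class_table = NULL, out_dir = NULL,
                            reference = "human", tags = list(),
                            qc = list(), models = c("SINGLE_RATIO",
                                                    "FREE_RATIO"),
                            stats = list(), fit_opts = list(), seed = 1L) {
  cfg <- list(
    genes_dir = genes_dir, tree_file = tree_file, class_table = class_table,
    out_dir = out_dir, reference = reference, tags = tags,
    qc = utils::modifyList(list(k = 4, dispersion = "sd",
                                policy = "flag_only"), qc),
    models = models,
    stats = utils::modifyList(list(lineages = NULL, exclude = character(0L),
                                   ds_floor = 1e-6, bootstrap_B = 0L,
                                   omega_source = "free_ratio"), stats),
    fit_opts = fit_opts, seed = as.integer(seed))
  if (length(cfg$models) < 1L) stop("at least one model must be named")
  ok <- c("SINGLE_RATIO", "BRANCH_CATARRHINE", "BRANCH_CATARRHINE_CETACEAN",
          "FREE_RATIO")
  bad <- setdiff(cfg$models, ok)
  if (length(bad) > 0L) stop("unknown model names: ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error with the offending key named.
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L) {
    stop("unknown config keys in ", path, ": ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, y)
}

#' Run the full comparative-constraint pipeline
#'
#' Stages: load inputs -> per-gene codon alignment -> dS-outlier QC ->
#' codon-model fits (all configured models, nested warm starts) ->
#' per-branch dN/dS -> class x lineage ratio-of-means table -> all-pairs
#' lineage contrasts. Every dropped gene/species appears in the exclusion
#' log with a reason code; per-gene soft failures (non-convergence) are
#' recorded and the pipeline continues. Outputs are written as flat TSV /
#' JSON under `out_dir` when it is set.
#'
#' @param config A `pipeline_config`, or a path to a YAML config file.
#' @param bundle Optional in-memory input bundle from
#'   [generate_gene_classes()] (overrides `genes_dir`/`tree_file`/
#'   `class_table`).
#' @return List with `alignments`, `qc`, `fits`, `branch_estimates`
#'   (stacked data.frame), `class_table` (class x lineage ratio-of-means),
#'   `contrasts` (per class), `contrast_matrices`, `exclusions`, `config`.
#' @export
run_pipeline <- function(config, bundle = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  excl <- list()
  note_excl <- function(stage, gene_id, species, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(
      stage = stage, gene_id = gene_id, species = species, reason = reason,
      stringsAsFactors = FALSE)
  }

  ## ---- load ----
  if (!is.null(bundle)) {
    tree <- bundle$tree
    classes <- bundle$classes
    raw <- lapply(bundle$genes, function(a) {
      gene_records(a$gene_id, a$species, gsub("-", "", a$rows))
    })
  } else {
    for (p in c(config$genes_dir, config$tree_file, config$class_table)) {
      if (!is.null(p) && !file.exists(p)) stop("input path missing: ", p)
    }
    tree <- read_species_tree(file = config$tree_file, tags = config$tags)
    classes <- load_gene_class_table(config$class_table)
    files <- sort(list.files(config$genes_dir, pattern = "\\.(fa|fasta|fna)$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no FASTA files in ", config$genes_dir)
    raw <- lapply(files, read_gene_fasta)
    names(raw) <- vapply(raw, function(r) r$gene_id[1L], "")
  }

  ## ---- align ----
  alignments <- list()
  for (g in names(raw)) {
    rec <- raw[[g]]
    rej <- attr(rec, "rejected")
    if (!is.null(rej) && nrow(rej) > 0L) {
      for (i in seq_len(nrow(rej))) note_excl("align", g, rej$species[i],
                                              rej$reason[i])
    }
    unknown <- setdiff(rec$species, tree$phy$tip.label)
    for (sp in unknown) note_excl("align", g, sp, "species_not_in_tree")
    rec <- rec[rec$species %in% tree$phy$tip.label, , drop = FALSE]
    if (nrow(rec) < 2L) {
      note_excl("align", g, NA_character_, "fewer_than_2_species")
      next
    }
    alignments[[g]] <- align_gene(rec)
  }

  ## ---- qc ----
  ds_tab <- ds_to_reference(alignments, config$reference)
  for (g in attr(ds_tab, "skipped")) {
    note_excl("qc", g, config$reference, "reference_missing")
  }
  qc_reports <- if (nrow(ds_tab) > 0L) {
    flag_ds_outliers(ds_tab, k = config$qc$k,
                     dispersion = config$qc$dispersion)
  } else list()
  filt <- apply_ds_filter(alignments, qc_reports, policy = config$qc$policy)
  alignments <- filt$alignments
  if (nrow(filt$log) > 0L) {
    for (i in seq_len(nrow(filt$log))) {
      note_excl("qc", filt$log$gene_id[i], filt$log$species[i],
                paste0("ds_outlier_", filt$log$action[i]))
    }
  }

  ## ---- fit ----
  fits <- list()
  model_order <- config$models[order(match(config$models,
    c("SINGLE_RATIO", "BRANCH_CATARRHINE", "BRANCH_CATARRHINE_CETACEAN",
      "FREE_RATIO")))]
  for (g in sort(names(alignments))) {
    aln <- alignments[[g]]
    fits[[g]] <- list()
    prev <- NULL
    for (m in model_order) {
      opts <- config$fit_opts
      opts$seed <- (config$seed + match(m, model_order)) %% .Machine$integer.max
      if (!is.null(prev) && isTRUE(prev$converged)) opts$init <- prev
      fit <- tryCatch(fit_codon_model(aln, tree, model_spec(m), opts),
                      error = function(e) NULL)
      if (is.null(fit)) {
        note_excl("fit", g, NA_character_, paste0("fit_error_", m))
        next
      }
      if (!fit$converged) note_excl("fit", g, NA_character_,
                                    paste0("not_converged_", m))
      fits[[g]][[m]] <- fit
      prev <- fit
    }
  }

  ## ---- per-branch estimates ----
  est_model <- if ("FREE_RATIO" %in% model_order) "FREE_RATIO" else
    model_order[length(model_order)]
  branch_rows <- list()
  for (g in sort(names(fits))) {
    fit <- fits[[g]][[est_model]]
    if (is.null(fit) || !isTRUE(fit$converged)) next
    branch_rows[[g]] <- branch_dnds(fit)
  }
  branch_est <- if (length(branch_rows) > 0L) {
    do.call(rbind, c(branch_rows, list(make.row.names = FALSE)))
  } else NULL

  ## ---- class summaries ----
  lineages <- config$stats$lineages
  if (is.null(lineages)) {
    lineages <- setdiff(tree$phy$tip.label,
                        c(config$reference, config$stats$exclude))
  }
  class_tab <- contrasts <- cmats <- NULL
  if (!is.null(branch_est)) {
    class_tab <- class_lineage_table(branch_est, classes,
                                     lineages = lineages)
    ## ---- contrasts ----
    if (config$stats$omega_source == "free_ratio" &&
        !"FREE_RATIO" %in% model_order) {
      contrasts <- "NOT_RUN"   # needs per-branch free-ratio omega
    } else {
      omega_tbl <- if (config$stats$omega_source == "ng86") {
        ng86_omega_table(alignments, config$reference)
      } else {
        data.frame(gene_id = branch_est$gene_id,
                   lineage = branch_est$child_name,
                   omega = branch_est$omega, dS = branch_est$dS,
                   stringsAsFactors = FALSE)[branch_est$terminal, ]
      }
      contrasts <- list()
      for (cl in sort(unique(classes$class_label))) {
        contrasts[[cl]] <- tryCatch(
          lineage_contrasts(omega_tbl, classes, cl, lineages = lineages,
                            ds_floor = config$stats$ds_floor),
          error = function(e) NULL)
      }
      cmats <- lapply(contrasts, function(ct) {
        if (is.null(ct)) NULL else contrast_matrix(ct)
      })
    }
  }

  exclusions <- if (length(excl) > 0L) {
    do.call(rbind, c(excl, list(make.row.names = FALSE)))
  } else data.frame(stage = character(0L), gene_id = character(0L),
                    species = character(0L), reason = character(0L))

  out <- list(alignments = alignments, qc = list(ds_table = ds_tab,
                                                 reports = qc_reports,
                                                 log = filt$log),
              fits = fits, branch_estimates = branch_est,
              class_table = class_tab, contrasts = contrasts,
              contrast_matrices = cmats, exclusions = exclusions,
              config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

# Per-gene per-lineage omega from NG86 reference-vs-species comparisons:
# a fast counting-based substitute for free-ratio terminal-branch omegas.
ng86_omega_table <- function(alignments, reference, code = genetic_code()) {
  rows <- list()
  for (aln in alignments) {
    if (!reference %in% aln$species) next
    ref_row <- aln$rows[[match(reference, aln$species)]]
    for (sp in setdiff(aln$species, reference)) {
      r <- ng86_pairwise(ref_row, aln$rows[[match(sp, aln$species)]], code)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = aln$gene_id, lineage = sp,
        omega = if (r$omega_defined) r$omega else NA_real_,
        dS = r$dS, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- out$config
  cfg$fit_opts <- cfg$fit_opts[lengths(cfg$fit_opts) > 0]
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  if (nrow(out$qc$ds_table) > 0L) wt(out$qc$ds_table, "qc_ds_table.tsv")
  wt(out$qc$log, "qc_removal_log.tsv")
  wt(out$exclusions, "exclusions.tsv")
  if (!is.null(out$branch_estimates)) {
    wt(out$branch_estimates, "branch_estimates.tsv")
  }
  if (!is.null(out$class_table)) wt(out$class_table, "class_lineage_table.tsv")
  if (is.list(out$contrasts)) {
    for (cl in names(out$contrasts)) {
      if (is.null(out$contrasts[[cl]])) next
      wt(out$contrasts[[cl]], paste0("contrasts_", cl, ".tsv"))
      m <- out$contrast_matrices[[cl]]
      utils::write.table(
        data.frame(lineage = rownames(m), m, check.names = FALSE),
        file.path(out_dir, paste0("significance_matrix_", cl, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  fits_summary <- list()
  for (g in names(out$fits)) {
    for (m in names(out$fits[[g]])) {
      f <- out$fits[[g]][[m]]
      fits_summary[[paste(g, m, sep = ".")]] <- list(
        gene_id = g, model = m, lnL = f$lnL, kappa = f$kappa,
        omega = as.list(f$omega), converged = f$converged,
        n_starts_used = f$n_starts_used)
    }
  }
  jsonlite::write_json(unname(fits_summary),
                       file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
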