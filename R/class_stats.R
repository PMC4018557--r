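# Class-level constraint summaries and lineage contrasts.
#
# The class statistic is the ratio of means, mean(dN)/mean(dS) over the
# genes of a class on a lineage, rather than the mean of per-gene dN/dS:
# short branches put individual dS against its zero bound, where per-gene
# ratios are undefined or wildly noisy, while the ratio of means stays
# well-behaved (genes with dS = 0 are deliberately included).

#' Ratio-of-means dN/dS for one gene class on one lineage
#'
#' @param branch_est data.frame of per-gene per-branch estimates as
#'   produced by [branch_dnds()] (stacked over genes): columns `gene_id`,
#'   `child_name`, `terminal`, `dN`, `dS`.
#' @param classes A `gene_class_map` (see [load_gene_class_table()]).
#' @param lineage Branch selector: a terminal species name or internal
#'   branch label matched against `child_name`.
#' @param class_label Class to summarise.
#' @return One-row data.frame: `class_label`, `lineage`, `mean_dN`,
#'   `mean_dS`, `ratio_of_means`, `mean_of_ratios` (reported alongside for
#'   comparison; `NA` when any per-gene dS is 0), `n_genes`, `n_excluded`.
#' @export
class_ratio_of_means <- function(branch_est, classes, lineage, class_label) {
  genes <- unique(classes$gene_id[classes$class_label == class_label])
  if (length(genes) == 0L) {
    warning("empty class: ", class_label)
    return(data.frame(class_label = class_label, lineage = lineage,
                      mean_dN = NA_real_, mean_dS = NA_real_,
                      ratio_of_means = NA_real_, mean_of_ratios = NA_real_,
                      n_genes = 0L, n_excluded = 0L,
                      stringsAsFactors = FALSE))
  }
  sub <- branch_est[branch_est$child_name == lineage &
                      branch_est$gene_id %in% genes, , drop = FALSE]
  sub <- sub[is.finite(sub$dN) & is.finite(sub$dS), , drop = FALSE]
  n <- nrow(sub)
  n_excluded <- length(genes) - n
  mean_dN <- if (n > 0L) mean(sub$dN) else NA_real_
  mean_dS <- if (n > 0L) mean(sub$dS) else NA_real_
  rom <- if (n > 0L && mean_dS > 0) mean_dN / mean_dS else NA_real_
  mor <- if (n > 0L && all(sub$dS > 0)) mean(sub$dN / sub$dS) else NA_real_
  data.frame(class_label = class_label, lineage = lineage,
             mean_dN = mean_dN, mean_dS = mean_dS,
             ratio_of_means = rom, mean_of_ratios = mor,
             n_genes = n, n_excluded = n_excluded, stringsAsFactors = FALSE)
}

#' Full gene-class x lineage ratio-of-means table
#'
#' @inheritParams class_ratio_of_means
#' @param lineages Character vector of lineages (default: all terminal
#'   `child_name` values present).
#' @param class_labels Classes (default: all in `classes`).
#' @return data.frame, one row per (class, lineage) cell.
#' @export
class_lineage_table <- function(branch_est, classes, lineages = NULL,
                                class_labels = NULL) {
  if (is.null(lineages)) {
    lineages <- sort(unique(branch_est$child_name[branch_est$terminal]))
  }
  if (is.null(class_labels)) class_labels <- sort(unique(classes$class_label))
  do.call(rbind, lapply(class_labels, function(cl) {
    do.call(rbind, lapply(lineages, function(ln) {
      class_ratio_of_means(branch_est, classes, ln, cl)
    }))
  }))
}

#' Bootstrap confidence interval for a class ratio-of-means
#'
#' Percentile interval over gene-level resamples with replacement
#' (the resampling unit is the gene). Seeded and reproducible.
#'
#' @inheritParams class_ratio_of_means
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return List `low`, `high`, `point`, `B`; attribute `degenerate` is TRUE
#'   for classes of a single gene.
#' @export
ratio_of_means_ci <- function(branch_est, classes, lineage, class_label,
                              B = 1000L, seed = 1L, level = 0.95) {
  if (B < 100L) stop("B must be >= 100")
  genes <- unique(classes$gene_id[classes$class_label == class_label])
  sub <- branch_est[branch_est$child_name == lineage &
                      branch_est$gene_id %in% genes, , drop = FALSE]
  sub <- sub[is.finite(sub$dN) & is.finite(sub$dS), , drop = FALSE]
  point <- if (nrow(sub) > 0L && mean(sub$dS) > 0) {
    mean(sub$dN) / mean(sub$dS)
  } else NA_real_
  rng <- local_rng(seed)
  idx <- matrix(sample.int(nrow(sub), nrow(sub) * B, replace = TRUE),
                nrow = B)
  restore_rng(rng)
  stat <- apply(idx, 1L, function(i) {
    ds <- mean(sub$dS[i])
    if (ds > 0) mean(sub$dN[i]) / ds else NA_real_
  })
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  out <- list(low = qs[1L], high = qs[2L], point = point, B = B)
  attr(out, "degenerate") <- nrow(sub) < 2L
  if (nrow(sub) < 2L) warning("class/lineage cell has <2 genes; CI degenerate")
  out
}

#' All-pairs lineage contrasts within a gene class
#'
#' For every unordered pair of lineages, a one-way ANOVA (two groups,
#' F with df (1, n_a + n_b - 2)) on the per-gene omega values, with
#' Bonferroni correction over all pairs tested within the class. Genes
#' whose dS on a branch is below `ds_floor` are excluded from that
#' lineage's sample (omega is not meaningfully defined there); lineages
#' left with fewer than 2 usable genes have their pairs reported as
#' `NOT_TESTED`.
#'
#' @param per_gene_omega data.frame with columns `gene_id`, `lineage`
#'   (`child_name`), `omega` and `dS` — typically stacked [branch_dnds()]
#'   rows from free-ratio fits restricted to terminal branches.
#' @param classes A `gene_class_map`.
#' @param class_label Class to test.
#' @param lineages Lineages to contrast (default: all present).
#' @param ds_floor Exclusion threshold on per-gene branch dS (default 1e-6).
#' @return data.frame, one row per unordered pair: `class_label`,
#'   `lineage_a`, `lineage_b`, `F_statistic`, `p_raw`, `p_bonferroni`,
#'   `n_a`, `n_b`, `status` (`"TESTED"`/`"NOT_TESTED"`); attribute
#'   `n_pairs` is the Bonferroni family size, attribute `n_excluded` the
#'   count of (gene, lineage) values dropped by the dS floor.
#' @export
lineage_contrasts <- function(per_gene_omega, classes, class_label,
                              lineages = NULL, ds_floor = 1e-6) {
  genes <- unique(classes$gene_id[classes$class_label == class_label])
  tab <- per_gene_omega[per_gene_omega$gene_id %in% genes, , drop = FALSE]
  if (is.null(lineages)) lineages <- sort(unique(tab$lineage))
  tab <- tab[tab$lineage %in% lineages, , drop = FALSE]
  usable <- is.finite(tab$omega) & is.finite(tab$dS) & tab$dS >= ds_floor
  n_excluded <- sum(!usable)
  tab <- tab[usable, , drop = FALSE]
  groups <- split(tab$omega, factor(tab$lineage, levels = lineages))
  ok <- vapply(groups, length, integer(1L)) >= 2L
  testable <- lineages[ok]
  L <- length(testable)
  n_pairs <- L * (L - 1L) / 2L
  if (length(lineages) < 2L) stop("need at least 2 lineages to contrast")
  pairs <- utils::combn(length(lineages), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- lineages[pairs[1L, k]]; b <- lineages[pairs[2L, k]]
    ga <- groups[[a]]; gb <- groups[[b]]
    if (!(a %in% testable) || !(b %in% testable)) {
      return(data.frame(class_label = class_label, lineage_a = a,
                        lineage_b = b, F_statistic = NA_real_,
                        p_raw = NA_real_, p_bonferroni = NA_real_,
                        n_a = length(ga), n_b = length(gb),
                        status = "NOT_TESTED", stringsAsFactors = FALSE))
    }
    x <- c(ga, gb)
    g <- factor(rep(c("a", "b"), c(length(ga), length(gb))))
    if (stats::var(x) < .Machine$double.eps) {
      Fst <- 0; p <- 1            # identical omega vectors across groups
    } else {
      tst <- stats::oneway.test(x ~ g, var.equal = TRUE)
      Fst <- unname(tst$statistic)
      p <- tst$p.value
      if (!is.finite(p)) { # zero within-group variance, groups differ
        Fst <- Inf; p <- .Machine$double.xmin
      }
      p <- max(p, .Machine$double.xmin)
    }
    data.frame(class_label = class_label, lineage_a = a, lineage_b = b,
               F_statistic = Fst, p_raw = p,
               p_bonferroni = min(1, p * n_pairs),
               n_a = length(ga), n_b = length(gb), status = "TESTED",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_pairs") <- n_pairs
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Pairwise significance matrix from lineage contrasts
#'
#' @param contrasts Output of [lineage_contrasts()].
#' @return Square matrix of Bonferroni-adjusted p-values (NA on the
#'   diagonal and for untested pairs).
#' @export
contrast_matrix <- function(contrasts) {
  lin <- sort(unique(c(contrasts$lineage_a, contrasts$lineage_b)))
  m <- matrix(NA_real_, length(lin), length(lin), dimnames = list(lin, lin))
  for (i in seq_len(nrow(contrasts))) {
    m[contrasts$lineage_a[i], contrasts$lineage_b[i]] <-
      m[contrasts$lineage_b[i], contrasts$lineage_a[i]] <-
      contrasts$p_bonferroni[i]
  }
  m
}
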