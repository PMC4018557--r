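est_row <- function(gene, lineage, dN, dS) {
  data.frame(gene_id = gene, child_name = lineage, terminal = TRUE,
             dN = dN, dS = dS, omega = ifelse(dS > 0, dN / dS, NA_real_),
             stringsAsFactors = FALSE)
}

two_gene_classes <- gene_class_map(
  data.frame(gene_id = c("g1", "g2"), class_label = "C"))

test_that("ratio of means follows the worked arithmetic, not mean of ratios", {
  est <- rbind(est_row("g1", "dog", 0.1, 0.2), est_row("g2", "dog", 0.3, 0.4))
  row <- class_ratio_of_means(est, two_gene_classes, "dog", "C")
  expect_equal(row$ratio_of_means, 0.2 / 0.3)
  expect_equal(row$ratio_of_means, 0.6667, tolerance = 1e-4)
  expect_equal(row$mean_of_ratios, 0.625)
  expect_identical(row$n_genes, 2L)
})

test_that("dS = 0 genes are included and never make the class value undefined", {
  est <- rbind(est_row("g1", "dog", 0, 0), est_row("g2", "dog", 0.1, 0.2))
  row <- class_ratio_of_means(est, two_gene_classes, "dog", "C")
  expect_equal(row$ratio_of_means, 0.05 / 0.10)
  expect_true(is.na(row$mean_of_ratios))  # the convention's motivation
  expect_identical(row$n_genes, 2L)
})

test_that("ratio of means is order-invariant, duplication-invariant, and
           coincides with mean of ratios at equal dS", {
  set.seed(20)
  n <- 30L
  est <- do.call(rbind, lapply(seq_len(n), function(i) {
    est_row(sprintf("g%02d", i), "dog", runif(1, 0, 0.2), runif(1, 0.01, 0.3))
  }))
  cls <- gene_class_map(data.frame(gene_id = est$gene_id, class_label = "C"))
  r1 <- class_ratio_of_means(est, cls, "dog", "C")$ratio_of_means
  r2 <- class_ratio_of_means(est[sample(n), ], cls, "dog", "C")$ratio_of_means
  expect_equal(r1, r2)
  dup <- rbind(est, transform(est, gene_id = paste0(gene_id, "b")))
  clsd <- gene_class_map(data.frame(gene_id = dup$gene_id, class_label = "C"))
  expect_equal(class_ratio_of_means(dup, clsd, "dog", "C")$ratio_of_means, r1)
  # equal dS: conventions coincide exactly
  esteq <- do.call(rbind, lapply(seq_len(10), function(i) {
    est_row(sprintf("h%02d", i), "dog", runif(1, 0, 0.2), 0.15)
  }))
  clse <- gene_class_map(data.frame(gene_id = esteq$gene_id,
                                    class_label = "E"))
  roweq <- class_ratio_of_means(esteq, clse, "dog", "E")
  expect_equal(roweq$ratio_of_means, roweq$mean_of_ratios)
})

test_that("genes lacking the branch are excluded with counts, empty class warns", {
  est <- est_row("g1", "dog", 0.1, 0.2)
  row <- class_ratio_of_means(est, two_gene_classes, "dog", "C")
  expect_identical(row$n_genes, 1L)
  expect_identical(row$n_excluded, 1L)
  expect_warning(class_ratio_of_means(est, two_gene_classes, "dog", "ZZZ"),
                 "empty")
})

test_that("bootstrap CI is seeded, contains the point estimate, and shrinks with n", {
  make_est <- function(n, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n), function(i) {
      est_row(sprintf("g%03d", i), "dog", rlnorm(1, log(0.05), 0.5),
              rlnorm(1, log(0.15), 0.5))
    }))
  }
  est <- make_est(50, 1)
  cls <- gene_class_map(data.frame(gene_id = est$gene_id, class_label = "C"))
  ci <- ratio_of_means_ci(est, cls, "dog", "C", B = 500, seed = 3)
  ci2 <- ratio_of_means_ci(est, cls, "dog", "C", B = 500, seed = 3)
  expect_identical(ci, ci2)
  expect_lte(ci$low, ci$point)
  expect_gte(ci$high, ci$point)
  # identical genes: zero-width CI at the point estimate
  estid <- do.call(rbind, lapply(1:8, function(i) {
    est_row(sprintf("i%d", i), "dog", 0.1, 0.2)
  }))
  clid <- gene_class_map(data.frame(gene_id = estid$gene_id,
                                    class_label = "I"))
  cid <- ratio_of_means_ci(estid, clid, "dog", "I", B = 200, seed = 1)
  expect_equal(cid$low, 0.5)
  expect_equal(cid$high, 0.5)
  # width shrinks roughly like 1/sqrt(n)
  big <- make_est(200, 2)
  clb <- gene_class_map(data.frame(gene_id = big$gene_id, class_label = "C"))
  cib <- ratio_of_means_ci(big, clb, "dog", "C", B = 500, seed = 3)
  small <- make_est(50, 2)
  cls2 <- gene_class_map(data.frame(gene_id = small$gene_id,
                                    class_label = "C"))
  cis <- ratio_of_means_ci(small, cls2, "dog", "C", B = 500, seed = 3)
  expect_lt(cib$high - cib$low, cis$high - cis$low)
  expect_error(ratio_of_means_ci(est, cls, "dog", "C", B = 50), ">= 100")
})

test_that("contrasts handle identical groups, separated groups and Bonferroni", {
  omega_tbl <- rbind(
    data.frame(gene_id = paste0("g", 1:3), lineage = "dog",
               omega = c(0.1, 0.1, 0.1), dS = 0.2),
    data.frame(gene_id = paste0("g", 1:3), lineage = "cat",
               omega = c(0.1, 0.1, 0.1), dS = 0.2),
    data.frame(gene_id = paste0("g", 1:3), lineage = "rat",
               omega = c(0.5, 0.5, 0.5), dS = 0.2))
  cls <- gene_class_map(data.frame(gene_id = rep(paste0("g", 1:3), 1L),
                                   class_label = "C"))
  ct <- lineage_contrasts(omega_tbl, cls, "C")
  expect_identical(attr(ct, "n_pairs"), 3)
  idr <- ct[ct$lineage_a == "cat" & ct$lineage_b == "dog", ]
  expect_equal(idr$F_statistic, 0)
  expect_equal(idr$p_raw, 1)
  expect_equal(idr$p_bonferroni, 1)
  sep <- ct[ct$lineage_a == "dog" & ct$lineage_b == "rat", ]
  expect_lt(sep$p_bonferroni, 1e-10)   # zero within-group variance
  # Bonferroni never below raw, capped at 1
  tst <- ct[ct$status == "TESTED", ]
  expect_true(all(tst$p_bonferroni >= tst$p_raw))
  expect_true(all(tst$p_bonferroni[tst$p_raw >= 1 / attr(ct, "n_pairs")] == 1))
})

test_that("low-dS genes are excluded and thin lineages are NOT_TESTED", {
  omega_tbl <- rbind(
    data.frame(gene_id = paste0("g", 1:4), lineage = "dog",
               omega = c(0.2, 0.3, 0.25, 0.22), dS = c(0.2, 0.2, 0.2, 1e-9)),
    data.frame(gene_id = paste0("g", 1:4), lineage = "cat",
               omega = c(0.2, 0.3, 0.25, 0.21), dS = 0.2),
    data.frame(gene_id = "g1", lineage = "rat", omega = 0.2, dS = 0.2))
  cls <- gene_class_map(data.frame(gene_id = paste0("g", 1:4),
                                   class_label = "C"))
  ct <- lineage_contrasts(omega_tbl, cls, "C")
  expect_identical(attr(ct, "n_excluded"), 1L)
  dogcat <- ct[ct$lineage_a == "cat" & ct$lineage_b == "dog", ]
  expect_identical(dogcat$n_b, 3L)     # the dS floor removed one dog gene
  ratrows <- ct[ct$lineage_a == "rat" | ct$lineage_b == "rat", ]
  expect_true(all(ratrows$status == "NOT_TESTED"))
  # family size counts testable lineages only
  expect_identical(attr(ct, "n_pairs"), 1)
  m <- contrast_matrix(ct)
  expect_identical(dim(m), c(3L, 3L))
  expect_true(is.na(m["rat", "dog"]))
})
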