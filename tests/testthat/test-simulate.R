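test_that("fixture trees carry the documented tips, tags and lengths", {
  t6 <- fixture_tree("TEST_6")
  expect_identical(ape::Ntip(t6$phy), 6L)
  expect_true(all(t6$phy$edge.length > 0))
  rt <- read_species_tree(write_species_tree(t6))
  expect_true(ape::all.equal.phylo(t6$phy, rt$phy, use.edge.length = TRUE))
  p12 <- fixture_tree("PRIMATE_12")
  expect_identical(ape::Ntip(p12$phy), 12L)
  expect_length(p12$tags$CATARRHINI, 8L)
  f45 <- fixture_tree("FULL_45")
  expect_identical(ape::Ntip(f45$phy), 45L)
  expect_length(f45$tags$CATARRHINI, 8L)
  expect_setequal(f45$tags$CETACEA, c("killer_whale", "bottlenosed_dolphin"))
  # catarrhine tag covers exactly 8 terminal branches
  edges <- branchomega:::tag_edges(f45, f45$tags$CATARRHINI)
  term <- f45$phy$edge[edges, 2L] <= 45L
  expect_identical(sum(term), 8L)
  # tip names match the shipped species mapping
  map <- utils::read.delim(system.file("extdata", "full45_species.tsv",
                                       package = "branchomega"))
  expect_setequal(f45$phy$tip.label, map$tip_name)
  expect_identical(nrow(map), 45L)
  expect_true(all(f45$phy$edge.length >= 0.01 & f45$phy$edge.length <= 0.3))
})

test_that("zero-length branches copy the root state everywhere", {
  tw <- read_species_tree("((a:0,b:0):0,c:0);")
  sim <- simulate_codon_alignment(sim_config(tw, n_codons = 30, seed = 2), "g")
  expect_identical(unname(sim$aln$rows[[1L]]), unname(sim$aln$rows[[2L]]))
  expect_identical(unname(sim$aln$rows[[1L]]), unname(sim$aln$rows[[3L]]))
  expect_true(all(sim$truth$subs_per_branch == 0L))
})

test_that("identical seeds reproduce byte-identical output, different seeds differ", {
  tr <- fixture_tree("TEST_6")
  s1 <- simulate_codon_alignment(sim_config(tr, n_codons = 50, seed = 33), "g")
  s2 <- simulate_codon_alignment(sim_config(tr, n_codons = 50, seed = 33), "g")
  s3 <- simulate_codon_alignment(sim_config(tr, n_codons = 50, seed = 34), "g")
  expect_identical(s1$aln$rows, s2$aln$rows)
  expect_false(identical(s1$aln$rows, s3$aln$rows))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_gene_fasta(s1$aln$rows, f1)
  write_gene_fasta(s2$aln$rows, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("realized substitution rate tracks branch length at low divergence", {
  tw <- read_species_tree("(a:0.05,(b:0.15,c:0.3):0.1);")
  reps <- lapply(1:10, function(i) {
    simulate_codon_alignment(sim_config(tw, n_codons = 1500, seed = 300L + i),
                             "g")$truth
  })
  t_e <- reps[[1L]]$edge_length
  mean_subs <- Reduce(`+`, lapply(reps, `[[`, "subs_per_branch")) / 10
  # observed changes per codon within 10% of t (multiple hits mildly deflate)
  obs <- mean_subs / 1500
  expect_true(all(abs(obs - t_e) / t_e < 0.10))
})

test_that("simulated codon frequencies converge to pi", {
  tw <- read_species_tree("(a:0.1,b:0.1);")
  sim <- simulate_codon_alignment(sim_config(tw, n_codons = 50000, seed = 12),
                                  "g")
  counts <- table(factor(substring(sim$aln$rows[[1L]],
                                   seq(1, 150000, 3), seq(3, 150000, 3)),
                         levels = genetic_code()$sense_codons))
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("NG86 on a neutral simulated pair recovers omega = 1", {
  tw <- read_species_tree("(a:0.1,b:0.1);")
  sim <- simulate_codon_alignment(
    sim_config(tw, kappa = 1, n_codons = 10000,
               omega_by_tag = list(default = 1), seed = 44), "g")
  r <- ng86_pairwise(sim$aln$rows[[1L]], sim$aln$rows[[2L]])
  expect_gt(r$omega, 0.93)
  expect_lt(r$omega, 1.07)
})

test_that("tagged branches evolve under their own omega", {
  tr <- fixture_tree("TEST_6")
  cfg <- sim_config(tr, n_codons = 200,
                    omega_by_tag = list(default = 0.1, CATARRHINI = 0.8),
                    seed = 71)
  omega_e <- branchomega:::sim_edge_omega(cfg)
  phy <- cfg$tree$phy
  tipname <- ifelse(phy$edge[, 2L] <= 6L, phy$tip.label[phy$edge[, 2L]], NA)
  expect_true(all(omega_e[tipname %in% c("human", "chimpanzee",
                                         "macaque")] == 0.8, na.rm = TRUE))
  expect_true(all(omega_e[tipname %in% c("mouse", "rat", "dog")] == 0.1,
                  na.rm = TRUE))
})

test_that("the class generator writes a consistent, replayable bundle", {
  tr <- fixture_tree("TEST_6")
  spec <- class_sim_spec(
    classes = list(
      list(label = "cons", n_genes = 3L,
           omega_by_tag = list(default = 0.05), length_codons = 30L),
      list(label = "elev", n_genes = 2L,
           omega_by_tag = list(default = 0.1, CATARRHINI = 0.4),
           length_codons = c(30L, 60L))),
    outlier_injections = list(list(class = "cons", species = "chimpanzee",
                                   ds_multiplier = 10, n_genes = 1L)))
  out <- withr::local_tempdir()
  b1 <- generate_gene_classes(spec, sim_config(tr, n_codons = 30, seed = 9),
                              out_dir = out)
  expect_length(b1$genes, 5L)
  cc <- class_counts(b1$classes)
  expect_identical(cc[["cons"]], 3L)
  expect_identical(cc[["elev"]], 2L)
  expect_true(file.exists(file.path(out, "classes.tsv")))
  expect_true(file.exists(file.path(out, "tree.nwk")))
  expect_true(file.exists(file.path(out, "truth.json")))
  expect_length(list.files(file.path(out, "genes")), 5L)
  # truth echoes the generator's spec: classes and counts agree
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_length(truth$genes, 5L)
  expect_length(truth$injections, 1L)
  expect_identical(truth$injections[[1L]]$species, "chimpanzee")
  # replay: same base seed, identical sequences
  b2 <- generate_gene_classes(spec, sim_config(tr, n_codons = 30, seed = 9))
  expect_identical(lapply(b1$genes, `[[`, "rows"),
                   lapply(b2$genes, `[[`, "rows"))
  # the injected outlier is dramatically diverged from human
  inj_gene <- truth$injections[[1L]]$gene_id
  tab <- ds_to_reference(b1$genes[inj_gene], "human")
  expect_gt(tab$ds[tab$species == "chimpanzee"],
            3 * max(tab$ds[tab$species == "macaque"]))
  expect_error(
    class_sim_spec(list(list(label = "a", n_genes = 1L),
                        list(label = "a", n_genes = 1L))), "duplicate")
})
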