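# Codon sequence simulator: the generative mirror of the GY94 likelihood
# model, with branch-tag-specific omega, gene classes of differing
# constraint and optional planted dS-outlier orthologs for QC testing.

#' Simulation configuration
#'
#' @param tree A [species_tree()] whose `phy` carries branch lengths
#'   (expected substitutions per codon).
#' @param kappa Transition/transversion rate ratio.
#' @param pi Sense-codon frequencies (`"uniform"` for equal frequencies, or
#'   a numeric vector over the package codon order).
#' @param omega_by_tag Named list of omega values; `default` covers
#'   untagged branches, any other name must be a branch tag of the tree and
#'   covers that tag's branches (terminal, internal and stem).
#' @param n_codons Alignment length in codons.
#' @param seed Mandatory RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(tree, kappa = 2, pi = "uniform",
                       omega_by_tag = list(default = 0.2),
                       n_codons = 300L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(tree, "species_tree"))
  if (is.null(tree$phy$edge.length)) stop("simulation tree needs branch lengths")
  if (any(tree$phy$edge.length < 0)) stop("negative branch length")
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (is.null(omega_by_tag$default)) stop("omega_by_tag needs a 'default' entry")
  extra <- setdiff(names(omega_by_tag), c("default", names(tree$tags)))
  if (length(extra) > 0L) {
    stop("omega_by_tag names not among tree tags: ",
         paste(extra, collapse = ", "))
  }
  structure(list(tree = tree, kappa = kappa, pi = pi,
                 omega_by_tag = omega_by_tag,
                 n_codons = as.integer(n_codons), seed = as.integer(seed)),
            class = "sim_config")
}

sim_pi <- function(cfg, code = genetic_code()) {
  if (identical(cfg$pi, "uniform")) {
    rep(1 / length(code$sense_codons), length(code$sense_codons))
  } else {
    stopifnot(length(cfg$pi) == length(code$sense_codons))
    cfg$pi / sum(cfg$pi)
  }
}

# omega per edge of the (rooted, cladewise) simulation tree; later tags in
# omega_by_tag win where tags overlap.
sim_edge_omega <- function(cfg) {
  phy <- cfg$tree$phy
  omega <- rep(cfg$omega_by_tag$default, nrow(phy$edge))
  for (tg in setdiff(names(cfg$omega_by_tag), "default")) {
    omega[tag_edges(cfg$tree, cfg$tree$tags[[tg]])] <- cfg$omega_by_tag[[tg]]
  }
  omega
}

# Evolve states along one branch by simulating the jump chain of the CTMC
# (exact: waiting times are exponential with the state's total exit rate,
# jumps follow the off-diagonal rates). Returns the endpoint states and the
# realized number of substitution events, which is therefore a true event
# count rather than an endpoint-difference count.
evolve_states <- function(parent, Q, t) {
  child <- parent
  exit <- -diag(Q)
  remaining <- rep(t, length(parent))
  active <- seq_along(parent)
  nsub <- 0L
  while (length(active) > 0L) {
    w <- stats::rexp(length(active), rate = pmax(exit[child[active]], 1e-300))
    jump <- active[w < remaining[active]]
    remaining[jump] <- remaining[jump] - w[w < remaining[active]]
    if (length(jump) > 0L) {
      from <- child[jump]            # freeze: one event per site per round
      for (s in unique(from)) {
        at <- jump[from == s]
        probs <- Q[s, ]
        probs[s] <- 0
        child[at] <- sample.int(ncol(Q), length(at), replace = TRUE,
                                prob = probs)
      }
      nsub <- nsub + length(jump)
    }
    active <- jump
  }
  list(states = child, nsub = nsub)
}

#' Simulate a codon alignment along the species tree
#'
#' Root codons are drawn from the stationary frequencies; each branch
#' evolves every site under the GY94 generator for that branch's
#' (kappa, omega) over duration t, by exact jump-chain simulation, so the
#' endpoint distribution matches the model's transition probabilities and
#' the recorded substitution counts are true event counts. The output is
#' gap-free with exactly `n_codons` columns; identical seeds give
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @param gene_id Gene identifier for the returned alignment.
#' @param code A [genetic_code()].
#' @return List with `aln` (a [codon_alignment()]) and `truth`: the config
#'   echo plus `edge_omega`, realized per-branch substitution counts
#'   (`subs_per_branch`), and internal-node states (`node_states`,
#'   rows = nodes) sufficient to replay or extend the simulation.
#' @export
simulate_codon_alignment <- function(cfg, gene_id = "gene",
                                     code = genetic_code()) {
  phy <- ape::reorder.phylo(cfg$tree$phy, "cladewise") # parents before kids
  cfg$tree$phy <- phy
  pi <- sim_pi(cfg, code)
  omega_e <- sim_edge_omega(cfg)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- ntip + 1L
  rng <- local_rng(cfg$seed)
  on.exit(restore_rng(rng))
  states <- matrix(0L, nrow = ntip + nnode, ncol = cfg$n_codons)
  states[root, ] <- sample.int(length(pi), cfg$n_codons, replace = TRUE,
                               prob = pi)
  subs <- integer(nrow(phy$edge))
  Qs <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(phy$edge))) {
    key <- sprintf("%.14g", omega_e[e])
    if (is.null(Qs[[key]])) {
      Qs[[key]] <- codon_rate_matrix(cfg$kappa, omega_e[e], pi, code)
    }
    parent <- states[phy$edge[e, 1L], ]
    ev <- evolve_states(parent, Qs[[key]], phy$edge.length[e])
    states[phy$edge[e, 2L], ] <- ev$states
    subs[e] <- ev$nsub
  }
  rows <- vapply(seq_len(ntip), function(i) {
    paste0(code$sense_codons[states[i, ]], collapse = "")
  }, "")
  names(rows) <- phy$tip.label
  aln <- codon_alignment(rows, gene_id)
  truth <- list(gene_id = gene_id, kappa = cfg$kappa,
                omega_by_tag = cfg$omega_by_tag, n_codons = cfg$n_codons,
                seed = cfg$seed, pi = pi, edge_omega = omega_e,
                edge_length = phy$edge.length, subs_per_branch = subs,
                node_states = states, phy = phy, tags = cfg$tree$tags)
  list(aln = aln, truth = truth)
}

#' Class simulation specification
#'
#' @param classes List of class descriptors, each a list with `label`,
#'   `n_genes`, `omega_by_tag`, and optionally `length_codons` (vector of
#'   codon counts sampled uniformly per gene; default 300).
#' @param outlier_injections Optional list of planted QC outliers, each a
#'   list with `class`, `species`, `ds_multiplier`, `n_genes`: in that many
#'   genes of the class, the species' sequence is replaced by one evolved
#'   from its ancestral node along a branch elongated by `ds_multiplier`
#'   (elevated dS with proportionally elevated dN — biologically shaped,
#'   unlike a shuffled decoy).
#' @return Object of class `class_sim_spec`.
#' @export
class_sim_spec <- function(classes, outlier_injections = list()) {
  labels <- vapply(classes, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate class labels")
  for (inj in outlier_injections) {
    if (!inj$class %in% labels) stop("injection names unknown class: ",
                                     inj$class)
  }
  structure(list(classes = classes, outlier_injections = outlier_injections),
            class = "class_sim_spec")
}

#' Generate a synthetic multi-class ortholog dataset
#'
#' Simulates `n_genes` codon alignments per class under that class's
#' branch-tag omega regime on the base config's tree, applies any planted
#' dS-outlier injections, and (optionally) writes the standard pipeline
#' input bundle: `genes/<gene_id>.fasta`, `classes.tsv`, `tree.nwk`,
#' `truth.json`, `manifest.tsv`.
#'
#' @param spec A [class_sim_spec()].
#' @param cfg_base A [sim_config()] providing tree, kappa, pi and seed
#'   (per-gene seeds are derived from it deterministically).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param code A [genetic_code()].
#' @return List with `genes` (named list of [codon_alignment()]),
#'   `classes` (a `gene_class_map`), `tree`, `truth` (per-gene generating
#'   parameters incl. seeds and injected outliers).
#' @export
generate_gene_classes <- function(spec, cfg_base, out_dir = NULL,
                                  code = genetic_code()) {
  stopifnot(inherits(spec, "class_sim_spec"), inherits(cfg_base, "sim_config"))
  genes <- list()
  class_rows <- list()
  truth_genes <- list()
  injections_done <- list()
  gene_no <- 0L
  rng <- local_rng(cfg_base$seed)
  on.exit(restore_rng(rng))
  # pre-draw per-gene lengths and injection targets so gene simulation seeds
  # stay decoupled from these choices
  plan <- list()
  for (cl in spec$classes) {
    lens <- cl$length_codons
    if (is.null(lens)) lens <- 300L
    drawn <- if (length(lens) == 1L) rep(lens, cl$n_genes) else
      sample(lens, cl$n_genes, replace = TRUE)
    for (g in seq_len(cl$n_genes)) {
      gene_no <- gene_no + 1L
      plan[[gene_no]] <- list(
        gene_id = sprintf("%s_g%03d", tolower(cl$label), g),
        label = cl$label, omega_by_tag = cl$omega_by_tag,
        n_codons = as.integer(drawn[g]),
        seed = (cfg_base$seed + 7919L * gene_no) %% .Machine$integer.max)
    }
  }
  ids <- vapply(plan, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("overlapping gene ids in simulation plan")
  inj_targets <- list()
  for (inj in spec$outlier_injections) {
    of_class <- which(vapply(plan, `[[`, "", "label") == inj$class)
    pick <- sort(sample(of_class, min(inj$n_genes, length(of_class))))
    for (k in pick) {
      inj_targets[[length(inj_targets) + 1L]] <-
        list(gene_idx = k, species = inj$species,
             ds_multiplier = inj$ds_multiplier)
    }
  }
  for (k in seq_along(plan)) {
    pl <- plan[[k]]
    cfg <- sim_config(cfg_base$tree, cfg_base$kappa, cfg_base$pi,
                      pl$omega_by_tag, pl$n_codons, pl$seed)
    sim <- simulate_codon_alignment(cfg, pl$gene_id, code)
    genes[[pl$gene_id]] <- sim$aln
    class_rows[[k]] <- data.frame(gene_id = pl$gene_id,
                                  class_label = pl$label,
                                  stringsAsFactors = FALSE)
    truth_genes[[pl$gene_id]] <- list(
      gene_id = pl$gene_id, class_label = pl$label, seed = pl$seed,
      n_codons = pl$n_codons, omega_by_tag = pl$omega_by_tag,
      subs_per_branch = sim$truth$subs_per_branch)
    for (inj in inj_targets) {
      if (inj$gene_idx != k) next
      genes[[pl$gene_id]] <- inject_ds_outlier(
        genes[[pl$gene_id]], sim$truth, inj$species, inj$ds_multiplier,
        seed = (pl$seed + 104729L) %% .Machine$integer.max, code = code)
      injections_done[[length(injections_done) + 1L]] <-
        list(gene_id = pl$gene_id, species = inj$species,
             ds_multiplier = inj$ds_multiplier)
    }
  }
  classes <- gene_class_map(do.call(rbind, class_rows))
  truth <- list(base_seed = cfg_base$seed, kappa = cfg_base$kappa,
                tree_newick = write_species_tree(cfg_base$tree),
                tags = cfg_base$tree$tags, genes = truth_genes,
                injections = injections_done)
  bundle <- list(genes = genes, classes = classes, tree = cfg_base$tree,
                 truth = truth)
  if (!is.null(out_dir)) write_sim_bundle(bundle, out_dir)
  bundle
}

# Replace `species`' sequence by one re-evolved from its ancestral node
# along a branch elongated ds_multiplier-fold (same kappa/omega regime).
inject_ds_outlier <- function(aln, truth, species, ds_multiplier, seed,
                              code = genetic_code()) {
  phy <- truth$phy
  tipno <- match(species, phy$tip.label)
  if (is.na(tipno)) stop("injection species not in tree: ", species)
  e <- which(phy$edge[, 2L] == tipno)
  parent_states <- truth$node_states[phy$edge[e, 1L], ]
  Q <- codon_rate_matrix(truth$kappa, truth$edge_omega[e], truth$pi, code)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  ev <- evolve_states(parent_states, Q, truth$edge_length[e] * ds_multiplier)
  aln$rows[[match(species, aln$species)]] <-
    paste0(code$sense_codons[ev$states], collapse = "")
  aln
}

write_sim_bundle <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "genes"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in names(bundle$genes)) {
    write_gene_fasta(bundle$genes[[g]]$rows,
                     file.path(out_dir, "genes", paste0(g, ".fasta")))
  }
  utils::write.table(bundle$classes, file.path(out_dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_species_tree(bundle$tree, file.path(out_dir, "tree.nwk"))
  truth <- bundle$truth
  truth$genes <- lapply(truth$genes, function(g) {
    g$subs_per_branch <- as.integer(g$subs_per_branch); g
  })
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(
    gene_id = names(bundle$genes),
    file = file.path("genes", paste0(names(bundle$genes), ".fasta")),
    n_species = vapply(bundle$genes, function(a) length(a$species),
                       integer(1L)),
    n_codons = vapply(bundle$genes, n_codon_columns, integer(1L)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Fixture species trees
#'
#' Shipped topologies with synthetic branch lengths in the low-divergence
#' regime (terminal branches 0.02-0.3, internal 0.01-0.12 expected
#' substitutions per codon) where counting and ML estimates agree well.
#'
#' * `TEST_6` - human, chimpanzee, macaque (tagged `CATARRHINI`), mouse,
#'   rat (tagged `SCIUROGNATHI`), dog: the smallest tree exercising a
#'   catarrhine/sciurognath contrast.
#' * `PRIMATE_12` - the eleven primates plus mouse as outgroup;
#'   `CATARRHINI` covers the eight apes and old-world monkeys.
#' * `FULL_45` - the 45-taxon mammal tree (snake_case common names;
#'   the tip-name-to-binomial mapping ships in
#'   `inst/extdata/full45_species.tsv`), `CATARRHINI` and `CETACEA`
#'   tagged, plus `SCIUROGNATHI` for the rodent contrast set.
#'
#' @param which Fixture name.
#' @return A [species_tree()] with branch lengths and tags.
#' @export
fixture_tree <- function(which = c("TEST_6", "PRIMATE_12", "FULL_45")) {
  which <- match.arg(which)
  if (which == "TEST_6") {
    nwk <- paste0("(((human:0.06,chimpanzee:0.06):0.04,macaque:0.09):0.10,",
                  "((mouse:0.16,rat:0.16):0.10,dog:0.22):0.04);")
    return(read_species_tree(nwk, tags = list(
      CATARRHINI = c("human", "chimpanzee", "macaque"),
      SCIUROGNATHI = c("mouse", "rat"))))
  }
  if (which == "PRIMATE_12") {
    nwk <- paste0(
      "((galago:0.20,((squirrel_monkey:0.07,marmoset:0.07):0.08,",
      "((macaque:0.04,baboon:0.04):0.05,(gibbon:0.07,(orangutan:0.05,",
      "(gorilla:0.03,(human:0.02,(chimpanzee:0.015,bonobo:0.015):0.01):0.01",
      "):0.015):0.02):0.02):0.06):0.05):0.10,mouse:0.30);")
    return(read_species_tree(nwk, tags = list(
      CATARRHINI = c("macaque", "baboon", "gibbon", "orangutan", "gorilla",
                     "human", "chimpanzee", "bonobo"),
      SCIUROGNATHI = "mouse")))
  }
  full45_tree()
}

full45_tree <- function() {
  # nested per NCBI-taxonomy-style mammal relationships; internal branches
  # 0.01-0.08, terminals 0.02-0.30 (synthetic)
  primates <- paste0(
    "(small_eared_galago:0.15,((bolivian_squirrel_monkey:0.08,",
    "white_tufted_ear_marmoset:0.08):0.05,((rhesus_macaque:0.05,",
    "olive_baboon:0.05):0.04,(northern_white_cheeked_gibbon:0.06,",
    "(sumatran_orangutan:0.05,(western_lowland_gorilla:0.03,(human:0.02,",
    "(chimpanzee:0.02,bonobo:0.02):0.01):0.01):0.02):0.02):0.02):0.04):0.04)",
    ":0.04")
  rodents <- paste0(
    "((naked_mole_rat:0.12,(guinea_pig:0.10,(degu:0.10,",
    "long_tailed_chinchilla:0.10):0.03):0.03):0.04,",
    "(thirteen_lined_ground_squirrel:0.12,(lesser_egyptian_jerboa:0.14,",
    "((prairie_vole:0.10,(golden_hamster:0.08,chinese_hamster:0.08):0.03)",
    ":0.04,(rat:0.09,mouse:0.09):0.05):0.04):0.03):0.03):0.04")
  glires <- paste0("((rabbit:0.10,american_pika:0.12):0.05,", rodents, "):0.03")
  euarch <- paste0("(", glires, ",", primates, "):0.03")
  cetartio <- paste0(
    "(pig:0.10,((cow:0.08,sheep:0.08):0.04,(killer_whale:0.05,",
    "bottlenosed_dolphin:0.05):0.06):0.03):0.04")
  carnivora <- paste0(
    "(cat:0.09,(dog:0.09,(giant_panda:0.08,(ferret:0.09,",
    "pacific_walrus:0.08):0.02):0.02):0.02):0.04")
  laurasia <- paste0(
    "((star_nosed_mole:0.14,european_shrew:0.16):0.05,((horse:0.08,",
    "southern_white_rhinoceros:0.08):0.04,(", cetartio, ",", carnivora,
    "):0.02):0.02):0.03")
  boreo <- paste0("(", laurasia, ",", euarch, "):0.03")
  afro <- paste0(
    "(small_madagascar_hedgehog:0.16,(african_savanna_elephant:0.10,",
    "florida_manatee:0.10):0.04):0.04")
  eutheria <- paste0("(nine_banded_armadillo:0.14,(", afro, ",", boreo,
                     "):0.02):0.03")
  marsupials <- "(gray_short_tailed_opossum:0.18,tasmanian_devil:0.18):0.08"
  nwk <- paste0("(platypus:0.30,(", marsupials, ",", eutheria, "):0.05);")
  read_species_tree(nwk, tags = list(
    CATARRHINI = c("rhesus_macaque", "olive_baboon",
                   "northern_white_cheeked_gibbon", "sumatran_orangutan",
                   "western_lowland_gorilla", "human", "chimpanzee",
                   "bonobo"),
    CETACEA = c("killer_whale", "bottlenosed_dolphin"),
    SCIUROGNATHI = c("thirteen_lined_ground_squirrel",
                     "lesser_egyptian_jerboa", "prairie_vole",
                     "golden_hamster", "chinese_hamster", "rat", "mouse")))
}
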