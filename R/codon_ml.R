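# Maximum-likelihood dN/dS on a species tree under the GY94 codon model:
# single-ratio, foreground/background branch models and free-ratio, fitted
# per gene with Felsenstein pruning (compiled core) and bounded
# quasi-Newton optimisation.

#' Codon model specification
#'
#' The four model configurations run per gene: one dN/dS for all branches
#' (`SINGLE_RATIO`); a branch model contrasting catarrhine branches with
#' all others (`BRANCH_CATARRHINE`); a branch model with catarrhine and
#' cetacean branches as joint foreground (`BRANCH_CATARRHINE_CETACEAN`);
#' and an independent dN/dS on every branch (`FREE_RATIO`). A generic
#' `BRANCH` name with explicit `foreground_tags` covers custom contrasts.
#'
#' @param name Model name.
#' @param foreground_tags Branch tags (see [species_tree()]) forming the
#'   foreground omega class; defaults follow the model name.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = c("SINGLE_RATIO", "BRANCH_CATARRHINE",
                                "BRANCH_CATARRHINE_CETACEAN", "FREE_RATIO",
                                "BRANCH"),
                       foreground_tags = NULL) {
  name <- match.arg(name)
  if (is.null(foreground_tags)) {
    foreground_tags <- switch(name,
      BRANCH_CATARRHINE = "CATARRHINI",
      BRANCH_CATARRHINE_CETACEAN = c("CATARRHINI", "CETACEA"),
      BRANCH = stop("model BRANCH requires explicit foreground_tags"),
      character(0L))
  }
  structure(list(name = name, foreground_tags = foreground_tags),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name)
  if (length(x$foreground_tags) > 0L) {
    cat(" [fg:", paste(x$foreground_tags, collapse = "+"), "]")
  }
  cat("\n")
  invisible(x)
}

is_branch_model <- function(spec) {
  spec$name %in% c("BRANCH_CATARRHINE", "BRANCH_CATARRHINE_CETACEAN", "BRANCH")
}

# Prepare a (tree, alignment) pair for likelihood work: prune the tree to
# the alignment's species, optionally unroot (the model is reversible, so
# the root placement is arbitrary; unrooting removes the unidentifiable
# root-edge split), reorder postorder, and derive the omega class of every
# edge under the model spec.
prepare_codon_tree <- function(aln, tree, spec, unroot = TRUE) {
  missing <- setdiff(aln$species, tree$phy$tip.label)
  if (length(missing) > 0L) {
    stop("alignment species absent from tree: ",
         paste(missing, collapse = ", "))
  }
  full_tips <- length(tree$phy$tip.label)
  if (length(aln$species) < full_tips) {
    tree <- prune_species_tree(tree, aln$species)
  }
  phy <- tree$phy
  if (unroot && length(phy$tip.label) >= 3L) phy <- ape::unroot(phy)
  phy <- ape::reorder.phylo(phy, "postorder")
  wtree <- species_tree(phy, tree$tags)
  nedge <- nrow(phy$edge)
  edge_class <- rep("all", nedge)
  if (is_branch_model(spec)) {
    fg <- unique(unlist(lapply(spec$foreground_tags, function(tg) {
      tag_edges(wtree, wtree$tags[[tg]])
    })))
    edge_class <- rep("background", nedge)
    edge_class[fg] <- "foreground"
  } else if (spec$name == "FREE_RATIO") {
    edge_class <- paste0("edge_", seq_len(nedge))
  }
  terminal <- phy$edge[, 2L] <= length(phy$tip.label)
  child_name <- ifelse(terminal, phy$tip.label[phy$edge[, 2L]],
                       paste0("node", phy$edge[, 2L]))
  list(tree = wtree, phy = phy, edge_class = edge_class,
       omega_classes = unique(edge_class), terminal = terminal,
       child_name = child_name,
       n_dropped_species = full_tips - length(phy$tip.label))
}

compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(states = states[, first, drop = FALSE], weights = w)
}

# Bounded eigensystem cache (per fit): avoids recomputing the 61x61
# decomposition when only branch lengths move during optimisation.
eigen_cache <- function(maxsize = 64L) {
  env <- new.env(parent = emptyenv())
  env$map <- list()
  env$maxsize <- maxsize
  env
}

cached_eigen <- function(cache, kappa, omega, pi, code) {
  key <- sprintf("%.14g_%.14g", kappa, omega)
  hit <- cache$map[[key]]
  if (!is.null(hit)) return(hit)
  eg <- gy94_eigen(kappa, omega, pi, code)
  cache$map[[key]] <- eg
  if (length(cache$map) > cache$maxsize) {
    cache$map <- cache$map[-1L]
  }
  eg
}

# Core likelihood: builds the per-edge transition-matrix cube and calls the
# compiled pruning kernel.
codon_ml_core <- function(prep, states_pat, weights, kappa, omega_by_class,
                          pi, t_edges, cache = NULL,
                          code = genetic_code()) {
  ns <- length(pi)
  nedge <- nrow(prep$phy$edge)
  P <- array(0, c(ns, ns, nedge))
  if (is.null(cache)) cache <- eigen_cache()
  for (cls in prep$omega_classes) {
    eg <- cached_eigen(cache, kappa, omega_by_class[[cls]], pi, code)
    for (e in which(prep$edge_class == cls)) {
      et <- exp(eg$d * t_edges[e])
      Pe <- eg$U %*% (et * eg$Vt)
      Pe[Pe < 0] <- 0
      P[, , e] <- Pe
    }
  }
  prune_loglik_cpp(prep$phy$edge, length(prep$phy$tip.label), P, list(),
                   states_pat, pi, weights, FALSE)
}

#' Log-likelihood of a codon alignment under a GY94 model
#'
#' Felsenstein pruning over codon columns with per-pattern scaling; gap or
#' ambiguous codons contribute all-ones partial likelihoods (missing data);
#' the root is weighted by the stationary frequencies. The tree is used as
#' given (rooted trees are fine: the model is reversible).
#'
#' @param aln A [codon_alignment()].
#' @param tree A [species_tree()]; extra tips are pruned away, missing tips
#'   are an error.
#' @param params List with `kappa`, `omega` (scalar, or named vector over
#'   the spec's omega classes), `pi` (sense-codon frequencies; default
#'   F3x4 from the alignment), `branch_lengths` (per edge of `tree$phy`;
#'   default the tree's own lengths).
#' @param spec A [model_spec()].
#' @param code A [genetic_code()].
#' @return Log-likelihood (numeric scalar).
#' @export
codon_loglik <- function(aln, tree, params, spec = model_spec("SINGLE_RATIO"),
                         code = genetic_code()) {
  if (!is.null(params$branch_lengths)) {
    tree$phy$edge.length <- params$branch_lengths
  }
  if (is.null(tree$phy$edge.length)) {
    stop("tree has no branch lengths and none were supplied")
  }
  prep <- prepare_codon_tree(aln, tree, spec, unroot = FALSE)
  pi <- if (!is.null(params$pi)) params$pi else f3x4_frequencies(aln, code = code)
  omega <- params$omega
  if (is.null(names(omega))) {
    omega <- stats::setNames(rep(omega, length(prep$omega_classes)),
                             prep$omega_classes)
  }
  states <- codon_state_matrix(aln, code)[prep$phy$tip.label, , drop = FALSE]
  pat <- compress_patterns(states)
  res <- codon_ml_core(prep, pat$states, pat$weights, params$kappa,
                       as.list(omega), pi, prep$phy$edge.length,
                       code = code)
  res$loglik
}

#' Fit a codon model by maximum likelihood
#'
#' Maximises the pruning likelihood over kappa, the spec's omega classes
#' and all branch lengths (estimated per gene; the species tree supplies
#' topology only). Optimisation is bounded quasi-Newton (`L-BFGS-B`) on
#' log-transformed parameters with analytic branch-length gradients and
#' central-difference gradients for kappa/omega, multi-started from a
#' heuristic initial point plus seeded random restarts. Bounds:
#' kappa in \[0.01, 100\], omega in \[1e-4, 20\], t in \[1e-6, 50\].
#'
#' @param aln A [codon_alignment()].
#' @param tree A [species_tree()] carrying the branch tags the spec needs.
#' @param spec A [model_spec()].
#' @param opts Optimiser settings: `n_starts` (default 3), `seed` (default
#'   1), `maxit` (default 300), `factr` (default 1e7, roughly 1e-6 relative
#'   tolerance on lnL), `freq` (`"F3x4"` default, `"F1x4"`, `"equal"`),
#'   `init` (a previous `model_fit` on the same gene, used as first start;
#'   fitting a general model from its nested restriction's optimum also
#'   guarantees lnL monotonicity across nested fits).
#' @param code A [genetic_code()].
#' @return Object of class `model_fit`: list with `spec`, `lnL`, `kappa`,
#'   `omega` (named per class), `pi`, `t` (per postorder edge), `prep`
#'   (prepared tree with edge classes), `converged`, `n_starts_used`,
#'   `gene_id`, `n_codons`.
#' @export
fit_codon_model <- function(aln, tree, spec = model_spec("SINGLE_RATIO"),
                            opts = list(), code = genetic_code()) {
  o <- utils::modifyList(list(n_starts = 3L, seed = 1L, maxit = 300L,
                              factr = 4.5e9, freq = "F3x4", init = NULL,
                              ndeps_h = 1e-4), opts)
  prep <- prepare_codon_tree(aln, tree, spec, unroot = TRUE)
  states <- codon_state_matrix(aln, code)[prep$phy$tip.label, , drop = FALSE]
  pat <- compress_patterns(states)
  pi <- f3x4_frequencies(aln, method = o$freq, code = code)
  nedge <- nrow(prep$phy$edge)
  classes <- prep$omega_classes
  ncls <- length(classes)
  cache <- eigen_cache()

  lb <- c(rep(log(1e-6), nedge), log(0.01), rep(log(1e-4), ncls))
  ub <- c(rep(log(50), nedge), log(100), rep(log(20), ncls))

  unpack <- function(theta) {
    list(t = exp(theta[seq_len(nedge)]),
         kappa = exp(theta[nedge + 1L]),
         omega = stats::setNames(as.list(exp(theta[nedge + 1L + seq_len(ncls)])),
                                 classes))
  }
  ns <- length(pi)
  edges_of <- lapply(classes, function(cl) which(prep$edge_class == cl))
  names(edges_of) <- classes
  ntip <- length(prep$phy$tip.label)
  # cubes are assembled inside one frame so slice assignment stays in place
  # (passing the array through helpers would trigger a full copy per call)
  nll <- function(theta) {
    p <- unpack(theta)
    P <- array(0, c(ns, ns, nedge))
    for (cl in classes) {
      eg <- cached_eigen(cache, p$kappa, p$omega[[cl]], pi, code)
      for (e in edges_of[[cl]]) {
        et <- exp(eg$d * p$t[e])
        Pe <- eg$U %*% (et * eg$Vt)
        Pe[Pe < 0] <- 0
        P[, , e] <- Pe
      }
    }
    -prune_loglik_cpp(prep$phy$edge, ntip, P, list(), pat$states, pi,
                      pat$weights, FALSE)$loglik
  }
  # analytic gradient: d lnL/dt via dP/dt = QP; d lnL/domega and d lnL/dkappa
  # via the Frechet derivative of expm in the shared eigenbasis
  ngr <- function(theta) {
    p <- unpack(theta)
    P <- array(0, c(ns, ns, nedge))
    Dt <- array(0, c(ns, ns, nedge))
    Dw <- array(0, c(ns, ns, nedge))
    Dk <- array(0, c(ns, ns, nedge))
    for (cl in classes) {
      eg <- cached_eigen(cache, p$kappa, p$omega[[cl]], pi, code)
      for (e in edges_of[[cl]]) {
        te <- p$t[e]
        ed <- exp(eg$d * te)
        Pe <- eg$U %*% (ed * eg$Vt)
        Pe[Pe < 0] <- 0
        P[, , e] <- Pe
        Dt[, , e] <- eg$U %*% ((eg$d * ed) * eg$Vt)
        G <- expm_frechet_gamma(eg$d, ed, te)
        Dw[, , e] <- eg$U %*% ((eg$Mw * G) %*% eg$Vt)
        Dk[, , e] <- eg$U %*% ((eg$Mk * G) %*% eg$Vt)
      }
    }
    res <- prune_loglik_cpp(prep$phy$edge, ntip, P, list(Dt, Dw, Dk),
                            pat$states, pi, pat$weights, TRUE)
    dth <- res$dtheta                 # nedge x 3: per-edge t, omega, kappa
    g <- numeric(length(theta))
    g[seq_len(nedge)] <- -dth[, 1L] * p$t       # chain rule to log t
    g[nedge + 1L] <- -sum(dth[, 3L]) * p$kappa  # kappa shared by all edges
    for (ci in seq_len(ncls)) {
      g[nedge + 1L + ci] <-
        -sum(dth[edges_of[[ci]], 2L]) * p$omega[[ci]]
    }
    g
  }

  t0 <- if (!is.null(prep$phy$edge.length)) {
    pmax(pmin(prep$phy$edge.length, 5), 0.01)
  } else rep(0.1, nedge)
  starts <- list(c(log(t0), log(2), rep(log(0.4), ncls)))
  if (!is.null(o$init)) {
    init <- o$init
    stopifnot(inherits(init, "model_fit"))
    om0 <- vapply(seq_len(nedge), function(e) {
      map_nested_omega(init, prep, e)
    }, numeric(1L))
    om_cls <- vapply(classes, function(cl) {
      stats::median(om0[prep$edge_class == cl])
    }, numeric(1L))
    starts <- c(list(c(log(pmax(init$t, 1e-6)), log(init$kappa),
                       log(pmax(om_cls, 1e-4)))), starts)
  }
  rng <- local_rng(o$seed)
  while (length(starts) < o$n_starts) {
    starts[[length(starts) + 1L]] <-
      c(log(t0 * exp(stats::runif(nedge, -0.7, 0.7))),
        log(stats::runif(1L, 1, 4)),
        log(stats::runif(ncls, 0.05, 1.5)))
  }
  restore_rng(rng)
  starts <- starts[seq_len(min(length(starts), max(o$n_starts, 1L)))]

  best <- NULL
  n_used <- 0L
  for (s in starts) {
    n_used <- n_used + 1L
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lb), ub), nll, ngr, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = o$maxit, factr = o$factr)),
      error = function(e) {
        warning("optimiser start failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, lnL = NA_real_, kappa = NA_real_,
                          omega = NULL, pi = pi, t = NULL, prep = prep,
                          converged = FALSE, n_starts_used = n_used,
                          gene_id = aln$gene_id,
                          n_codons = n_codon_columns(aln)),
                     class = "model_fit"))
  }
  p <- unpack(best$par)
  structure(list(spec = spec, lnL = -best$value, kappa = p$kappa,
                 omega = unlist(p$omega), pi = pi, t = p$t, prep = prep,
                 converged = best$convergence == 0L,
                 n_starts_used = n_used, gene_id = aln$gene_id,
                 n_codons = n_codon_columns(aln)),
            class = "model_fit")
}

# omega of edge e under a previously fitted (nested) model, matched by the
# edge's child clade so that fits chain across models on the same gene.
map_nested_omega <- function(init, prep, e) {
  if (length(init$omega) == 1L) return(init$omega[[1L]])
  if (init$spec$name == "FREE_RATIO" || length(init$omega) == 0L) {
    # match edge by child split where possible; fall back to median
    old_e <- match_edge(init$prep$phy, prep$phy, e)
    if (!is.na(old_e)) return(init$omega[[init$prep$edge_class[old_e]]])
    return(stats::median(unlist(init$omega)))
  }
  cls <- init$prep$edge_class[match_edge(init$prep$phy, prep$phy, e)]
  if (is.na(cls)) cls <- names(init$omega)[1L]
  init$omega[[cls]]
}

# find the edge of phy_old whose child clade (tip set) equals that of edge e
# in phy_new; NA if topologies differ.
match_edge <- function(phy_old, phy_new, e) {
  tipset <- function(phy, edge_row) {
    child <- phy$edge[edge_row, 2L]
    if (child <= length(phy$tip.label)) return(phy$tip.label[child])
    sort(phy$tip.label[intersect(clade_nodes(phy, child),
                                 seq_along(phy$tip.label))])
  }
  target <- tipset(phy_new, e)
  for (k in seq_len(nrow(phy_old$edge))) {
    if (identical(tipset(phy_old, k), target)) return(k)
  }
  NA_integer_
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>", x$spec$name, "gene", x$gene_id,
      sprintf("lnL=%.4f kappa=%.3f", x$lnL, x$kappa),
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  if (length(x$omega) <= 4L) {
    cat("  omega:", paste(sprintf("%s=%.4f", names(x$omega), x$omega),
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' Per-branch dN and dS from a fitted codon model
#'
#' Site counts follow the model's mutational opportunity at omega = 1:
#' with synonymous/nonsynonymous rate flows `R_S`, `R_N` under the fitted
#' kappa and pi, a codon has `S = 3 R_S / (R_S + R_N)` synonymous sites.
#' Each branch's expected substitutions `t` are partitioned into synonymous
#' and nonsynonymous flow under that branch's omega, and divided by the
#' respective site counts, which guarantees `dN/dS == omega` exactly.
#'
#' @param fit A converged `model_fit`.
#' @return data.frame with one row per branch: `gene_id`, `branch_id`,
#'   `child_name`, `terminal`, `omega_class`, `t`, `omega`, `dN`, `dS`,
#'   `S_sites`, `N_sites` (site units per codon, `S_sites + N_sites == 3`).
#' @export
branch_dnds <- function(fit) {
  if (!isTRUE(fit$converged)) stop("branch_dnds requires a converged fit")
  fl <- gy94_flows(fit$kappa, fit$pi)
  S <- fl$S_per_codon; N <- fl$N_per_codon
  prep <- fit$prep
  nedge <- nrow(prep$phy$edge)
  omega_e <- unname(unlist(fit$omega)[prep$edge_class])
  rho_s <- fl$RS / (fl$RS + omega_e * fl$RN)
  rho_n <- 1 - rho_s
  dS <- fit$t * rho_s / S
  dN <- fit$t * rho_n / N
  parent_lab <- paste0("node", prep$phy$edge[, 1L])
  data.frame(gene_id = fit$gene_id,
             branch_id = paste0(parent_lab, "..", prep$child_name),
             child_name = prep$child_name,
             terminal = prep$terminal,
             omega_class = prep$edge_class,
             t = fit$t, omega = omega_e, dN = dN, dS = dS,
             S_sites = S, N_sites = N,
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested codon models
#'
#' @param restricted,general Converged `model_fit` objects on the same
#'   gene; the restricted spec must be nested in the general one
#'   (SINGLE_RATIO within any branch model or FREE_RATIO; a branch model
#'   within FREE_RATIO).
#' @return List with `statistic` (2 dlnL, clamped at 0), `df` (omega-class
#'   difference) and `p` (chi-squared upper tail).
#' @export
lrt_codon_models <- function(restricted, general) {
  rank <- c(SINGLE_RATIO = 1L, BRANCH_CATARRHINE = 2L,
            BRANCH_CATARRHINE_CETACEAN = 2L, BRANCH = 2L, FREE_RATIO = 3L)
  if (rank[restricted$spec$name] >= rank[general$spec$name]) {
    stop("models are not nested: ", restricted$spec$name, " vs ",
         general$spec$name)
  }
  if (!isTRUE(restricted$converged) || !isTRUE(general$converged)) {
    stop("both fits must be converged")
  }
  df <- length(general$omega) - length(restricted$omega)
  if (df < 1L) stop("general model adds no omega classes on this tree")
  stat <- max(0, 2 * (general$lnL - restricted$lnL))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
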