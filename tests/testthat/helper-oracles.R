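# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately brute-force and separate from the package
# implementation paths it checks.

code_univ <- genetic_code()

## ---- NG86 oracles: plain enumeration against the code table ----

oracle_site_count <- function(codon, code = code_univ) {
  nt <- c("T", "C", "A", "G")
  chars <- strsplit(codon, "")[[1L]]
  aa <- code$codon_to_aa
  s <- 0
  for (p in 1:3) {
    syn <- 0; tot <- 0
    for (b in setdiff(nt, chars[p])) {
      m <- chars; m[p] <- b
      mc <- paste0(m, collapse = "")
      if (aa[[mc]] == "*") next
      tot <- tot + 1
      if (aa[[mc]] == aa[[codon]]) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  s
}

# average syn/nonsyn steps over all stop-free substitution orderings
oracle_path_diffs <- function(a, b, code = code_univ) {
  aa <- code$codon_to_aa
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  pos <- which(ca != cb)
  if (length(pos) == 0L) return(c(0, 0))
  perms <- if (length(pos) == 1L) list(pos) else {
    idx <- seq_along(pos)
    ords <- if (length(pos) == 2L) list(idx, rev(idx)) else {
      do.call(c, lapply(1:3, function(i) {
        lapply(setdiff(1:3, i), function(j) c(i, j, setdiff(1:3, c(i, j))))
      }))
    }
    lapply(ords, function(o) pos[o])
  }
  sd <- nd <- 0; nok <- 0L
  for (ord in perms) {
    cur <- ca; psd <- pnd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- cb[p]
      if (aa[[paste0(nxt, collapse = "")]] == "*") { ok <- FALSE; break }
      if (aa[[paste0(cur, collapse = "")]] ==
          aa[[paste0(nxt, collapse = "")]]) psd <- psd + 1 else pnd <- pnd + 1
      cur <- nxt
    }
    if (ok) { sd <- sd + psd; nd <- nd + pnd; nok <- nok + 1L }
  }
  if (nok == 0L) return(c(NA_real_, NA_real_))
  c(sd / nok, nd / nok)
}

## ---- brute-force pruning oracle: sum over all ancestral codon states ----

# log-likelihood by explicit summation over every assignment of sense
# codons to the internal nodes (feasible for <= 3 internal nodes).
oracle_loglik <- function(aln, tree, kappa, omega, pi,
                          code = code_univ) {
  phy <- ape::reorder.phylo(tree$phy, "postorder")
  ns <- length(pi)
  Q <- codon_rate_matrix(kappa, omega, pi, code)
  P <- lapply(seq_len(nrow(phy$edge)), function(e) {
    transition_probabilities(Q, phy$edge.length[e])
  })
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  root <- ntip + 1L
  states <- t(vapply(aln$rows[phy$tip.label], function(r) {
    idx <- code_univ$codon_index[substring(r, seq(1, nchar(r), 3),
                                           seq(3, nchar(r), 3))]
    idx[is.na(idx)] <- 0L
    as.integer(idx)
  }, integer(nchar(aln$rows[[1L]]) / 3L)))
  ncol_a <- ncol(states)
  # every assignment of sense codons to the internal nodes (columns of grid)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  total <- 0
  for (col in seq_len(ncol_a)) {
    node_state <- function(node) {
      if (node <= ntip) rep(states[node, col], nrow(grid))
      else grid[, node - ntip]
    }
    term <- pi[grid[, root - ntip]]
    for (e in seq_len(nrow(phy$edge))) {
      u <- node_state(phy$edge[e, 1L])
      v <- node_state(phy$edge[e, 2L])
      obs <- v != 0L   # missing tips contribute a factor of 1
      term[obs] <- term[obs] * P[[e]][cbind(u[obs], v[obs])]
    }
    total <- total + log(sum(term))
  }
  total
}

## ---- affine-gap global alignment DP oracle ----

# independent Needleman-Wunsch with affine gaps (Gotoh), cost of a gap run
# of length L = open + L * extend, scores from the named Biostrings matrix.
oracle_align_score <- function(a, b, open = 11, extend = 1,
                               matname = "BLOSUM62") {
  S <- get(data(list = matname, package = "Biostrings",
                envir = environment()))
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (j in 2:(m + 1L)) Y[1, j] <- -(open + extend * (j - 1L))
  if (n >= 1L) for (i in 2:(n + 1L)) X[i, 1] <- -(open + extend * (i - 1L))
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      sc <- S[av[i - 1L], bv[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sc
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## ---- misc fixtures ----

random_cds <- function(n_codons, seed, code = code_univ) {
  set.seed(seed)
  paste0(sample(code$sense_codons, n_codons, replace = TRUE), collapse = "")
}

tiny_tree <- function(nwk = "((a:0.1,b:0.2):0.05,c:0.3);", tags = list()) {
  read_species_tree(nwk, tags = tags)
}
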