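# Goldman-Yang (GY94) codon substitution model: reversible Markov generator
# over the 61 sense codons parameterised by kappa (transition/transversion
# rate ratio), omega (dN/dS) and stationary codon frequencies pi.

.gy94_cache <- new.env(parent = emptyenv())

# Structural tables shared by every (kappa, omega, pi): ordered single-step
# codon pairs with transition / synonymous flags.
gy94_structure <- function(code = genetic_code()) {
  key <- code$table_id
  if (!is.null(.gy94_cache[[key]])) return(.gy94_cache[[key]])
  sense <- code$sense_codons
  n <- length(sense)
  chars <- strsplit(sense, "")
  aa <- code$codon_to_aa[sense]
  ii <- jj <- integer(0L); ts <- syn <- logical(0L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(chars[[i]] != chars[[j]])
      if (length(d) != 1L) next
      pair <- paste0(sort(c(chars[[i]][d], chars[[j]][d])), collapse = "")
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, pair %in% c("CT", "AG"))
      syn <- c(syn, aa[[i]] == aa[[j]])
    }
  }
  out <- list(i = ii, j = jj, ts = ts, syn = syn, n = n)
  .gy94_cache[[key]] <- out
  out
}

#' GY94 codon rate matrix
#'
#' `Q[i, j]` is zero for codon pairs differing at more than one position and
#' otherwise `pi[j] * kappa^[transition] * omega^[nonsynonymous]`; the
#' diagonal makes rows sum to zero and the matrix is rescaled so that
#' `-sum(pi * diag(Q)) == 1`, i.e. branch lengths are expected substitutions
#' per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Stationary frequencies over the sense codons (sums to 1), in
#'   the package codon order; see [f3x4_frequencies()].
#' @param code A [genetic_code()].
#' @param scale Rescale to one expected substitution per codon per unit
#'   time (default TRUE).
#' @return 61 x 61 rate matrix with attribute `pi`.
#' @export
codon_rate_matrix <- function(kappa, omega, pi, code = genetic_code(),
                              scale = TRUE) {
  st <- gy94_structure(code)
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (length(pi) != st$n || any(pi < 0) || abs(sum(pi) - 1) > 1e-6) {
    stop("pi must be ", st$n, " nonnegative frequencies summing to 1")
  }
  Q <- matrix(0, st$n, st$n,
              dimnames = list(code$sense_codons, code$sense_codons))
  rate <- pi[st$j]
  rate[st$ts] <- rate[st$ts] * kappa
  rate[!st$syn] <- rate[!st$syn] * omega
  Q[cbind(st$i, st$j)] <- rate
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  attr(Q, "pi") <- pi
  Q
}

# Eigendecomposition of the reversible generator in the pi^{1/2}-symmetrised
# basis: Q = U diag(d) Vt with U = D^{-1/2} R, Vt = R' D^{1/2}. Stable and
# reusable across branch lengths. pi entries are floored at 1e-10 upstream
# so D^{-1/2} is finite.
gy94_eigen <- function(kappa, omega, pi, code = genetic_code()) {
  Q <- codon_rate_matrix(kappa, omega, pi, code)
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))       # D^{1/2} Q D^{-1/2}
  B <- (B + t(B)) / 2              # symmetrise against roundoff
  eg <- sym_eigen_cpp(B)
  U <- eg$vectors / sq
  Vt <- t(eg$vectors) * rep(sq, each = length(sq))
  d <- as.numeric(eg$values)
  # eigenbasis images of dQ/domega and dQ/dkappa for analytic gradients:
  # with unnormalised generator N (Q = N/mu, mu the expected-rate scaler),
  # dQ/dtheta = (dN/dtheta)/mu - (dmu/dtheta / mu) * Q.
  st <- gy94_structure(code)
  n <- st$n
  off <- pi[st$j]
  off[st$ts] <- off[st$ts] * kappa
  off[!st$syn] <- off[!st$syn] * omega
  mu <- sum(pi[st$i] * off)
  bw <- pi[st$j]                       # dN/domega off-diagonals
  bw[st$ts] <- bw[st$ts] * kappa
  bw[st$syn] <- 0
  tk <- pi[st$j]                       # dN/dkappa off-diagonals
  tk[!st$syn] <- tk[!st$syn] * omega
  tk[!st$ts] <- 0
  basis_image <- function(vals, dmu) {
    M <- matrix(0, n, n)
    M[cbind(st$i, st$j)] <- vals
    diag(M) <- -rowSums(M)
    MM <- (Vt %*% M %*% U) / mu
    diag(MM) <- diag(MM) - (dmu / mu) * d
    MM
  }
  list(U = U, Vt = Vt, d = d,
       Mw = basis_image(bw, sum(pi[st$i] * bw)),
       Mk = basis_image(tk, sum(pi[st$i] * tk)),
       pi = pi, kappa = kappa, omega = omega)
}

# divided-difference matrix for the Frechet derivative of expm in the
# eigenbasis: G_ij = (e^{d_i t} - e^{d_j t}) / (d_i - d_j), t e^{d_i t} on
# (near-)coincident eigenvalues.
expm_frechet_gamma <- function(d, ed, t) {
  den <- outer(d, d, "-")
  G <- outer(ed, ed, "-") / den
  near <- abs(den) < 1e-9
  if (any(near)) {
    dbar <- outer(d, d, "+") / 2
    G[near] <- t * exp(dbar[near] * t)
  }
  G
}

#' Transition probability matrix of a codon model
#'
#' Matrix exponential `expm(Q t)` computed through the symmetrised
#' eigendecomposition of the reversible generator. Numerically negative
#' entries (roundoff) are clamped at zero; the largest clamped magnitude is
#' available as attribute `clamped`.
#'
#' @param Q Rate matrix from [codon_rate_matrix()] (carries `pi`), or a
#'   precomputed eigensystem from the internal decomposition.
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return Stochastic matrix; rows sum to 1 within 1e-10.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  eig <- if (is.matrix(Q)) {
    pi <- attr(Q, "pi")
    if (is.null(pi)) stop("Q lacks a pi attribute; build it with codon_rate_matrix()")
    sq <- sqrt(pi)
    B <- Q * (sq %o% (1 / sq))
    B <- (B + t(B)) / 2
    eg <- eigen(B, symmetric = TRUE)
    list(U = eg$vectors / sq, Vt = t(eg$vectors) * rep(sq, each = length(sq)),
         d = eg$values)
  } else Q
  P <- eig$U %*% (exp(eig$d * t) * eig$Vt)
  clamped <- min(P, 0)
  P[P < 0] <- 0
  attr(P, "clamped") <- abs(clamped)
  P
}

#' Codon equilibrium frequencies from an alignment
#'
#' `"F3x4"` (default, the codeml default): codon frequency proportional to
#' the product of position-specific nucleotide frequencies observed in the
#' alignment; `"F1x4"`: overall nucleotide frequencies; `"equal"`: uniform
#' over sense codons. Stop codons are removed and the vector renormalised.
#' Frequencies are floored at 1e-10 (then renormalised) so the reversible
#' eigendecomposition stays defined when a nucleotide is absent at a codon
#' position.
#'
#' @param aln A [codon_alignment()], or a character vector of (gapped) CDS.
#' @param method `"F3x4"`, `"F1x4"` or `"equal"`.
#' @param code A [genetic_code()].
#' @return Numeric vector over the sense codons (package codon order).
#' @export
f3x4_frequencies <- function(aln, method = c("F3x4", "F1x4", "equal"),
                             code = genetic_code()) {
  method <- match.arg(method)
  sense <- code$sense_codons
  if (method == "equal") {
    return(stats::setNames(rep(1 / length(sense), length(sense)), sense))
  }
  rows <- if (inherits(aln, "codon_alignment")) aln$rows else aln
  cod <- unlist(lapply(rows, split_codons), use.names = FALSE)
  cod <- cod[!grepl("[^ACGT]", cod)]
  if (length(cod) == 0L) stop("no unambiguous codons to estimate frequencies")
  nt <- c("T", "C", "A", "G")
  if (method == "F3x4") {
    freq <- vapply(1:3, function(p) {
      tab <- table(factor(substr(cod, p, p), levels = nt))
      as.numeric(tab) / sum(tab)
    }, numeric(4L))            # 4 x 3, rows in T,C,A,G order
    rownames(freq) <- nt
    pi <- vapply(sense, function(cd) {
      prod(freq[cbind(match(strsplit(cd, "")[[1L]], nt), 1:3)])
    }, numeric(1L))
  } else {
    tab <- table(factor(strsplit(paste0(cod, collapse = ""), "")[[1L]],
                        levels = nt))
    f <- stats::setNames(as.numeric(tab) / sum(tab), nt)
    pi <- vapply(sense, function(cd) {
      prod(f[strsplit(cd, "")[[1L]]])
    }, numeric(1L))
  }
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

# Synonymous/nonsynonymous mutational-opportunity flows under (kappa, pi):
# unnormalised rate mass R_S = sum_{syn pairs} pi_i pi_j kappa^[ts], R_N
# likewise over nonsynonymous pairs (omega = 1 flow). These define the
# model-based site counts S = 3 R_S / (R_S + R_N) per codon.
gy94_flows <- function(kappa, pi, code = genetic_code()) {
  st <- gy94_structure(code)
  mass <- pi[st$i] * pi[st$j] * ifelse(st$ts, kappa, 1)
  RS <- sum(mass[st$syn])
  RN <- sum(mass[!st$syn])
  list(RS = RS, RN = RN, S_per_codon = 3 * RS / (RS + RN),
       N_per_codon = 3 * RN / (RS + RN))
}
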