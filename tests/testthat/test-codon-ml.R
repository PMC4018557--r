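uniform_pi <- rep(1 / 61, 61)

test_that("two identical one-codon sequences at t = 0 give lnL = log(pi)", {
  tw <- read_species_tree("(a:0.0,b:0.0);")
  aln <- codon_alignment(c(a = "ATG", b = "ATG"), "g")
  ll <- codon_loglik(aln, tw, params = list(kappa = 2, omega = 0.5,
                                            pi = uniform_pi))
  expect_equal(ll, log(1 / 61), tolerance = 1e-10)
})

test_that("pruning equals brute-force ancestral summation on small instances", {
  # 3 tips (2 internal nodes) and 4 tips (3 internal nodes), <= 3 columns
  cases <- list(
    list(nwk = "((a:0.1,b:0.2):0.05,c:0.3);", n_codons = 3L, seed = 3),
    list(nwk = "((a:0.1,b:0.2):0.05,c:0.3);", n_codons = 2L, seed = 13),
    list(nwk = "((a:0.12,b:0.07):0.04,(c:0.2,d:0.15):0.06);", n_codons = 2L,
         seed = 23))
  for (cs in cases) {
    tw <- read_species_tree(cs$nwk)
    sim <- simulate_codon_alignment(
      sim_config(tw, kappa = 2, n_codons = cs$n_codons,
                 omega_by_tag = list(default = 0.5), seed = cs$seed), "g")
    lo <- oracle_loglik(sim$aln, tw, kappa = 2, omega = 0.5, pi = uniform_pi)
    lp <- codon_loglik(sim$aln, tw,
                       params = list(kappa = 2, omega = 0.5, pi = uniform_pi))
    expect_equal(lp, lo, tolerance = 1e-8)
  }
})

test_that("brute-force agreement holds with missing data in a column", {
  tw <- read_species_tree("((a:0.1,b:0.2):0.05,c:0.3);")
  aln <- codon_alignment(c(a = "ATGTTT", b = "ATG---", c = "ATGTTC"), "g")
  lo <- oracle_loglik(aln, tw, kappa = 1.5, omega = 0.8, pi = uniform_pi)
  lp <- codon_loglik(aln, tw, params = list(kappa = 1.5, omega = 0.8,
                                            pi = uniform_pi))
  expect_equal(lp, lo, tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  sim <- simulate_codon_alignment(
    sim_config(read_species_tree("((a:0.1,b:0.2):0.03,(c:0.15,d:0.3):0.02);"),
               n_codons = 80, seed = 9), "g")
  # slide the root along the central branch: 0.03+0.02 split three ways
  splits <- list(c(0.04, 0.01), c(0.025, 0.025), c(0.001, 0.049))
  lls <- vapply(splits, function(s) {
    nwk <- sprintf("((a:0.1,b:0.2):%f,(c:0.15,d:0.3):%f);", s[1L], s[2L])
    codon_loglik(sim$aln, read_species_tree(nwk),
                 params = list(kappa = 2, omega = 0.4, pi = uniform_pi))
  }, numeric(1L))
  expect_lt(diff(range(lls)), 1e-8)
})

test_that("a zero-length identical extra taxon shifts lnL by a computable constant", {
  base <- read_species_tree("((a:0.1,b:0.2):0.05,c:0.3);")
  sim <- simulate_codon_alignment(sim_config(base, n_codons = 40, seed = 14),
                                  "g")
  ll1 <- codon_loglik(sim$aln, base, params = list(kappa = 2, omega = 0.4,
                                                   pi = uniform_pi))
  # duplicate c at distance 0: emission certain, lnL unchanged
  ext <- read_species_tree("((a:0.1,b:0.2):0.05,(c:0.0,c2:0.0):0.3);")
  aln2 <- codon_alignment(c(sim$aln$rows, c2 = sim$aln$rows[["c"]]), "g")
  ll2 <- codon_loglik(aln2, ext, params = list(kappa = 2, omega = 0.4,
                                               pi = uniform_pi))
  expect_equal(ll2, ll1, tolerance = 1e-8)
})

test_that("species absent from the tree is an error", {
  tw <- read_species_tree("(a:0.1,b:0.1);")
  aln <- codon_alignment(c(a = "ATG", z = "ATG"), "g")
  expect_error(codon_loglik(aln, tw, params = list(kappa = 2, omega = 1,
                                                   pi = uniform_pi)),
               "absent")
})

test_that("single-ratio fit recovers generating omega within 20%", {
  tr8 <- read_species_tree(paste0(
    "(((s1:0.08,s2:0.08):0.05,(s3:0.08,s4:0.08):0.05):0.04,",
    "((s5:0.08,s6:0.08):0.05,(s7:0.08,s8:0.08):0.05):0.04);"))
  sim <- simulate_codon_alignment(
    sim_config(tr8, kappa = 2, n_codons = 500,
               omega_by_tag = list(default = 0.3), seed = 101), "g")
  fit <- fit_codon_model(sim$aln, tr8, model_spec("SINGLE_RATIO"),
                         opts = list(n_starts = 2, seed = 1))
  expect_true(fit$converged)
  expect_gte(fit$omega[["all"]], 0.24)
  expect_lte(fit$omega[["all"]], 0.36)
  expect_gt(fit$kappa, 1.4)
  expect_lt(fit$kappa, 2.8)
})

test_that("nested models are monotone in lnL and identical sequences hit bounds", {
  tr <- fixture_tree("TEST_6")
  sim <- simulate_codon_alignment(
    sim_config(tr, n_codons = 150, omega_by_tag = list(default = 0.3),
               seed = 55), "g")
  fs <- fit_codon_model(sim$aln, tr, model_spec("SINGLE_RATIO"),
                        opts = list(n_starts = 1, seed = 1))
  fb <- fit_codon_model(sim$aln, tr, model_spec("BRANCH_CATARRHINE"),
                        opts = list(n_starts = 1, seed = 1, init = fs))
  ff <- fit_codon_model(sim$aln, tr, model_spec("FREE_RATIO"),
                        opts = list(n_starts = 1, seed = 1, init = fb))
  expect_gte(fb$lnL, fs$lnL - 1e-4)
  expect_gte(ff$lnL, fb$lnL - 1e-4)
  # identical sequences: no substitutions, branch lengths at the floor
  rows <- stats::setNames(rep(random_cds(60, 2), 6L), tr$phy$tip.label)
  fid <- fit_codon_model(codon_alignment(rows, "gid"), tr,
                         model_spec("SINGLE_RATIO"),
                         opts = list(n_starts = 1, seed = 1))
  expect_true(all(fid$t <= 1e-5))
})

test_that("per-branch dN/dS equals the fitted omega and omega=1 means dN=dS", {
  tr <- fixture_tree("TEST_6")
  sim <- simulate_codon_alignment(
    sim_config(tr, n_codons = 120, omega_by_tag = list(default = 0.4),
               seed = 77), "g")
  fit <- fit_codon_model(sim$aln, tr, model_spec("FREE_RATIO"),
                         opts = list(n_starts = 1, seed = 1))
  bd <- branch_dnds(fit)
  ok <- bd$dS > 0
  expect_true(all(abs(bd$dN[ok] / bd$dS[ok] - bd$omega[ok]) <=
                    1e-6 * bd$omega[ok]))
  expect_equal(bd$S_sites + bd$N_sites, rep(3, nrow(bd)), tolerance = 1e-12)
  expect_true(all(bd[, c("t", "omega", "dN", "dS")] >= 0))
  # construction: with omega = 1 the two distances coincide
  fl <- branchomega:::gy94_flows(fit$kappa, fit$pi)
  t_ex <- 0.2
  dS1 <- t_ex * (fl$RS / (fl$RS + fl$RN)) / (fl$S_per_codon / 3) / 3
  dN1 <- t_ex * (fl$RN / (fl$RS + fl$RN)) / (fl$N_per_codon / 3) / 3
  expect_equal(dS1, dN1)
  expect_error(branch_dnds(structure(list(converged = FALSE),
                                     class = "model_fit")), "converged")
})

test_that("free-ratio dS along a 2-branch path matches pairwise NG86", {
  tw <- read_species_tree("(a:0.1,b:0.1);")
  sim <- simulate_codon_alignment(
    sim_config(tw, kappa = 2, n_codons = 2000,
               omega_by_tag = list(default = 0.4), seed = 202), "g")
  fit <- fit_codon_model(sim$aln, tw, model_spec("FREE_RATIO"),
                         opts = list(n_starts = 1, seed = 1))
  bd <- branch_dnds(fit)
  ng <- ng86_pairwise(sim$aln$rows[[1L]], sim$aln$rows[[2L]])
  expect_equal(sum(bd$dS), ng$dS, tolerance = 0.15)
  expect_equal(sum(bd$dN), ng$dN, tolerance = 0.15)
})

test_that("analytic gradients match numerical differences for every model", {
  tr <- fixture_tree("TEST_6")
  sim <- simulate_codon_alignment(
    sim_config(tr, n_codons = 80,
               omega_by_tag = list(default = 0.3, CATARRHINI = 0.6),
               seed = 5), "g")
  code <- genetic_code()
  pi <- f3x4_frequencies(sim$aln)
  for (sp in c("SINGLE_RATIO", "BRANCH_CATARRHINE", "FREE_RATIO")) {
    spec <- model_spec(sp)
    prep <- branchomega:::prepare_codon_tree(sim$aln, tr, spec)
    st <- branchomega:::codon_state_matrix(sim$aln)[prep$phy$tip.label, ,
                                                    drop = FALSE]
    pat <- branchomega:::compress_patterns(st)
    cache <- branchomega:::eigen_cache()
    nedge <- nrow(prep$phy$edge)
    classes <- prep$omega_classes
    ncls <- length(classes)
    set.seed(3)
    theta <- c(log(runif(nedge, 0.03, 0.3)), log(2.3),
               log(runif(ncls, 0.2, 0.8)))
    unpack <- function(th) {
      list(t = exp(th[seq_len(nedge)]), kappa = exp(th[nedge + 1L]),
           omega = stats::setNames(
             as.list(exp(th[nedge + 1L + seq_len(ncls)])), classes))
    }
    ll <- function(th) {
      p <- unpack(th)
      branchomega:::codon_ml_core(prep, pat$states, pat$weights, p$kappa,
                                  p$omega, pi, p$t, cache = cache)$loglik
    }
    p <- unpack(theta)
    P <- array(0, c(61, 61, nedge))
    Dt <- Dw <- Dk <- array(0, c(61, 61, nedge))
    for (cl in classes) {
      eg <- branchomega:::cached_eigen(cache, p$kappa, p$omega[[cl]], pi,
                                       code)
      for (e in which(prep$edge_class == cl)) {
        te <- p$t[e]; ed <- exp(eg$d * te)
        Pe <- eg$U %*% (ed * eg$Vt); Pe[Pe < 0] <- 0
        P[, , e] <- Pe
        Dt[, , e] <- eg$U %*% ((eg$d * ed) * eg$Vt)
        G <- branchomega:::expm_frechet_gamma(eg$d, ed, te)
        Dw[, , e] <- eg$U %*% ((eg$Mw * G) %*% eg$Vt)
        Dk[, , e] <- eg$U %*% ((eg$Mk * G) %*% eg$Vt)
      }
    }
    res <- branchomega:::prune_loglik_cpp(
      prep$phy$edge, length(prep$phy$tip.label), P, list(Dt, Dw, Dk),
      pat$states, pi, pat$weights, TRUE)
    analytic <- c(res$dtheta[, 1L] * p$t,
                  sum(res$dtheta[, 3L]) * p$kappa,
                  vapply(seq_len(ncls), function(ci) {
                    sum(res$dtheta[prep$edge_class == classes[ci], 2L]) *
                      p$omega[[ci]]
                  }, numeric(1L)))
    numeric_g <- vapply(seq_along(theta), function(k) {
      hh <- 1e-6
      up <- dn <- theta
      up[k] <- up[k] + hh; dn[k] <- dn[k] - hh
      (ll(up) - ll(dn)) / (2 * hh)
    }, numeric(1L))
    expect_lt(max(abs(analytic - numeric_g)), 1e-4)
  }
})

test_that("the LRT is computed from nesting rank with chi-squared tail", {
  f1 <- structure(list(spec = model_spec("SINGLE_RATIO"), lnL = -100,
                       omega = c(all = 0.3), converged = TRUE),
                  class = "model_fit")
  f2 <- structure(list(spec = model_spec("BRANCH_CATARRHINE"), lnL = -100,
                       omega = c(background = 0.3, foreground = 0.3),
                       converged = TRUE), class = "model_fit")
  r <- lrt_codon_models(f1, f2)
  expect_equal(r$statistic, 0)
  expect_identical(r$df, 1L)
  expect_equal(r$p, 1)
  f3 <- f2; f3$lnL <- -97.5
  r2 <- lrt_codon_models(f1, f3)
  expect_equal(r2$statistic, 5)
  expect_equal(r2$p, stats::pchisq(5, 1, lower.tail = FALSE))
  expect_error(lrt_codon_models(f2, f1), "nested")
})
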