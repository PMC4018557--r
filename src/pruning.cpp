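// Felsenstein pruning for codon models, with per-pattern scaling and
// analytic parameter derivatives via a pre-order (outside) pass.
//
// Conventions: nodes are numbered ape-style (tips 1..ntip, internals
// ntip+1..), edges arrive in postorder (every child's subtree edges before
// the edge to its parent). P.slice(e) is the transition matrix of edge e
// (row = parent state, column = child state). Each element of `derivs` is
// a cube D with D.slice(e) = dP_e/dtheta for some parameter theta; the
// kernel returns, per cube, the per-edge derivative contributions
// d lnL / dtheta_e, which the caller sums over edges sharing a parameter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List prune_loglik_cpp(const arma::imat& edge,   // nedge x 2, 1-based (parent, child)
                      int ntip,
                      const arma::cube& P,      // ns x ns x nedge
                      const List& derivs,       // list of ns x ns x nedge cubes
                      const arma::imat& tip_states, // ntip x npat, 0 = missing
                      const arma::vec& pi,
                      const arma::vec& weights, // npat
                      bool grad) {
  const int nedge = edge.n_rows;
  const int ns = pi.n_elem;
  const int npat = tip_states.n_cols;
  const int nnode_total = edge.max();
  const int nd = grad ? derivs.size() : 0;

  std::vector<arma::cube> D(nd);
  for (int k = 0; k < nd; ++k) D[k] = as<arma::cube>(derivs[k]);

  std::vector<arma::mat> Lpart(nnode_total + 1); // partials per node
  std::vector<arma::rowvec> slog(nnode_total + 1); // accumulated log scalers
  std::vector<arma::mat> A(nedge);               // per-edge messages
  std::vector<std::vector<arma::mat>> C(nd,
      std::vector<arma::mat>(nedge));            // derivative messages

  NumericMatrix dtheta(nedge, nd);
  List fail = List::create(_["loglik"] = R_NegInf, _["dtheta"] = dtheta);

  for (int e = 0; e < nedge; ++e) {
    const int u = edge(e, 0), v = edge(e, 1);
    arma::mat Ae(ns, npat);
    std::vector<arma::mat> Ce(nd);
    arma::rowvec childlog(npat, arma::fill::zeros);
    if (v <= ntip) {
      for (int p = 0; p < npat; ++p) {
        const int s = tip_states(v - 1, p);
        if (s > 0) Ae.col(p) = P.slice(e).col(s - 1);
        else Ae.col(p).ones(); // missing data: row sums of a stochastic matrix
      }
      for (int k = 0; k < nd; ++k) {
        Ce[k].set_size(ns, npat);
        for (int p = 0; p < npat; ++p) {
          const int s = tip_states(v - 1, p);
          if (s > 0) Ce[k].col(p) = D[k].slice(e).col(s - 1);
          else Ce[k].col(p).zeros(); // dP/dtheta has zero row sums
        }
      }
    } else {
      Ae = P.slice(e) * Lpart[v];
      for (int k = 0; k < nd; ++k) Ce[k] = D[k].slice(e) * Lpart[v];
      childlog = slog[v];
    }
    // per-pattern scaling; derivative ratios are scale-invariant as long
    // as A and C share the same factor
    for (int p = 0; p < npat; ++p) {
      double m = Ae.col(p).max();
      if (m <= 0.0 || !std::isfinite(m)) return fail;
      Ae.col(p) /= m;
      for (int k = 0; k < nd; ++k) Ce[k].col(p) /= m;
      childlog(p) += std::log(m);
    }
    if (Lpart[u].n_elem == 0) {
      Lpart[u] = Ae;
      slog[u] = childlog;
    } else {
      Lpart[u] %= Ae;
      slog[u] += childlog;
    }
    A[e] = std::move(Ae);
    for (int k = 0; k < nd; ++k) C[k][e] = std::move(Ce[k]);
  }

  const int root = edge(nedge - 1, 0);
  arma::rowvec rootlik = pi.t() * Lpart[root]; // 1 x npat
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (rootlik(p) <= 0.0) return fail;
    ll += weights(p) * (std::log(rootlik(p)) + slog[root](p));
  }

  if (grad && nd > 0) {
    // children edges per parent
    std::vector<std::vector<int>> kids(nnode_total + 1);
    for (int e = 0; e < nedge; ++e) kids[edge(e, 0)].push_back(e);
    std::vector<arma::mat> H(nnode_total + 1); // outside partials
    H[root] = arma::repmat(pi, 1, npat);
    for (int e = nedge - 1; e >= 0; --e) {     // reverse postorder: u before v
      const int u = edge(e, 0), v = edge(e, 1);
      arma::mat B = H[u];
      for (int e2 : kids[u]) {
        if (e2 != e) B %= A[e2];
      }
      arma::rowvec denom = arma::sum(B % A[e], 0);
      for (int k = 0; k < nd; ++k) {
        arma::rowvec numer = arma::sum(B % C[k][e], 0);
        double g = 0.0;
        for (int p = 0; p < npat; ++p) g += weights(p) * numer(p) / denom(p);
        dtheta(e, k) = g;
      }
      if (v > ntip) {
        arma::mat Hv = P.slice(e).t() * B;
        for (int p = 0; p < npat; ++p) { // rescale freely (ratios only)
          double m = Hv.col(p).max();
          if (m > 0.0) Hv.col(p) /= m;
        }
        H[v] = std::move(Hv);
      }
    }
  }
  return List::create(_["loglik"] = ll, _["dtheta"] = dtheta);
}

// Symmetric eigendecomposition (divide and conquer) for the
// pi^{1/2}-symmetrised reversible generator.
// [[Rcpp::export]]
List sym_eigen_cpp(const arma::mat& B) {
  arma::vec d;
  arma::mat V;
  if (!arma::eig_sym(d, V, B, "dc")) {
    stop("symmetric eigendecomposition failed");
  }
  return List::create(_["values"] = d, _["vectors"] = V);
}
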