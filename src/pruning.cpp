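#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Felsenstein pruning over one site class.
//
// edge:       nedge x 2 matrix of 1-based node indices (ape convention),
//             rows in postorder (children before parents).
// P:          list of nedge transition matrices (nstate x nstate), row =
//             parent state, col = child state.
// tipStates:  ntip x npat integer matrix; 1-based state index, 0 = missing
//             (integrates over all states).
// pi:         root frequencies, length nstate.
//
// Returns the per-pattern log-likelihood (length npat).
// [[Rcpp::export]]
NumericVector prune_loglik(const IntegerMatrix edge, const List P,
                           const IntegerMatrix tipStates,
                           const NumericVector pi,
                           const int ntip, const int nnode) {
  const int nedge = edge.nrow();
  const int npat = tipStates.ncol();
  const int nstate = pi.size();
  const int ntot = ntip + nnode;

  std::vector<arma::mat> partial(ntot + 1);
  std::vector<bool> has(ntot + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  // tip partials
  for (int t = 1; t <= ntip; ++t) {
    arma::mat m(nstate, npat);
    for (int p = 0; p < npat; ++p) {
      int s = tipStates(t - 1, p);
      if (s <= 0) {
        m.col(p).ones();
      } else {
        m.col(p).zeros();
        m(s - 1, p) = 1.0;
      }
    }
    partial[t] = m;
    has[t] = true;
  }

  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    const arma::mat Pm = as<arma::mat>(P[e]);
    arma::mat up = Pm * partial[child];
    if (!has[parent]) {
      partial[parent] = up;
      has[parent] = true;
    } else {
      partial[parent] %= up;
    }
    // rescale the parent's partials after its last child would be ideal;
    // rescaling after every edge is cheap and numerically safe
    arma::rowvec mx = arma::max(partial[parent], 0);
    for (int p = 0; p < npat; ++p) {
      if (mx(p) > 0 && (mx(p) < 1e-200 || mx(p) > 1e200)) {
        partial[parent].col(p) /= mx(p);
        logscale(p) += std::log(mx(p));
      }
    }
  }

  int root = edge(nedge - 1, 0);
  const arma::vec piv = as<arma::vec>(pi);
  NumericVector out(npat);
  for (int p = 0; p < npat; ++p) {
    double lik = arma::dot(piv, partial[root].col(p));
    out[p] = (lik > 0 ? std::log(lik) : -1e300) + logscale(p);
  }
  return out;
}

// Evolve states down a tree for simulation: for each edge (postorder input
// reversed in R to preorder), child states are sampled from the parent's
// row of P. Kept in R; no C++ needed there.
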