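#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Spherical k-means on rows of X (assumed unit-normalised upstream).
// Distance is cosine distance 1 - x.c; Lloyd assignment maximises the
// cosine, centroids are normalised cluster means, SSE is the summed
// cosine distance of members to their centroid.  All randomness comes
// from R's RNG (unif_rand) so set.seed() in R controls every draw.

namespace {

// sample an index in [0, n) with probability proportional to w
arma::uword sample_weighted(const arma::vec& w) {
  double tot = arma::accu(w);
  if (tot <= 0.0) return static_cast<arma::uword>(unif_rand() * w.n_elem);
  double u = unif_rand() * tot, acc = 0.0;
  for (arma::uword i = 0; i < w.n_elem; ++i) {
    acc += w(i);
    if (u <= acc) return i;
  }
  return w.n_elem - 1;
}

// k-means++ seeding on the unit sphere: squared Euclidean distance
// between unit vectors is 2(1 - cos), so weighting by cosine distance
// is the classic D^2 rule up to a constant factor.
arma::mat init_plusplus(const arma::mat& X, int k) {
  arma::uword n = X.n_rows;
  arma::mat C(k, X.n_cols);
  arma::uword first = static_cast<arma::uword>(unif_rand() * n);
  if (first >= n) first = n - 1;
  C.row(0) = X.row(first);
  if (k == 1) return C;
  arma::vec d2 = 1.0 - X * C.row(0).t();
  d2.clamp(0.0, arma::datum::inf);
  for (int j = 1; j < k; ++j) {
    arma::uword idx = sample_weighted(d2);
    C.row(j) = X.row(idx);
    if (j + 1 < k) {
      arma::vec dn = 1.0 - X * C.row(j).t();
      dn.clamp(0.0, arma::datum::inf);
      d2 = arma::min(d2, dn);
    }
  }
  return C;
}

struct KmFit {
  arma::uvec assign;
  arma::mat centroids;
  double sse;
};

KmFit lloyd_once(const arma::mat& X, int k, int max_iter) {
  arma::uword n = X.n_rows;
  arma::mat C = init_plusplus(X, k);
  arma::uvec assign(n, arma::fill::zeros), prev(n);
  prev.fill(n + 1);

  for (int it = 0; it < max_iter; ++it) {
    arma::mat sims = X * C.t();            // n x k cosines
    for (arma::uword i = 0; i < n; ++i) assign(i) = sims.row(i).index_max();

    // repair empty clusters: hand each one the point farthest from its
    // current centroid (smallest best-cosine), as its own singleton
    arma::vec best(n);
    for (arma::uword i = 0; i < n; ++i) best(i) = sims(i, assign(i));
    for (int j = 0; j < k; ++j) {
      if (!arma::any(assign == static_cast<arma::uword>(j))) {
        arma::uword far = best.index_min();
        assign(far) = j;
        best(far) = 2.0; // don't reuse the same point for another empty cluster
      }
    }

    if (arma::all(assign == prev)) break;
    prev = assign;

    for (int j = 0; j < k; ++j) {
      arma::uvec members = arma::find(assign == static_cast<arma::uword>(j));
      if (members.n_elem == 0) continue; // repair stole its only member
      arma::rowvec m = arma::mean(X.rows(members), 0);
      double nrm = arma::norm(m, 2);
      if (nrm > 1e-12) {
        C.row(j) = m / nrm;
      } else {
        C.row(j) = X.row(members(0)); // antipodal degenerate mean
      }
    }
  }

  arma::mat sims = X * C.t();
  for (arma::uword i = 0; i < n; ++i) assign(i) = sims.row(i).index_max();
  double sse = 0.0;
  for (arma::uword i = 0; i < n; ++i) sse += 1.0 - sims(i, assign(i));
  if (sse < 0.0) sse = 0.0;
  return KmFit{assign, C, sse};
}

KmFit best_of_restarts(const arma::mat& X, int k, int n_restarts, int max_iter) {
  KmFit best = lloyd_once(X, k, max_iter);
  for (int r = 1; r < n_restarts; ++r) {
    KmFit fit = lloyd_once(X, k, max_iter);
    if (fit.sse < best.sse) best = fit;
  }
  return best;
}

} // namespace

// [[Rcpp::export(rng = true)]]
List sph_kmeans_cpp(const arma::mat& X, int k, int n_restarts, int max_iter) {
  KmFit fit = best_of_restarts(X, k, n_restarts, max_iter);
  return List::create(
    _["assignments"] = IntegerVector(fit.assign.begin(), fit.assign.end()),
    _["centroids"] = fit.centroids,
    _["sse"] = fit.sse);
}

// [[Rcpp::export(rng = true)]]
NumericVector sse_profile_cpp(const arma::mat& X, int k_max, int n_restarts,
                              int max_iter) {
  NumericVector out(k_max);
  for (int k = 1; k <= k_max; ++k) {
    out[k - 1] = best_of_restarts(X, k, n_restarts, max_iter).sse;
  }
  return out;
}
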