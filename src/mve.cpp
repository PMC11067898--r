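// Resampling search for the minimum volume ellipsoid (MVE) covering h of n
// points: each candidate is the mean/covariance of a (d+1)-point subset,
// inflated to cover the h nearest points; the candidate with the smallest
// volume wins. The subset index matrix is generated (and seeded) on the R
// side so all randomness goes through R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".mve_search")]]
Rcpp::List mve_search(const arma::mat& X, const arma::imat& subsets, int h) {
  const uword n = X.n_rows, d = X.n_cols, m = subsets.n_rows;
  double best_logvol = datum::inf;
  vec best_center;
  mat best_shape;
  double best_s = NA_REAL;
  uword tried = 0;

  for (uword k = 0; k < m; ++k) {
    mat sub(subsets.n_cols, d);
    for (uword j = 0; j < subsets.n_cols; ++j)
      sub.row(j) = X.row(subsets(k, j));
    rowvec mu = mean(sub, 0);
    mat C = cov(sub); // sample covariance of the d+1 subset points
    // near-collinear subsets give numerically meaningless inverses and
    // spurious "small" volumes; require a usable condition number
    if (rcond(C) < 1e-10) continue;
    mat Cinv;
    if (!inv_sympd(Cinv, C)) continue; // singular subset
    ++tried;
    // squared Mahalanobis distances of all n points under (mu, C)
    mat centered = X.each_row() - mu;
    vec d2(n);
    for (uword i = 0; i < n; ++i) {
      rowvec r = centered.row(i);
      d2(i) = as_scalar(r * Cinv * r.t());
    }
    vec sorted = sort(d2);
    double s = sorted(h - 1); // h-th smallest: inflation factor
    if (s <= 0) continue;     // >= h coincident points; degenerate
    double ldet, sign;
    log_det(ldet, sign, C);
    if (sign <= 0) continue;
    double logvol = 0.5 * (d * std::log(s) + ldet);
    if (logvol < best_logvol) {
      best_logvol = logvol;
      best_center = mu.t();
      best_shape = s * C;
      best_s = s;
    }
  }
  if (!best_center.n_elem)
    Rcpp::stop("no non-singular candidate subset found");
  return Rcpp::List::create(
      Rcpp::Named("center") = best_center,
      Rcpp::Named("shape") = best_shape,
      Rcpp::Named("log_volume") = best_logvol,
      Rcpp::Named("inflation") = best_s,
      Rcpp::Named("n_candidates") = (int)tried);
}

// Squared Mahalanobis distances of rows of X to (center, shape^-1)
// [[Rcpp::export(name = ".mahal_sq")]]
arma::vec mahal_sq(const arma::mat& X, const arma::vec& center,
                   const arma::mat& shape) {
  mat Sinv;
  if (!inv_sympd(Sinv, shape) && !inv(Sinv, shape))
    Sinv = pinv(shape); // numerically semi-definite shape: least-squares sense

  mat centered = X.each_row() - center.t();
  vec out(X.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    rowvec r = centered.row(i);
    out(i) = as_scalar(r * Sinv * r.t());
  }
  return out;
}
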