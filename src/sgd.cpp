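#include <Rcpp.h>
using namespace Rcpp;

// Per-observation SGD for biased matrix factorization.
// r_hat = mu + b_u + b_i + q_i . p_u ; observations are visited in the order
// given, once per epoch, so training is deterministic for a fixed input
// order and initialization. Indices are 0-based.
// [[Rcpp::export]]
List sgd_svd_cpp(IntegerVector u, IntegerVector i, NumericVector r,
                 double mu, NumericVector bu0, NumericVector bi0,
                 NumericMatrix P0, NumericMatrix Q0,
                 int epochs, double lr, double reg) {
  NumericVector bu = clone(bu0), bi = clone(bi0);
  NumericMatrix P = clone(P0), Q = clone(Q0);
  const int n = r.size(), f = P.ncol();
  for (int ep = 0; ep < epochs; ++ep) {
    for (int t = 0; t < n; ++t) {
      const int uu = u[t], ii = i[t];
      double dot = 0.0;
      for (int k = 0; k < f; ++k) dot += P(uu, k) * Q(ii, k);
      const double e = r[t] - (mu + bu[uu] + bi[ii] + dot);
      if (!R_finite(e)) stop("non-finite training error at epoch %d, obs %d", ep + 1, t + 1);
      bu[uu] += lr * (e - reg * bu[uu]);
      bi[ii] += lr * (e - reg * bi[ii]);
      for (int k = 0; k < f; ++k) {
        const double puk = P(uu, k), qik = Q(ii, k);
        P(uu, k) += lr * (e * qik - reg * puk);
        Q(ii, k) += lr * (e * puk - reg * qik);
      }
    }
  }
  return List::create(_["bu"] = bu, _["bi"] = bi, _["P"] = P, _["Q"] = Q);
}

// SGD for SVD++: r_hat = mu + b_u + b_i + q_i . (p_u + |I_u|^{-1/2} sum_{j in I_u} y_j),
// where I_u is the set of items the user rated in training. Iu is a list of
// 0-based item index vectors per user.
// [[Rcpp::export]]
List sgd_svdpp_cpp(IntegerVector u, IntegerVector i, NumericVector r,
                   double mu, NumericVector bu0, NumericVector bi0,
                   NumericMatrix P0, NumericMatrix Q0, NumericMatrix Y0,
                   List Iu, int epochs, double lr, double reg) {
  NumericVector bu = clone(bu0), bi = clone(bi0);
  NumericMatrix P = clone(P0), Q = clone(Q0), Y = clone(Y0);
  const int n = r.size(), f = P.ncol();
  std::vector<double> impl(f);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int t = 0; t < n; ++t) {
      const int uu = u[t], ii = i[t];
      IntegerVector items_u = Iu[uu];
      const int nu = items_u.size();
      const double sqrt_inv = nu > 0 ? 1.0 / std::sqrt((double)nu) : 0.0;
      for (int k = 0; k < f; ++k) impl[k] = 0.0;
      for (int j = 0; j < nu; ++j) {
        const int jj = items_u[j];
        for (int k = 0; k < f; ++k) impl[k] += Y(jj, k);
      }
      for (int k = 0; k < f; ++k) impl[k] *= sqrt_inv;
      double dot = 0.0;
      for (int k = 0; k < f; ++k) dot += Q(ii, k) * (P(uu, k) + impl[k]);
      const double e = r[t] - (mu + bu[uu] + bi[ii] + dot);
      if (!R_finite(e)) stop("non-finite training error at epoch %d, obs %d", ep + 1, t + 1);
      bu[uu] += lr * (e - reg * bu[uu]);
      bi[ii] += lr * (e - reg * bi[ii]);
      for (int k = 0; k < f; ++k) {
        const double puk = P(uu, k), qik = Q(ii, k);
        P(uu, k) += lr * (e * qik - reg * puk);
        Q(ii, k) += lr * (e * (puk + impl[k]) - reg * qik);
        for (int j = 0; j < nu; ++j) {
          const int jj = items_u[j];
          Y(jj, k) += lr * (e * sqrt_inv * qik - reg * Y(jj, k));
        }
      }
    }
  }
  return List::create(_["bu"] = bu, _["bi"] = bi, _["P"] = P, _["Q"] = Q,
                      _["Y"] = Y);
}
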