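#include <Rcpp.h>
using namespace Rcpp;

// EM for a two-component 1-D Gaussian mixture with fixed initialization,
// at most max_iter iterations or a log-likelihood change below tol.
// Returns means, sds, weights, iterations, loglik.
//
// [[Rcpp::export]]
List gmm2_em_cpp(NumericVector x, double mu1, double mu2, double sg1,
                 double sg2, double w1, int max_iter, double tol,
                 double sig_floor) {
  int n = x.size();
  double w2 = 1.0 - w1;
  double ll_prev = R_NegInf, ll = R_NegInf;
  int it = 0;
  NumericVector g(n);
  for (it = 1; it <= max_iter; ++it) {
    ll = 0.0;
    double n1 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = w1 * R::dnorm(x[i], mu1, sg1, 0);
      double d2 = w2 * R::dnorm(x[i], mu2, sg2, 0);
      double tot = d1 + d2;
      if (tot <= 0) tot = DBL_MIN;
      g[i] = d1 / tot;
      ll += std::log(tot);
      n1 += g[i];
      s1 += g[i] * x[i];
      s2 += (1.0 - g[i]) * x[i];
    }
    if (R_finite(ll_prev) && std::fabs(ll - ll_prev) < tol) break;
    ll_prev = ll;
    double n2 = n - n1;
    mu1 = s1 / n1;
    mu2 = s2 / n2;
    double v1 = 0.0, v2 = 0.0;
    for (int i = 0; i < n; ++i) {
      v1 += g[i] * (x[i] - mu1) * (x[i] - mu1);
      v2 += (1.0 - g[i]) * (x[i] - mu2) * (x[i] - mu2);
    }
    sg1 = std::max(std::sqrt(v1 / n1), sig_floor);
    sg2 = std::max(std::sqrt(v2 / n2), sig_floor);
    w1 = n1 / n;
    w2 = 1.0 - w1;
  }
  return List::create(_["means"] = NumericVector::create(mu1, mu2),
                      _["sds"] = NumericVector::create(sg1, sg2),
                      _["weights"] = NumericVector::create(w1, w2),
                      _["iterations"] = it, _["loglik"] = ll);
}
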