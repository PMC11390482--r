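#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of the asymmetric Student-t residual model
// e = cell - a - r * np, with scale s for negative residuals and
// asymmetry * s for positive ones. Hot path of the neuropil fit.
//
// [[Rcpp::export]]
double ast_negll_cpp(NumericVector cell, NumericVector np, double r,
                     double a, double s, double nu, double asymmetry) {
  int n = cell.size();
  // log density constant of the t distribution
  double lc = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0) -
              0.5 * std::log(nu * M_PI);
  double s_pos = asymmetry * s;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = cell[i] - a - r * np[i];
    double sc = e > 0 ? s_pos : s;
    double z = e / sc;
    nll -= lc - 0.5 * (nu + 1.0) * std::log1p(z * z / nu) - std::log(sc);
  }
  return nll;
}
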