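#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of the hierarchical bootstrap for the default
// mean-difference statistic on paired nested data.
//
// Each iteration resamples animals with replacement, then resamples each
// drawn animal's cells with replacement (to that animal's original cell
// count), then applies an independent within-pair condition swap (sign flip
// of the paired difference) with probability 0.5, and records the mean of
// the signed differences. Uses R's RNG so set.seed() governs the draws.
//
// [[Rcpp::export]]
NumericVector hier_boot_null_meandiff(NumericVector d, IntegerVector animal,
                                      int n_animals, int n_boot) {
  int n = d.size();
  // group cell indices by animal (animal ids are 1..n_animals)
  std::vector< std::vector<int> > cells(n_animals);
  for (int i = 0; i < n; ++i) cells[animal[i] - 1].push_back(i);
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    double sum = 0.0;
    int count = 0;
    for (int a = 0; a < n_animals; ++a) {
      int drawn = (int)(unif_rand() * n_animals);
      if (drawn == n_animals) drawn = n_animals - 1;
      const std::vector<int>& cc = cells[drawn];
      int na = cc.size();
      for (int c = 0; c < na; ++c) {
        int ci = (int)(unif_rand() * na);
        if (ci == na) ci = na - 1;
        double v = d[cc[ci]];
        if (unif_rand() < 0.5) v = -v;
        sum += v;
        ++count;
      }
    }
    out[b] = count > 0 ? sum / count : NA_REAL;
  }
  return out;
}
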