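#include <Rcpp.h>
using namespace Rcpp;

// Averaged-perceptron training loop. Mirrors the textbook online update:
// for each presentation, if y * (w.x + b) <= 0, w += lr*y*x, b += lr*y;
// the returned weights are the average over all presentations, which
// stabilizes the otherwise order-sensitive final iterate. `order` is a
// 1-based presentation order fixed by the caller's seed.
// [[Rcpp::export]]
List perceptron_train_cpp(NumericMatrix x, IntegerVector y01,
                          IntegerVector order, int epochs, double lr) {
  const int n = x.nrow(), p = x.ncol();
  std::vector<double> w(p, 0.0), wsum(p, 0.0);
  double b = 0.0, bsum = 0.0;
  double count = 0.0;
  for (int e = 0; e < epochs; ++e) {
    for (int oi = 0; oi < n; ++oi) {
      const int i = order[oi] - 1;
      const double yy = (y01[i] == 1) ? 1.0 : -1.0;
      double m = b;
      for (int j = 0; j < p; ++j) m += w[j] * x(i, j);
      if (yy * m <= 0) {
        for (int j = 0; j < p; ++j) w[j] += lr * yy * x(i, j);
        b += lr * yy;
      }
      for (int j = 0; j < p; ++j) wsum[j] += w[j];
      bsum += b;
      count += 1.0;
    }
  }
  NumericVector wout(p);
  for (int j = 0; j < p; ++j) wout[j] = wsum[j] / count;
  return List::create(_["w"] = wout, _["b"] = bsum / count);
}
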