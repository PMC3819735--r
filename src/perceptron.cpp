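#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Classical perceptron: learning rate 1, weights initialized at zero,
// samples shuffled each epoch (Fisher-Yates with R's RNG), update
// w <- w + y_k x_k on every sample with y_k * (w . x_k) <= 0.  Stops at
// the first epoch with no errors or at the epoch cap.  X holds one
// sample per COLUMN (contiguous access in the inner loop).
// [[Rcpp::export]]
List perceptron_cpp(NumericMatrix X, IntegerVector y, int max_epochs) {
  int d = X.nrow(), nsamp = X.ncol();
  std::vector<double> w(d, 0.0);
  std::vector<int> idx(nsamp);
  for (int i = 0; i < nsamp; ++i) idx[i] = i;
  IntegerVector errors(max_epochs, NA_INTEGER);
  bool converged = false;
  int epochs_run = 0;
  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int i = nsamp - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    int nerr = 0;
    for (int s = 0; s < nsamp; ++s) {
      int k = idx[s];
      const double *xk = &X(0, k);
      double dot = 0.0;
      for (int f = 0; f < d; ++f) dot += w[f] * xk[f];
      if (y[k] * dot <= 0.0) {
        nerr++;
        for (int f = 0; f < d; ++f) w[f] += y[k] * xk[f];
      }
    }
    errors[ep] = nerr;
    epochs_run = ep + 1;
    if (nerr == 0) { converged = true; break; }
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["converged"] = converged,
                      _["epochs_run"] = epochs_run,
                      _["errors"] = errors[Range(0, epochs_run - 1)]);
}
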