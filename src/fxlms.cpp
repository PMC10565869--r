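#include <Rcpp.h>
using namespace Rcpp;

// Sample-wise filtered-x LMS loop for CTC-filter estimation.
//
// sR:  reference input s_R(n), length n
// d:   primary-path contribution conv(s_R, h_RL)(n), truncated to n
// xf:  filtered-x signal conv(s_R, c_LL)(n), truncated to n
// hLL: secondary-path response (length q), applied to the anti-signal history
// p:   adaptive filter length
// mu:  learning rate; with normalized = true the effective step is
//      mu / (||xf_vec||^2 + delta)
//
// The error is e(n) = d(n) + sum_k hLL[k] * anti(n - k) with
// anti(n) = w(n)^T s_vec(n); the update is w <- w - step * e(n) * xf_vec(n).
// Coefficient change is logged per block of p samples as
// ||w_end - w_start|| / max(||w_end||, 1e-30). Divergence is flagged when a
// block's mean e^2 exceeds 1e6 times the first block's (or 1e6 absolute while
// the first block is still silent).
// [[Rcpp::export]]
List fxlms_core(NumericVector sR, NumericVector d, NumericVector xf,
                NumericVector hLL, int p, double mu, bool normalized,
                double delta) {
  const int n = sR.size();
  const int q = hLL.size();
  std::vector<double> w(p, 0.0);
  std::vector<double> anti(n, 0.0);
  NumericVector err(n);
  const int n_blocks = (n + p - 1) / p;
  NumericVector coef_change(n_blocks);
  std::vector<double> w_prev(p, 0.0);

  double xnorm = 0.0;
  double block_e2 = 0.0, first_block_e2 = -1.0;
  bool diverged = false;
  int block = 0;

  for (int t = 0; t < n; ++t) {
    // anti-signal output of the CTC filter
    double a = 0.0;
    const int kmaxp = std::min(p, t + 1);
    for (int k = 0; k < kmaxp; ++k) a += w[k] * sR[t - k];
    anti[t] = a;

    // error at the sensor: primary contribution + anti through secondary path
    double e = d[t];
    const int kmaxq = std::min(q, t + 1);
    for (int k = 0; k < kmaxq; ++k) e += hLL[k] * anti[t - k];
    err[t] = e;
    block_e2 += e * e;

    // running ||xf_vec||^2 over the last p samples
    xnorm += xf[t] * xf[t];
    if (t >= p) xnorm -= xf[t - p] * xf[t - p];

    double step = normalized ? mu / (xnorm + delta) : mu;
    const double g = step * e;
    for (int k = 0; k < kmaxp; ++k) w[k] -= g * xf[t - k];

    if ((t + 1) % p == 0 || t == n - 1) {
      double dw = 0.0, nw = 0.0;
      for (int k = 0; k < p; ++k) {
        double diff = w[k] - w_prev[k];
        dw += diff * diff;
        nw += w[k] * w[k];
      }
      coef_change[block] = std::sqrt(dw) / std::max(std::sqrt(nw), 1e-30);
      std::copy(w.begin(), w.end(), w_prev.begin());
      if (first_block_e2 < 0.0) first_block_e2 = block_e2;
      if (block_e2 > 1e6 * std::max(first_block_e2, 1e-300)) {
        diverged = true;
        block += 1;
        break;
      }
      block_e2 = 0.0;
      block += 1;
    }
  }

  if (block < n_blocks) {
    coef_change = coef_change[Range(0, std::max(block - 1, 0))];
    err = err[Range(0, std::min(block * p, n) - 1)];
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["error"] = err,
                      _["coef_change"] = coef_change,
                      _["diverged"] = diverged);
}
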