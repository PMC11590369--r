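#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning for the k-state symmetric Mk model with a discrete
// gamma rate mixture. Characters may have different state counts; each
// column's k comes in kvec. Transition probabilities use the closed form
//   p_same(t) = 1/k + (k-1)/k * exp(-k t / (k-1))
//   p_diff(t) = 1/k -   1/k  * exp(-k t / (k-1))
// Edges must be supplied in postorder (children before parents). Tip data
// arrive as state bitmasks; partials are rescaled lazily (only when they
// shrink below a threshold) so large trees cannot underflow. Returns one
// log-likelihood per character, averaged over the rate categories, under
// uniform root frequencies.

// [[Rcpp::export]]
NumericVector mk_loglik_cpp(IntegerVector parent, IntegerVector child,
                            NumericVector elen, int ntip, int nnode_total,
                            int root, IntegerMatrix tipmask,
                            IntegerVector kvec, NumericVector gamma_rates) {
  const int nedge = parent.size();
  const int nchar = tipmask.ncol();
  const int nrate = gamma_rates.size();
  NumericVector out(nchar);

  // distinct state counts
  std::vector<int> ks;
  std::vector<int> kidx(6, -1);  // state counts 2..5 supported
  for (int ch = 0; ch < nchar; ++ch) {
    int k = kvec[ch];
    if (k < 2 || k > 5) stop("state counts must be between 2 and 5");
    if (kidx[k] < 0) { kidx[k] = ks.size(); ks.push_back(k); }
  }
  const int nk = ks.size();

  // hoisted exp(-k t / (k-1)) per edge x rate x k-class
  std::vector<double> ex(nedge * nrate * nk);
  for (int e = 0; e < nedge; ++e) {
    if (elen[e] < 0) stop("negative effective branch length");
    for (int r = 0; r < nrate; ++r) {
      const double t = elen[e] * gamma_rates[r];
      for (int j = 0; j < nk; ++j) {
        const double k = ks[j];
        ex[(e * nrate + r) * nk + j] = std::exp(-k * t / (k - 1.0));
      }
    }
  }

  std::vector<double> partial(nnode_total * 5);
  std::vector<double> logscale(nnode_total);
  std::vector<double> pervec(5);
  std::vector<double> ll_rate(nrate);
  const double tiny = 1e-120;

  for (int ch = 0; ch < nchar; ++ch) {
    const int k = kvec[ch];
    const int j = kidx[k];
    for (int r = 0; r < nrate; ++r) {
      for (int n = 0; n < nnode_total; ++n) {
        logscale[n] = 0.0;
        double init = (n < ntip) ? 0.0 : 1.0;
        for (int s = 0; s < k; ++s) partial[n * 5 + s] = init;
      }
      for (int t = 0; t < ntip; ++t) {
        int mask = tipmask(t, ch);
        for (int s = 0; s < k; ++s)
          if (mask & (1 << s)) partial[t * 5 + s] = 1.0;
      }
      for (int e = 0; e < nedge; ++e) {
        const int p = parent[e] - 1, c = child[e] - 1;
        const double exv = ex[(e * nrate + r) * nk + j];
        const double pdiff = (1.0 - exv) / double(k);
        double S = 0.0;
        for (int s = 0; s < k; ++s) S += partial[c * 5 + s];
        double mx = 0.0;
        for (int s = 0; s < k; ++s) {
          pervec[s] = pdiff * S + exv * partial[c * 5 + s];
          if (pervec[s] > mx) mx = pervec[s];
        }
        double newscale = logscale[c];
        if (mx < tiny) {
          if (mx <= 0.0) mx = 1.0;  // impossible data under this rate
          for (int s = 0; s < k; ++s)
            partial[p * 5 + s] *= pervec[s] / mx;
          newscale += std::log(mx);
        } else {
          for (int s = 0; s < k; ++s)
            partial[p * 5 + s] *= pervec[s];
        }
        logscale[p] += newscale;
      }
      double L = 0.0;
      const int rt = root - 1;
      for (int s = 0; s < k; ++s) L += partial[rt * 5 + s];
      ll_rate[r] = (L <= 0.0) ? R_NegInf
                              : std::log(L / double(k)) + logscale[rt];
    }
    double m = ll_rate[0];
    for (int r = 1; r < nrate; ++r) if (ll_rate[r] > m) m = ll_rate[r];
    if (!std::isfinite(m)) { out[ch] = R_NegInf; continue; }
    double acc = 0.0;
    for (int r = 0; r < nrate; ++r) acc += std::exp(ll_rate[r] - m);
    out[ch] = m + std::log(acc / double(nrate));
  }
  return out;
}
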