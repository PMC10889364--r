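#include <Rcpp.h>
using namespace Rcpp;

// log10 entropy of a nonnegative weight vector; all-zero -> log10(B)
static double entropy10(const std::vector<double>& w) {
  double s = 0.0;
  for (double x : w) s += x;
  if (s <= 0.0) return std::log10((double)w.size());
  double h = 0.0;
  for (double x : w) {
    if (x > 0.0) {
      double p = x / s;
      h -= p * std::log10(p);
    }
  }
  return h;
}

// Deterministic replay of a choice/outcome sequence through the basis-weight
// learning rule (selective maintenance when gamma > 0; traditional RL when
// gamma == 0). Returns the negative log-likelihood of the observed response
// bins under the softmax policy and, optionally, the per-trial latents.
//
// phi:  n_bins x B unit-height basis at the bin centers
// elig: n_bins x B eligibility at the bin centers
// rt_bin: 0-based observed response bins
// run: run index per trial (trials sorted within run); weights re-initialize
//      to w_init whenever run changes if reset_per_run is true
// [[Rcpp::export(name = ".replay_cpp")]]
List replay_cpp(NumericMatrix phi, NumericMatrix elig,
                IntegerVector rt_bin, NumericVector reward,
                IntegerVector run,
                double alpha, double beta, double gamma, double h,
                bool reset_per_run, NumericVector w_init,
                bool latents) {
  const int n = rt_bin.size();
  const int n_bins = phi.nrow();
  const int B = phi.ncol();
  if (reward.size() != n || run.size() != n)
    stop("rt_bin, reward and run must have equal length");
  if (w_init.size() != B) stop("w_init must have length B");

  std::vector<double> w(B), v(n_bins);
  for (int b = 0; b < B; ++b) w[b] = w_init[b];
  const double* phi_p = phi.begin();   // column-major, n_bins x B
  const double* elig_p = elig.begin();

  double nll = 0.0;
  NumericVector H, dH, rtv, vmax, vch, pe_out;
  NumericMatrix vmat, wmat;
  if (latents) {
    H = NumericVector(n); dH = NumericVector(n); rtv = NumericVector(n);
    vmax = NumericVector(n); vch = NumericVector(n); pe_out = NumericVector(n);
    vmat = NumericMatrix(n, n_bins);
    wmat = NumericMatrix(n + 1, B);
  }

  int cur_run = (n > 0) ? run[0] : 0;
  for (int i = 0; i < n; ++i) {
    if (reset_per_run && run[i] != cur_run) {
      for (int b = 0; b < B; ++b) w[b] = w_init[b];
      cur_run = run[i];
    }
    const int j = rt_bin[i];
    if (j < 0 || j >= n_bins) stop("rt_bin out of range at trial %d", i + 1);

    // pre-choice value function and softmax log-likelihood
    std::fill(v.begin(), v.end(), 0.0);
    for (int b = 0; b < B; ++b) {
      const double wb = w[b];
      if (wb == 0.0) continue;
      const double* col = phi_p + (size_t)b * n_bins;
      for (int k = 0; k < n_bins; ++k) v[k] += col[k] * wb;
    }
    double vmx = v[0];
    int jmx = 0;
    for (int k = 1; k < n_bins; ++k) {
      if (v[k] > vmx) { vmx = v[k]; jmx = k; }
    }
    double lse = 0.0;
    for (int k = 0; k < n_bins; ++k) lse += std::exp((v[k] - vmx) / beta);
    lse = std::log(lse);
    nll -= (v[j] - vmx) / beta - lse;

    double h_before = 0.0, h_after = 0.0;
    if (latents) {
      h_before = entropy10(w);
      for (int k = 0; k < n_bins; ++k) vmat(i, k) = v[k];
      for (int b = 0; b < B; ++b) wmat(i, b) = w[b];
    }

    // weight update
    const double r = reward[i];
    for (int b = 0; b < B; ++b) {
      const double e = elig_p[j + (size_t)b * n_bins];
      w[b] += e * alpha * (r - w[b]) - gamma * (1.0 - e) * (w[b] - h);
    }

    if (latents) {
      h_after = entropy10(w);
      H[i] = h_before;
      dH[i] = h_after - h_before;
      rtv[i] = jmx;                 // 0-based argmax bin; earliest tie wins
      vmax[i] = v[jmx];
      vch[i] = v[j];
      pe_out[i] = r - v[j];
    }
  }
  if (!std::isfinite(nll)) stop("non-finite negative log-likelihood");

  if (latents) {
    for (int b = 0; b < B; ++b) wmat(n, b) = w[b];
    return List::create(_["nll"] = nll, _["entropy"] = H,
                        _["entropy_change"] = dH, _["rt_vmax_bin"] = rtv,
                        _["v_max"] = vmax, _["v_chosen"] = vch,
                        _["pe"] = pe_out, _["values"] = vmat,
                        _["weights"] = wmat);
  }
  return List::create(_["nll"] = nll);
}
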