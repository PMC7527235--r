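#include <Rcpp.h>
using namespace Rcpp;

// Swap-dynamics engine. Proposes `iters` random axon-pair swaps on the
// bijection `perm` (0-based targets), accepting each with probability
// 1/(1+exp(beta*dE)). dE is computed incrementally: O(1) for the chemical
// term, O(N) over partners for the activity term, with the correlation (C)
// and overlap (U) kernels pre-tabulated. Uses R's RNG so runs are
// reproducible under set.seed().

// [[Rcpp::export]]
List engine_run(IntegerVector init_perm, NumericVector R, NumericVector L,
                NumericMatrix C, NumericMatrix U,
                double alpha, double gamma, double beta,
                double iters, int trace) {
  const int n = init_perm.size();
  std::vector<int> t(init_perm.begin(), init_perm.end());
  const double *Cp = C.begin(), *Up = U.begin();

  // current energy, only tracked when a trace is requested
  double E = 0.0;
  NumericVector trace_out(trace > 0 ? trace + 1 : 0);
  long long trace_every = 0;
  int trace_k = 0;
  if (trace > 0) {
    for (int i = 0; i < n; ++i) E += alpha * R[i] * L[t[i]];
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        E -= gamma * Cp[i + n * j] * Up[t[i] + n * t[j]];
    trace_out[trace_k++] = E;
    trace_every = (long long)(iters / trace);
    if (trace_every < 1) trace_every = 1;
  }

  RNGScope scope;
  const long long niter = (long long)iters;
  for (long long it = 0; it < niter; ++it) {
    int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
    int j = (int)(unif_rand() * n); if (j == n) j = n - 1;
    if (i == j) { if (trace > 0 && (it + 1) % trace_every == 0 && trace_k <= trace) trace_out[trace_k++] = E; continue; }

    const int ti = t[i], tj = t[j];
    double dE = alpha * (R[i] - R[j]) * (L[tj] - L[ti]);
    if (gamma != 0.0) {
      const double *Ci = Cp + (size_t)i * n, *Cj = Cp + (size_t)j * n;
      const double *Ui = Up + (size_t)ti * n, *Uj = Up + (size_t)tj * n;
      double s = 0.0;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        s += (Ci[k] - Cj[k]) * (Uj[t[k]] - Ui[t[k]]);
      }
      dE -= gamma * s;
    }

    // logistic acceptance, stable for large |dE|
    double z = beta * dE, p;
    if (z > 0) { double e = std::exp(-z); p = e / (1.0 + e); }
    else       { p = 1.0 / (1.0 + std::exp(z)); }
    if (unif_rand() < p) {
      t[i] = tj; t[j] = ti;
      E += dE;
    }
    if (trace > 0 && (it + 1) % trace_every == 0 && trace_k <= trace)
      trace_out[trace_k++] = E;
  }

  IntegerVector out(t.begin(), t.end());
  return List::create(_["perm"] = out,
                      _["trace"] = trace_out);
}
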