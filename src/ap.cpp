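#include <Rcpp.h>
using namespace Rcpp;

// Affinity propagation by responsibility/availability message passing on a
// dense similarity matrix. Exemplars are points k with A(k,k)+R(k,k) > 0;
// convergence is declared when the exemplar set is unchanged for conv_iter
// consecutive iterations. All loops run column-contiguous over the
// column-major matrices.
// [[Rcpp::export(name = ".ap_message_passing")]]
List ap_message_passing(NumericMatrix S_, double damping, int max_iter,
                        int conv_iter) {
  const int n = S_.nrow();
  const double keep = damping, mix = 1.0 - damping;
  std::vector<double> S(S_.begin(), S_.end());
  std::vector<double> R(n * n, 0.0), A(n * n, 0.0);
  std::vector<double> max1(n), max2(n);
  std::vector<int> arg1(n), exemplar_flag(n, 0), prev_flag(n, -1);
  int stable = 0, it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    // per-row max and second max of A + S (k outer, i inner: contiguous)
    for (int i = 0; i < n; ++i) {
      max1[i] = -INFINITY; max2[i] = -INFINITY; arg1[i] = -1;
    }
    for (int k = 0; k < n; ++k) {
      const double *a = &A[(size_t)k * n], *s = &S[(size_t)k * n];
      for (int i = 0; i < n; ++i) {
        double v = a[i] + s[i];
        if (v > max1[i]) { max2[i] = max1[i]; max1[i] = v; arg1[i] = k; }
        else if (v > max2[i]) { max2[i] = v; }
      }
    }
    // damped responsibility update
    for (int k = 0; k < n; ++k) {
      const double *s = &S[(size_t)k * n];
      double *r = &R[(size_t)k * n];
      for (int i = 0; i < n; ++i) {
        double newr = s[i] - (k == arg1[i] ? max2[i] : max1[i]);
        r[i] = keep * r[i] + mix * newr;
      }
    }
    // damped availability update, one column at a time
    for (int k = 0; k < n; ++k) {
      const double *r = &R[(size_t)k * n];
      double *a = &A[(size_t)k * n];
      double sum = 0.0;
      for (int i = 0; i < n; ++i)
        if (i != k && r[i] > 0.0) sum += r[i];
      const double rkk = r[k];
      for (int i = 0; i < n; ++i) {
        double newa;
        if (i == k) {
          newa = sum;
        } else {
          double s = rkk + sum - (r[i] > 0.0 ? r[i] : 0.0);
          newa = s < 0.0 ? s : 0.0;
        }
        a[i] = keep * a[i] + mix * newa;
      }
    }
    // exemplar set and convergence check
    bool same = true;
    for (int k = 0; k < n; ++k) {
      size_t kk = (size_t)k * n + k;
      exemplar_flag[k] = (A[kk] + R[kk]) > 0.0 ? 1 : 0;
      if (exemplar_flag[k] != prev_flag[k]) same = false;
      prev_flag[k] = exemplar_flag[k];
    }
    // with heavy damping the messages evolve slowly, so the exemplar
    // sign pattern can look stable long before the fixed point is
    // reached; only count stability after a burn-in
    const int burn_in = 100;
    stable = (it > burn_in && same) ? stable + 1 : 0;
    if (stable >= conv_iter) { converged = true; break; }
  }

  std::vector<int> ex;
  for (int k = 0; k < n; ++k) if (exemplar_flag[k]) ex.push_back(k);
  if (ex.empty()) {
    // fall back to the point with the largest self-evidence
    int best = 0;
    double bv = A[0] + R[0];
    for (int k = 1; k < n; ++k) {
      size_t kk = (size_t)k * n + k;
      double v = A[kk] + R[kk];
      if (v > bv) { bv = v; best = k; }
    }
    ex.push_back(best);
  }
  // assign every point to its most similar exemplar; exemplars to themselves
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    int best = ex[0];
    double bv = S[(size_t)ex[0] * n + i];
    for (size_t j = 1; j < ex.size(); ++j) {
      double v = S[(size_t)ex[j] * n + i];
      if (v > bv) { bv = v; best = ex[j]; }
    }
    assign[i] = best + 1;  // 1-based for R
  }
  for (size_t j = 0; j < ex.size(); ++j) assign[ex[j]] = ex[j] + 1;

  IntegerVector exemplars(ex.size());
  for (size_t j = 0; j < ex.size(); ++j) exemplars[j] = ex[j] + 1;
  return List::create(_["exemplars"] = exemplars, _["assignments"] = assign,
                      _["iterations"] = it > max_iter ? max_iter : it,
                      _["converged"] = converged);
}
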