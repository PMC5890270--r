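#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update for one parameter tensor.
//
// Mutates `w`, `m` and `v` directly: callers must own these vectors
// exclusively (the R side deep-copies before snapshotting/restoring so
// copy-on-write aliases are never written through).
//
// Uses the bias-corrected form folded into the step size:
//   alpha_t = lr * sqrt(1 - b2^t) / (1 - b1^t)
//   w <- w - alpha_t * m / (sqrt(v) + eps * sqrt(1 - b2^t))
// which is algebraically the standard update with mhat = m/(1-b1^t),
// vhat = v/(1-b2^t).
// [[Rcpp::export]]
void adam_update_inplace(NumericVector w, NumericVector g,
                         NumericVector m, NumericVector v,
                         double lr, double b1, double b2,
                         double eps, double t) {
  const R_xlen_t n = w.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_inplace: length mismatch");
  const double c1 = 1.0 - b1, c2 = 1.0 - b2;
  const double bc2 = std::sqrt(1.0 - std::pow(b2, t));
  const double alpha = lr * bc2 / (1.0 - std::pow(b1, t));
  const double eps_t = eps * bc2;
  double *pw = REAL(w), *pg = REAL(g), *pm = REAL(m), *pv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = b1 * pm[i] + c1 * pg[i];
    const double vi = b2 * pv[i] + c2 * pg[i] * pg[i];
    pm[i] = mi;
    pv[i] = vi;
    pw[i] -= alpha * mi / (std::sqrt(vi) + eps_t);
  }
}
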