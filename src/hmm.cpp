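#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward over one sequence.
// B: T x K matrix of per-bin emission probabilities P(x_t | state k).
// Returns log-likelihood, gamma (T x K posterior), xi_sum (K x K expected
// transition counts summed over t) and gamma1 (posterior at t = 1).
// Per-bin scaling keeps everything in [0, 1]; the log-likelihood is the sum
// of log scale factors, so sequences of up to ~1e7 bins stay finite.
// Internally everything is laid out row-major (bin-contiguous) so the
// recursions stream through memory.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B) {
  const int T = B.nrow(), K = B.ncol();
  NumericMatrix gamma_out(T, K);
  NumericMatrix xi(K, K);
  NumericVector gamma1(K);

  if (T == 0) {
    return List::create(_["loglik"] = 0.0, _["gamma"] = gamma_out,
                        _["xi_sum"] = xi, _["gamma1"] = gamma1);
  }

  // row-major copies: b[t*K + k]
  std::vector<double> b((size_t)T * K), alpha((size_t)T * K),
      beta((size_t)T * K), a((size_t)K * K), scale(T);
  for (int k = 0; k < K; ++k) {
    const double *col = &B(0, k);
    for (int t = 0; t < T; ++t) b[(size_t)t * K + k] = col[t];
  }
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) a[(size_t)j * K + k] = A(j, k);

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi[k] * b[k]; s += alpha[k]; }
  if (s <= 0) stop("zero forward probability at bin 1");
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha[k] /= s;
  for (int t = 1; t < T; ++t) {
    const double *ap = &alpha[(size_t)(t - 1) * K];
    const double *bp = &b[(size_t)t * K];
    double *an = &alpha[(size_t)t * K];
    for (int k = 0; k < K; ++k) an[k] = 0.0;
    for (int j = 0; j < K; ++j) {
      const double aj = ap[j];
      const double *arow = &a[(size_t)j * K];
      for (int k = 0; k < K; ++k) an[k] += aj * arow[k];
    }
    s = 0.0;
    for (int k = 0; k < K; ++k) { an[k] *= bp[k]; s += an[k]; }
    if (s <= 0) stop("zero forward probability at bin %d", t + 1);
    scale[t] = s;
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k) an[k] *= inv;
  }

  // backward (same scale factors), xi accumulated on the fly
  std::vector<double> xi_acc((size_t)K * K, 0.0), bb(K);
  for (int k = 0; k < K; ++k) beta[(size_t)(T - 1) * K + k] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double *bn = &beta[(size_t)(t + 1) * K];
    const double *bp = &b[(size_t)(t + 1) * K];
    const double *ap = &alpha[(size_t)t * K];
    double *bt = &beta[(size_t)t * K];
    const double inv = 1.0 / scale[t + 1];
    for (int k = 0; k < K; ++k) bb[k] = bp[k] * bn[k] * inv;
    for (int j = 0; j < K; ++j) {
      const double *arow = &a[(size_t)j * K];
      double *xrow = &xi_acc[(size_t)j * K];
      double acc = 0.0;
      const double aj = ap[j];
      for (int k = 0; k < K; ++k) {
        const double term = arow[k] * bb[k];
        acc += term;
        xrow[k] += aj * term;
      }
      bt[j] = acc;
    }
  }

  // posteriors
  for (int t = 0; t < T; ++t) {
    const double *ap = &alpha[(size_t)t * K];
    const double *bp = &beta[(size_t)t * K];
    double g = 0.0;
    for (int k = 0; k < K; ++k) g += ap[k] * bp[k];
    const double inv = 1.0 / g;
    for (int k = 0; k < K; ++k) gamma_out(t, k) = ap[k] * bp[k] * inv;
  }
  for (int k = 0; k < K; ++k) gamma1[k] = gamma_out(0, k);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) xi(j, k) = xi_acc[(size_t)j * K + k];

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma_out,
                      _["xi_sum"] = xi, _["gamma1"] = gamma1);
}

// Viterbi decoding in log space. logB: T x K log emission probabilities.
// Ties break toward the lower state index (strict > comparisons with
// ascending scan). Returns 1-based state path.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericVector logpi, NumericMatrix logA,
                          NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  if (T == 0) return IntegerVector(0);
  std::vector<double> lb((size_t)T * K), la((size_t)K * K),
      prev(K), cur(K);
  std::vector<int> psi((size_t)T * K);
  for (int k = 0; k < K; ++k) {
    const double *col = &logB(0, k);
    for (int t = 0; t < T; ++t) lb[(size_t)t * K + k] = col[t];
  }
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) la[(size_t)j * K + k] = logA(j, k);

  for (int k = 0; k < K; ++k) prev[k] = logpi[k] + lb[k];
  for (int t = 1; t < T; ++t) {
    const double *bp = &lb[(size_t)t * K];
    int *ps = &psi[(size_t)t * K];
    for (int k = 0; k < K; ++k) {
      double best = prev[0] + la[k];
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        const double v = prev[j] + la[(size_t)j * K + k];
        if (v > best) { best = v; arg = j; }
      }
      cur[k] = best + bp[k];
      ps[k] = arg;
    }
    std::swap(prev, cur);
  }
  IntegerVector path(T);
  int arg = 0;
  double best = prev[0];
  for (int k = 1; k < K; ++k) if (prev[k] > best) { best = prev[k]; arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi[(size_t)(t + 1) * K + arg];
    path[t] = arg + 1;
  }
  return path;
}
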