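#include <Rcpp.h>
using namespace Rcpp;

// E-step for one group of a 2PL marginal-likelihood EM.
//
// X:     N x I integer response matrix, entries 0/1, NA_INTEGER for missing.
// theta: Q quadrature node locations on the latent scale for this group.
// logw:  Q log prior weights (normalized weights of the quadrature rule).
// a, d:  item discriminations and intercepts for this group.
//
// Returns the observed-data log-likelihood, the expected per-node counts
// nq (sum of posteriors over persons), the expected correct counts r (I x Q)
// and, when missing entries are present, expected exposure counts n (I x Q).
// Work arrays are Q-major so the inner loops stay cache-contiguous.
// [[Rcpp::export(name = ".estep_cpp")]]
List estep_cpp(IntegerMatrix X, NumericVector theta, NumericVector logw,
               NumericVector a, NumericVector d) {
  const int N = X.nrow(), I = X.ncol(), Q = theta.size();
  std::vector<double> logP((size_t)I * Q), log1mP((size_t)I * Q);
  for (int i = 0; i < I; ++i) {
    for (int q = 0; q < Q; ++q) {
      double eta = a[i] * theta[q] - d[i];
      double lp = (eta > 0) ? -log1p(std::exp(-eta)) : eta - log1p(std::exp(eta));
      logP[(size_t)i * Q + q] = lp;
      log1mP[(size_t)i * Q + q] = lp - eta;
    }
  }

  bool any_na = false;
  for (int idx = 0; idx < N * I && !any_na; ++idx)
    if (X[idx] == NA_INTEGER) any_na = true;

  NumericVector nq(Q);
  std::vector<double> racc((size_t)I * Q, 0.0);
  std::vector<double> nacc(any_na ? (size_t)I * Q : 0, 0.0);
  std::vector<double> lp(Q), post(Q);
  double loglik = 0.0;

  for (int p = 0; p < N; ++p) {
    for (int q = 0; q < Q; ++q) lp[q] = logw[q];
    for (int i = 0; i < I; ++i) {
      int x = X[(size_t)i * N + p];
      if (x == NA_INTEGER) continue;
      const double *row = (x == 1) ? &logP[(size_t)i * Q] : &log1mP[(size_t)i * Q];
      for (int q = 0; q < Q; ++q) lp[q] += row[q];
    }
    double m = lp[0];
    for (int q = 1; q < Q; ++q) if (lp[q] > m) m = lp[q];
    double s = 0.0;
    for (int q = 0; q < Q; ++q) { post[q] = std::exp(lp[q] - m); s += post[q]; }
    loglik += m + std::log(s);
    double inv = 1.0 / s;
    for (int q = 0; q < Q; ++q) { post[q] *= inv; nq[q] += post[q]; }
    for (int i = 0; i < I; ++i) {
      int x = X[(size_t)i * N + p];
      if (x == NA_INTEGER) continue;
      if (x == 1) {
        double *racc_i = &racc[(size_t)i * Q];
        for (int q = 0; q < Q; ++q) racc_i[q] += post[q];
      }
      if (any_na) {
        double *nacc_i = &nacc[(size_t)i * Q];
        for (int q = 0; q < Q; ++q) nacc_i[q] += post[q];
      }
    }
  }

  NumericMatrix r(I, Q);
  for (int i = 0; i < I; ++i)
    for (int q = 0; q < Q; ++q) r(i, q) = racc[(size_t)i * Q + q];
  List out = List::create(_["loglik"] = loglik, _["nq"] = nq, _["r"] = r);
  if (any_na) {
    NumericMatrix n(I, Q);
    for (int i = 0; i < I; ++i)
      for (int q = 0; q < Q; ++q) n(i, q) = nacc[(size_t)i * Q + q];
    out["n"] = n;
  } else {
    out["n"] = R_NilValue;
  }
  return out;
}
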