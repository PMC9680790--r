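#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward (sum-product on a chain factor graph).
//
// B[k,i]  = p(y_k | s_k = i)      (n x S emission likelihoods)
// Q[i,j]  = Pr(s_k = j | s_{k-1} = i)
// init[i] = p(s_1 = i)
//
// Messages are renormalized at every step so sequences of length up to 1e6
// run without underflow; the log normalizers sum to log p(y). xi_sum
// accumulates the pairwise posteriors summed over time, which is all the EM
// M-step needs. Full messages (alpha, beta, logc) are returned so short
// sequences can reconstruct the complete pairwise posterior.
//
// Internally the time dimension is kept innermost-contiguous (S-major per
// step) so the recursions stream through memory.
// [[Rcpp::export]]
List fb_core(NumericMatrix B, NumericMatrix Q, NumericVector init,
             bool keep_messages = false) {
  const int n = B.nrow(), S = B.ncol();
  if (Q.nrow() != S || Q.ncol() != S || init.size() != S)
    stop("dimension mismatch between emissions, transition matrix and init");

  // transposed copies: Bt[k*S + i], Qv row-major
  std::vector<double> Bt((size_t)n * S), Qv((size_t)S * S);
  const double *pB = REAL(B), *pQ = REAL(Q);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < S; ++i) Bt[(size_t)k * S + i] = pB[(size_t)i * n + k];
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) Qv[(size_t)i * S + j] = pQ[(size_t)j * S + i];

  std::vector<double> A((size_t)n * S), logc(n);
  double c = 0.0;
  for (int i = 0; i < S; ++i) { A[i] = init[i] * Bt[i]; c += A[i]; }
  if (c <= 0.0 || !R_finite(c))
    stop("zero likelihood at sample 1 (degenerate emission model)");
  for (int i = 0; i < S; ++i) A[i] /= c;
  logc[0] = std::log(c);

  for (int k = 1; k < n; ++k) {
    const double *ap = &A[(size_t)(k - 1) * S];
    const double *bk = &Bt[(size_t)k * S];
    double *an = &A[(size_t)k * S];
    c = 0.0;
    for (int j = 0; j < S; ++j) {
      double a = 0.0;
      for (int i = 0; i < S; ++i) a += ap[i] * Qv[(size_t)i * S + j];
      a *= bk[j];
      an[j] = a;
      c += a;
    }
    if (c <= 0.0 || !R_finite(c))
      stop("zero likelihood at sample %d (degenerate emission model)", k + 1);
    for (int j = 0; j < S; ++j) an[j] /= c;
    logc[k] = std::log(c);
  }

  NumericMatrix gamma(n, S), xi_sum(S, S), alpha(n, S);
  NumericMatrix beta_full;
  if (keep_messages) beta_full = NumericMatrix(n, S);
  double *pg = REAL(gamma), *pa = REAL(alpha);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < S; ++i) pa[(size_t)i * n + k] = A[(size_t)k * S + i];

  std::vector<double> beta(S, 1.0), bn(S), bb(S);
  std::vector<double> xiv((size_t)S * S, 0.0);
  for (int i = 0; i < S; ++i) {
    pg[(size_t)i * n + (n - 1)] = A[(size_t)(n - 1) * S + i];
    if (keep_messages) REAL(beta_full)[(size_t)i * n + (n - 1)] = 1.0;
  }
  for (int k = n - 2; k >= 0; --k) {
    const double ck1 = std::exp(logc[k + 1]);
    const double *bk1 = &Bt[(size_t)(k + 1) * S];
    const double *ap = &A[(size_t)k * S];
    for (int j = 0; j < S; ++j) bb[j] = bk1[j] * beta[j] / ck1;
    double gsum = 0.0;
    for (int i = 0; i < S; ++i) {
      const double *qr = &Qv[(size_t)i * S];
      double b = 0.0;
      for (int j = 0; j < S; ++j) b += qr[j] * bb[j];
      bn[i] = b;
      gsum += ap[i] * b;
    }
    for (int i = 0; i < S; ++i) pg[(size_t)i * n + k] = ap[i] * bn[i] / gsum;
    for (int i = 0; i < S; ++i) {
      const double ai = ap[i];
      if (ai == 0.0) continue;
      const double *qr = &Qv[(size_t)i * S];
      double *xr = &xiv[(size_t)i * S];
      for (int j = 0; j < S; ++j) xr[j] += ai * qr[j] * bb[j];
    }
    beta.swap(bn);
    if (keep_messages)
      for (int i = 0; i < S; ++i) REAL(beta_full)[(size_t)i * n + k] = beta[i];
  }

  double *px = REAL(xi_sum);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) px[(size_t)j * S + i] = xiv[(size_t)i * S + j];

  double ll = 0.0;
  for (int k = 0; k < n; ++k) ll += logc[k];

  List out = List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                          _["loglik"] = ll, _["logc"] = wrap(logc),
                          _["alpha"] = alpha);
  if (keep_messages) out["beta"] = beta_full;
  return out;
}

// Sample a discrete-time Markov chain of length n from transition matrix Q
// starting from init. Uses R's RNG so set.seed() controls reproducibility.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector sample_states_cpp(NumericMatrix Q, int n, NumericVector init) {
  const int S = Q.ncol();
  if (Q.nrow() != S || init.size() != S)
    stop("dimension mismatch between transition matrix and init");
  IntegerVector out(n);

  std::vector<double> cum((size_t)S * S);
  for (int i = 0; i < S; ++i) {
    double acc = 0.0;
    for (int j = 0; j < S; ++j) {
      acc += Q(i, j);
      cum[(size_t)i * S + j] = acc;
    }
  }
  std::vector<double> cinit(S);
  double acc = 0.0;
  for (int i = 0; i < S; ++i) {
    acc += init[i];
    cinit[i] = acc;
  }

  double u = unif_rand();
  int s = 0;
  while (s < S - 1 && u > cinit[s]) ++s;
  out[0] = s + 1;
  for (int k = 1; k < n; ++k) {
    u = unif_rand();
    const double *row = &cum[(size_t)s * S];
    int j = 0;
    while (j < S - 1 && u > row[j]) ++j;
    s = j;
    out[k] = s + 1;
  }
  return out;
}
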