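// Multiplicative-update NMF for the Frobenius objective ||M - P E||_F^2.
// The update rules keep P and E nonnegative and make the objective
// non-increasing; denominators are floored at machine epsilon.
//
// The inner loop is written with explicit dot/axpy-style loops over
// preallocated buffers: the factor ranks are small (N ~ 10), where generic
// BLAS gemm calls spend most of their time on dispatch overhead, and this
// loop runs for tens of thousands of iterations per bootstrap replicate.
// Hot kernels are cloned for newer vector units with runtime dispatch, so
// the binary stays portable across x86-64 levels.
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

#if defined(__GNUC__) && !defined(__clang__)
// the toolchain's default -O2 cost model declines to vectorize the
// variable-length reductions below; this unit is pure numeric kernels
#pragma GCC optimize("O3")
#endif

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define NMF_CLONES __attribute__((target_clones("arch=haswell", "default")))
#else
#define NMF_CLONES
#endif

// C[r x c] = A[k x r]' * B[k x c], column-major, contiguous dot products;
// four output rows are accumulated per pass so the reduction chains are
// independent and pipeline
NMF_CLONES
static void crossdot(const double* A, const double* B, double* C,
                     int k, int r, int c) {
  for (int j = 0; j < c; ++j) {
    const double* bj = B + (size_t)j * k;
    int i = 0;
    for (; i + 4 <= r; i += 4) {
      const double* a0 = A + (size_t)i * k;
      const double* a1 = a0 + k;
      const double* a2 = a1 + k;
      const double* a3 = a2 + k;
      double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
#pragma omp simd reduction(+ : s0, s1, s2, s3)
      for (int t = 0; t < k; ++t) {
        const double b = bj[t];
        s0 += a0[t] * b;
        s1 += a1[t] * b;
        s2 += a2[t] * b;
        s3 += a3[t] * b;
      }
      double* cj = C + (size_t)j * r + i;
      cj[0] = s0; cj[1] = s1; cj[2] = s2; cj[3] = s3;
    }
    for (; i < r; ++i) {
      const double* ai = A + (size_t)i * k;
      double s = 0.0;
#pragma omp simd reduction(+ : s)
      for (int t = 0; t < k; ++t) s += ai[t] * bj[t];
      C[(size_t)j * r + i] = s;
    }
  }
}

// E <- E .* (P'M) ./ max(P'P E, eps); PtP, PtM already computed
NMF_CLONES
static void update_E(double* e, const double* PtP, const double* PtM,
                     double* denomE, int N, int G, double eps) {
  for (int g = 0; g < G; ++g) {
    double* dg = denomE + (size_t)g * N;
    const double* eg = e + (size_t)g * N;
    for (int n = 0; n < N; ++n) {
      double s = 0.0;
      const double* row = PtP + n;  // PtP[n, j], stride N
      for (int j = 0; j < N; ++j) s += row[(size_t)j * N] * eg[j];
      dg[n] = s < eps ? eps : s;
    }
  }
  for (size_t i = 0; i < (size_t)N * G; ++i) e[i] *= PtM[i] / denomE[i];
}

// P <- P .* (M E') ./ max(P E E', eps)
NMF_CLONES
static void update_P(double* p, const double* m, const double* e,
                     double* MEt, double* EEt, double* denomP,
                     int K, int N, int G, double eps) {
  std::fill(EEt, EEt + (size_t)N * N, 0.0);
  std::fill(MEt, MEt + (size_t)K * N, 0.0);
  for (int g = 0; g < G; ++g) {
    const double* eg = e + (size_t)g * N;
    const double* mg = m + (size_t)g * K;
    for (int n = 0; n < N; ++n) {
      const double w = eg[n];
      if (w == 0.0) continue;
      double* col = MEt + (size_t)n * K;
#pragma omp simd
      for (int k = 0; k < K; ++k) col[k] += w * mg[k];
      double* ee = EEt + (size_t)n * N;
      for (int j = 0; j < N; ++j) ee[j] += w * eg[j];
    }
  }
  for (int n = 0; n < N; ++n) {
    double* col = denomP + (size_t)n * K;
    std::fill(col, col + K, 0.0);
    const double* ee = EEt + (size_t)n * N;
    for (int j = 0; j < N; ++j) {
      const double w = ee[j];
      const double* pj = p + (size_t)j * K;
#pragma omp simd
      for (int k = 0; k < K; ++k) col[k] += w * pj[k];
    }
    for (int k = 0; k < K; ++k) if (col[k] < eps) col[k] = eps;
  }
  for (size_t i = 0; i < (size_t)K * N; ++i) p[i] *= MEt[i] / denomP[i];
}

NMF_CLONES
static double objective(const double* m, const double* p, const double* e,
                        double* pe, int K, int N, int G) {
  double s = 0.0;
  for (int g = 0; g < G; ++g) {
    std::fill(pe, pe + K, 0.0);
    for (int n = 0; n < N; ++n) {
      const double w = e[(size_t)g * N + n];
      const double* pn = p + (size_t)n * K;
#pragma omp simd
      for (int k = 0; k < K; ++k) pe[k] += w * pn[k];
    }
    const double* mg = m + (size_t)g * K;
    double sg = 0.0;
#pragma omp simd reduction(+ : sg)
    for (int k = 0; k < K; ++k) {
      const double d = mg[k] - pe[k];
      sg += d * d;
    }
    s += sg;
  }
  return s;
}

// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& M, arma::mat P, arma::mat E,
                      int max_iter, int conv_window, double conv_tol,
                      int check_every) {
  const double eps = arma::datum::eps;
  const int K = M.n_rows, G = M.n_cols, N = P.n_cols;
  const int lag = std::max(1, conv_window / check_every);

  std::vector<double> PtP((size_t)N * N), PtM((size_t)N * G),
      denomE((size_t)N * G), EEt((size_t)N * N), MEt((size_t)K * N),
      denomP((size_t)K * N), pe(K);
  const double* m = M.memptr();
  double* p = P.memptr();
  double* e = E.memptr();

  std::vector<double> trace_obj;
  std::vector<int> trace_iter;
  trace_obj.reserve(max_iter / check_every + 2);
  trace_iter.reserve(max_iter / check_every + 2);

  trace_obj.push_back(objective(m, p, e, pe.data(), K, N, G));
  trace_iter.push_back(0);

  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    crossdot(p, p, PtP.data(), K, N, N);
    crossdot(p, m, PtM.data(), K, N, G);
    update_E(e, PtP.data(), PtM.data(), denomE.data(), N, G, eps);
    update_P(p, m, e, MEt.data(), EEt.data(), denomP.data(), K, N, G, eps);

    if (it % check_every == 0 || it == max_iter) {
      const double obj = objective(m, p, e, pe.data(), K, N, G);
      trace_obj.push_back(obj);
      trace_iter.push_back(it);
      const int kk = (int)trace_obj.size() - 1;
      if (kk >= lag) {
        const double ref = trace_obj[kk - lag];
        if (ref - obj < conv_tol * std::max(ref, eps)) {
          converged = true;
          break;
        }
      }
      if (it % (check_every * 200) == 0) Rcpp::checkUserInterrupt();
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("P") = P,
    Rcpp::Named("E") = E,
    Rcpp::Named("trace_iter") = trace_iter,
    Rcpp::Named("trace_obj") = trace_obj,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
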