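// Hot inner loops of the transformer decomposer: time-delay aggregation of
// autocorrelation attention (forward and backward) and the replicate-padded
// moving average with its adjoint. Activations are (L, B, d) arrays in R's
// column-major layout. The R-level finite-difference gradient test exercises
// all of these.
#include <Rcpp.h>
using namespace Rcpp;

// Out[t,b,c] = sum_i wts(i,b) * V[(t + tau_ib) mod L, b, c], tau = idx - 1
// [[Rcpp::export]]
NumericVector agg_fwd_cpp(NumericVector V, IntegerMatrix idx,
                          NumericMatrix wts) {
  IntegerVector dims = V.attr("dim");
  int L = dims[0], B = dims[1], d = dims[2];
  int k = idx.nrow();
  NumericVector Out(static_cast<R_xlen_t>(L) * B * d);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < k; ++i) {
      int tau = idx(i, b) - 1;
      double w = wts(i, b);
      for (int c = 0; c < d; ++c) {
        const double* v = &V[(static_cast<size_t>(c) * B + b) * L];
        double* o = &Out[(static_cast<size_t>(c) * B + b) * L];
        int s = tau;
        for (int t = 0; t < L; ++t) {
          o[t] += w * v[s];
          if (++s == L) s = 0;
        }
      }
    }
  }
  Out.attr("dim") = dims;
  return Out;
}

// Backward of the aggregation + softmax-weighted delay scores.
// Returns dQ, dK, dV given upstream dOut; norm = 1/(L*d) is the scale of
// the channel-averaged circular correlation.
// [[Rcpp::export]]
List agg_bwd_cpp(NumericVector Q, NumericVector K, NumericVector V,
                 NumericVector dOut, IntegerMatrix idx, NumericMatrix wts,
                 double norm) {
  IntegerVector dims = V.attr("dim");
  int L = dims[0], B = dims[1], d = dims[2];
  int k = idx.nrow();
  R_xlen_t n = static_cast<R_xlen_t>(L) * B * d;
  NumericVector dQ(n), dK(n), dV(n);
  std::vector<double> dw(k);
  for (int b = 0; b < B; ++b) {
    // dw_i = <dOut_b, roll(V_b, tau_i)>; dV accumulates the weighted rolls
    for (int i = 0; i < k; ++i) {
      int tau = idx(i, b) - 1;
      double w = wts(i, b), acc = 0.0;
      for (int c = 0; c < d; ++c) {
        const double* v = &V[(static_cast<size_t>(c) * B + b) * L];
        const double* g = &dOut[(static_cast<size_t>(c) * B + b) * L];
        double* dv = &dV[(static_cast<size_t>(c) * B + b) * L];
        int s = tau;
        for (int t = 0; t < L; ++t) {
          acc += g[t] * v[s];
          dv[s] += w * g[t];
          if (++s == L) s = 0;
        }
      }
      dw[i] = acc;
    }
    double wsum = 0.0;
    for (int i = 0; i < k; ++i) wsum += wts(i, b) * dw[i];
    for (int i = 0; i < k; ++i) {
      double da = wts(i, b) * (dw[i] - wsum) * norm;   // softmax backward
      if (da == 0.0) continue;
      int tau = idx(i, b) - 1;
      for (int c = 0; c < d; ++c) {
        const double* q = &Q[(static_cast<size_t>(c) * B + b) * L];
        const double* kk = &K[(static_cast<size_t>(c) * B + b) * L];
        double* dq = &dQ[(static_cast<size_t>(c) * B + b) * L];
        double* dk = &dK[(static_cast<size_t>(c) * B + b) * L];
        int s = tau;
        for (int t = 0; t < L; ++t) {
          dq[t] += da * kk[s];
          dk[s] += da * q[t];
          if (++s == L) s = 0;
        }
      }
    }
  }
  dQ.attr("dim") = dims;
  dK.attr("dim") = dims;
  dV.attr("dim") = dims;
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// centered moving average along columns, replicate padding
// [[Rcpp::export]]
NumericMatrix ma_cols_cpp(NumericMatrix M, int window) {
  int n = M.nrow(), m = M.ncol();
  int hl = (window - 1) / 2, hr = window - 1 - hl;
  NumericMatrix Y(n, m);
  for (int j = 0; j < m; ++j) {
    const double* x = &M(0, j);
    double* y = &Y(0, j);
    double run = hl * x[0];        // left replicate pad
    for (int s = 0; s < window - hl; ++s) run += x[std::min(s, n - 1)];
    y[0] = run / window;
    for (int t = 1; t < n; ++t) {
      int add = t + hr, drop = t - hl - 1;
      run += x[add >= n ? n - 1 : add] - x[drop < 0 ? 0 : drop];
      y[t] = run / window;
    }
  }
  return Y;
}

// adjoint of ma_cols_cpp as a linear operator
// [[Rcpp::export]]
NumericMatrix ma_cols_adjoint_cpp(NumericMatrix G, int window) {
  int n = G.nrow(), m = G.ncol();
  int hl = (window - 1) / 2, hr = window - 1 - hl;
  NumericMatrix X(n, m);
  std::vector<double> gp(n + window - 1);
  std::vector<double> cs(n + 1);
  for (int j = 0; j < m; ++j) {
    const double* g = &G(0, j);
    double* x = &X(0, j);
    cs[0] = 0.0;
    for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + g[t];
    // gp[s] = (1/window) * sum of g[t] for windows t covering padded pos s
    for (int s = 0; s < n + window - 1; ++s) {
      int lo = std::max(0, s - window + 1), hi = std::min(n - 1, s);
      gp[s] = (cs[hi + 1] - cs[lo]) / window;
    }
    for (int t = 0; t < n; ++t) x[t] = gp[hl + t];
    for (int s = 0; s < hl; ++s) x[0] += gp[s];
    for (int s = hl + n; s < n + window - 1; ++s) x[n - 1] += gp[s];
  }
  return X;
}
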