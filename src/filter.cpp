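#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward filter for a hidden Markov chain observed through fixed
// per-frame emission densities. G is T x n (rows: frames, cols: states),
// worm_start holds the 0-based first frame of each worm; the filter is
// re-initialized at the stationary distribution Pinf at each worm start.
// Returns the total log-likelihood sum_t log(P_pred(t) . G(t)).
// [[Rcpp::export]]
double cpp_filter_loglik(const NumericMatrix& G,
                         const IntegerVector& worm_start,
                         const NumericMatrix& M,
                         const NumericVector& Pinf) {
  const int T = G.nrow(), n = G.ncol(), W = worm_start.size();
  std::vector<double> P(n), Pn(n);
  double lnL = 0.0;
  int w = 0;
  for (int t = 0; t < T; ++t) {
    if (w < W && t == worm_start[w]) {
      for (int j = 0; j < n; ++j) P[j] = Pinf[j];
      ++w;
    } else {
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += P[i] * M(i, j);
        Pn[j] = acc;
      }
      std::copy(Pn.begin(), Pn.end(), P.begin());
    }
    double c = 0.0;
    for (int j = 0; j < n; ++j) {
      P[j] *= G(t, j);
      c += P[j];
    }
    if (c <= 0.0 || !std::isfinite(c)) return R_NegInf;
    for (int j = 0; j < n; ++j) P[j] /= c;
    lnL += std::log(c);
  }
  return lnL;
}

// Filtered posteriors and per-frame log normalizers for one worm.
// [[Rcpp::export]]
List cpp_filter_posterior(const NumericMatrix& G,
                          const NumericMatrix& M,
                          const NumericVector& Pinf) {
  const int T = G.nrow(), n = G.ncol();
  NumericMatrix post(T, n);
  NumericVector logc(T);
  std::vector<double> P(Pinf.begin(), Pinf.end()), Pn(n);
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += P[i] * M(i, j);
        Pn[j] = acc;
      }
      std::copy(Pn.begin(), Pn.end(), P.begin());
    }
    double c = 0.0;
    for (int j = 0; j < n; ++j) { P[j] *= G(t, j); c += P[j]; }
    if (c <= 0.0 || !std::isfinite(c)) stop("zero likelihood at frame %d", t + 1);
    for (int j = 0; j < n; ++j) { P[j] /= c; post(t, j) = P[j]; }
    logc[t] = std::log(c);
  }
  return List::create(_["posterior"] = post, _["log_c"] = logc);
}

// Viterbi decoding (log domain); ties break toward the lower state index.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(const NumericMatrix& logG,
                          const NumericMatrix& logM,
                          const NumericVector& logPinf) {
  const int T = logG.nrow(), n = logG.ncol();
  NumericMatrix delta(T, n);
  IntegerMatrix psi(T, n);
  for (int j = 0; j < n; ++j) delta(0, j) = logPinf[j] + logG(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < n; ++i) {
        double cand = delta(t - 1, i) + logM(i, j);
        if (cand > best) { best = cand; arg = i; }
      }
      delta(t, j) = best + logG(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int j = 0; j < n; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// Forward-Backward smoothing (scaled) for one worm.
// [[Rcpp::export]]
NumericMatrix cpp_forward_backward(const NumericMatrix& G,
                                   const NumericMatrix& M,
                                   const NumericVector& Pinf) {
  const int T = G.nrow(), n = G.ncol();
  NumericMatrix alpha(T, n), beta(T, n), post(T, n);
  NumericVector c(T);
  // forward
  double acc = 0.0;
  for (int j = 0; j < n; ++j) { alpha(0, j) = Pinf[j] * G(0, j); acc += alpha(0, j); }
  if (acc <= 0.0) stop("zero likelihood at frame 1");
  c[0] = acc;
  for (int j = 0; j < n; ++j) alpha(0, j) /= acc;
  for (int t = 1; t < T; ++t) {
    acc = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = 0.0;
      for (int i = 0; i < n; ++i) a += alpha(t - 1, i) * M(i, j);
      alpha(t, j) = a * G(t, j);
      acc += alpha(t, j);
    }
    if (acc <= 0.0) stop("zero likelihood at frame %d", t + 1);
    c[t] = acc;
    for (int j = 0; j < n; ++j) alpha(t, j) /= acc;
  }
  // backward
  for (int j = 0; j < n; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < n; ++i) {
      double b = 0.0;
      for (int j = 0; j < n; ++j) b += M(i, j) * G(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) { post(t, j) = alpha(t, j) * beta(t, j); s += post(t, j); }
    for (int j = 0; j < n; ++j) post(t, j) /= s;
  }
  return post;
}

// Draw a state sequence from the per-frame transition matrix M using
// pre-drawn uniforms (so all randomness flows through R's RNG).
// init and the returned states are 1-based.
// [[Rcpp::export]]
IntegerVector cpp_simulate_states(const NumericMatrix& M, int n_frames,
                                  int init, const NumericVector& u) {
  const int n = M.nrow();
  IntegerVector out(n_frames);
  int s = init - 1;
  out[0] = init;
  for (int t = 1; t < n_frames; ++t) {
    double r = u[t - 1], acc = 0.0;
    int nxt = n - 1;
    for (int j = 0; j < n; ++j) {
      acc += M(s, j);
      if (r <= acc) { nxt = j; break; }
    }
    s = nxt;
    out[t] = s + 1;
  }
  return out;
}
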