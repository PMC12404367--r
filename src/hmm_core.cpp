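#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward (optionally forward-backward) recursion over independent
// track segments.
//
// ldens : T x K matrix of per-step emission log-densities
// trans : K x K x T array; trans(.,.,t) is the transition matrix applied
//         between step t and t+1 (row-stochastic); the entry at the last
//         step of each segment is unused
// seg   : integer segment id per step; steps of a segment are contiguous
// delta : nseg x K matrix of initial state distributions, one row per
//         segment (rows indexed by order of first appearance)
//
// Returns log-likelihood and, if want_post, the posterior state
// probabilities P(S_t = k | data) ("gamma" of Baum-Welch).
// [[Rcpp::export(name = ".hmmForwardCpp")]]
List hmmForwardCpp(NumericMatrix ldens, NumericVector trans,
                   IntegerVector seg, NumericMatrix delta,
                   bool want_post) {
  const int T = ldens.nrow(), K = ldens.ncol();
  IntegerVector tdim = trans.attr("dim");
  if (tdim[0] != K || tdim[1] != K || tdim[2] != T)
    stop("transition array dimension mismatch");
  std::vector<double> w(T * K), e(T * K), cvec(T), mvec(T);
  double loglik = 0.0;
  int segrow = -1, prev_seg = INT_MIN;

  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) m = std::max(m, ldens(t, k));
    if (!R_finite(m)) {
      // all-states -Inf emission: impossible observation
      if (m == R_NegInf) return List::create(_["loglik"] = R_NegInf);
      stop("non-finite emission log-density at step %d", t + 1);
    }
    mvec[t] = m;
    for (int k = 0; k < K; ++k) e[t * K + k] = std::exp(ldens(t, k) - m);

    double c = 0.0;
    if (seg[t] != prev_seg) {           // segment start
      prev_seg = seg[t];
      ++segrow;
      for (int k = 0; k < K; ++k) {
        double a = delta(segrow, k) * e[t * K + k];
        w[t * K + k] = a; c += a;
      }
    } else {
      const double* G = &trans[(size_t)(t - 1) * K * K];
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += w[(t - 1) * K + j] * G[j + k * K];
        a *= e[t * K + k];
        w[t * K + k] = a; c += a;
      }
    }
    if (c <= 0.0 || !R_finite(c)) return List::create(_["loglik"] = R_NegInf);
    for (int k = 0; k < K; ++k) w[t * K + k] /= c;
    cvec[t] = c;
    loglik += std::log(c) + m;
  }

  if (!want_post) return List::create(_["loglik"] = loglik);

  // scaled backward pass and posteriors
  NumericMatrix post(T, K);
  std::vector<double> b(K), bnew(K);
  for (int t = T - 1; t >= 0; --t) {
    bool seg_end = (t == T - 1) || (seg[t + 1] != seg[t]);
    if (seg_end) {
      for (int k = 0; k < K; ++k) b[k] = 1.0;
    } else {
      const double* G = &trans[(size_t)t * K * K];
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k)
          s += G[j + k * K] * e[(t + 1) * K + k] * b[k];
        bnew[j] = s / cvec[t + 1];
      }
      b = bnew;
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += w[t * K + k] * b[k];
    for (int k = 0; k < K; ++k) post(t, k) = w[t * K + k] * b[k] / tot;
  }
  return List::create(_["loglik"] = loglik, _["post"] = post);
}

// Viterbi decoding (max-product in log space); ties broken toward the
// lower state index.
// [[Rcpp::export(name = ".hmmViterbiCpp")]]
IntegerVector hmmViterbiCpp(NumericMatrix ldens, NumericVector trans,
                            IntegerVector seg, NumericMatrix delta) {
  const int T = ldens.nrow(), K = ldens.ncol();
  IntegerVector tdim = trans.attr("dim");
  if (tdim[0] != K || tdim[1] != K || tdim[2] != T)
    stop("transition array dimension mismatch");
  std::vector<double> v(T * K);
  std::vector<int> back(T * K);
  IntegerVector path(T);
  int segrow = -1, prev_seg = INT_MIN;

  for (int t = 0; t < T; ++t) {
    if (seg[t] != prev_seg) {
      prev_seg = seg[t]; ++segrow;
      for (int k = 0; k < K; ++k) {
        v[t * K + k] = std::log(delta(segrow, k)) + ldens(t, k);
        back[t * K + k] = -1;
      }
    } else {
      const double* G = &trans[(size_t)(t - 1) * K * K];
      for (int k = 0; k < K; ++k) {
        double best = R_NegInf; int arg = 0;
        for (int j = 0; j < K; ++j) {
          double cand = v[(t - 1) * K + j] + std::log(G[j + k * K]);
          if (cand > best) { best = cand; arg = j; }  // strict: ties keep lower j
        }
        v[t * K + k] = best + ldens(t, k);
        back[t * K + k] = arg;
      }
    }
  }
  // trace back segment by segment
  int t = T - 1;
  while (t >= 0) {
    int s0 = t;
    while (s0 > 0 && seg[s0 - 1] == seg[t]) --s0;
    double best = R_NegInf; int arg = 0;
    for (int k = 0; k < K; ++k)
      if (v[t * K + k] > best) { best = v[t * K + k]; arg = k; }
    path[t] = arg + 1;
    for (int u = t; u > s0; --u) {
      path[u - 1] = back[u * K + path[u] - 1] + 1;
    }
    t = s0 - 1;
  }
  return path;
}
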