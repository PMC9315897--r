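#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

// Restricted Damerau-Levenshtein (optimal string alignment) distance.
// Returns min(distance, cap + 1) so callers can use `cap` as an early-exit
// threshold. Operates on bytes; matching always runs on normalized
// (ASCII-folded) strings so byte == character here.
static int osa_dist(const std::string &a, const std::string &b, int cap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > cap) return cap + 1;
  if (n == 0) return std::min(m, cap + 1);
  if (m == 0) return std::min(n, cap + 1);

  std::vector<int> prev2(m + 1), prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    for (int j = 1; j <= m; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, prev2[j - 2] + 1);
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > cap) return cap + 1;
    prev2.swap(prev);
    prev.swap(cur);
  }
  return std::min(prev[m], cap + 1);
}

// [[Rcpp::export]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b, int cap) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  if (cap < 0) cap = 1000000;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string sa = as<std::string>(a[i]);
    const std::string sb = as<std::string>(b[i]);
    out[i] = osa_dist(sa, sb, cap);
  }
  return out;
}

// All (candidate, surface) pairs within the allowed edit distance.
// Surfaces shorter than min_fuzzy_nchar must match exactly.
// [[Rcpp::export]]
DataFrame fuzzy_pairs_cpp(CharacterVector candidates, CharacterVector surfaces,
                          int max_edits, int min_fuzzy_nchar) {
  std::vector<std::string> cand(candidates.size()), surf(surfaces.size());
  for (R_xlen_t i = 0; i < candidates.size(); ++i)
    cand[i] = as<std::string>(candidates[i]);
  for (R_xlen_t j = 0; j < surfaces.size(); ++j)
    surf[j] = as<std::string>(surfaces[j]);

  std::vector<int> ci, si, di;
  for (size_t i = 0; i < cand.size(); ++i) {
    for (size_t j = 0; j < surf.size(); ++j) {
      const int allowed =
          ((int)surf[j].size() < min_fuzzy_nchar) ? 0 : max_edits;
      if (std::abs((int)cand[i].size() - (int)surf[j].size()) > allowed)
        continue;
      const int d = osa_dist(cand[i], surf[j], allowed);
      if (d <= allowed) {
        ci.push_back((int)i + 1);
        si.push_back((int)j + 1);
        di.push_back(d);
      }
    }
  }
  return DataFrame::create(_["cand_idx"] = ci, _["surf_idx"] = si,
                           _["dist"] = di);
}

static inline double logsumexp(const std::vector<double> &v) {
  double mx = v[0];
  for (double x : v)
    if (x > mx) mx = x;
  if (!std::isfinite(mx)) return mx;
  double s = 0.0;
  for (double x : v) s += std::exp(x - mx);
  return mx + std::log(s);
}

// Weight layout: emission[f, y] = w[(f-1)*nlab + (y-1)],
// transition[y1, y2] = w[nfeat*nlab + (y1-1)*nlab + (y2-1)].

// Node scores for one sentence: T x nlab.
static void node_scores(const List &feats, const NumericVector &w, int nlab,
                        std::vector<std::vector<double> > &s) {
  const int T = feats.size();
  s.assign(T, std::vector<double>(nlab, 0.0));
  for (int t = 0; t < T; ++t) {
    IntegerVector fv = feats[t];
    for (int k = 0; k < fv.size(); ++k) {
      const int off = (fv[k] - 1) * nlab;
      for (int y = 0; y < nlab; ++y) s[t][y] += w[off + y];
    }
  }
}

// Regularized negative log-likelihood and gradient over a corpus of
// sentences. feats: list of sentences, each a list of integer feature-id
// vectors per token; labels: list of integer label vectors (1-based).
// [[Rcpp::export]]
List crf_nll_grad_cpp(List feats, List labels, NumericVector w, int nfeat,
                      int nlab, double lambda) {
  const int S = feats.size();
  NumericVector grad(w.size());
  double nll = 0.0;
  const int troff = nfeat * nlab;

  for (int snt = 0; snt < S; ++snt) {
    List sf = feats[snt];
    IntegerVector sy = labels[snt];
    const int T = sf.size();
    if (T == 0) continue;

    std::vector<std::vector<double> > s;
    node_scores(sf, w, nlab, s);

    // forward
    std::vector<std::vector<double> > alpha(T, std::vector<double>(nlab));
    for (int y = 0; y < nlab; ++y) alpha[0][y] = s[0][y];
    std::vector<double> tmp(nlab);
    for (int t = 1; t < T; ++t) {
      for (int y = 0; y < nlab; ++y) {
        for (int yp = 0; yp < nlab; ++yp)
          tmp[yp] = alpha[t - 1][yp] + w[troff + yp * nlab + y];
        alpha[t][y] = s[t][y] + logsumexp(tmp);
      }
    }
    const double logZ = logsumexp(alpha[T - 1]);

    // backward
    std::vector<std::vector<double> > beta(T, std::vector<double>(nlab, 0.0));
    for (int t = T - 2; t >= 0; --t) {
      for (int y = 0; y < nlab; ++y) {
        for (int yn = 0; yn < nlab; ++yn)
          tmp[yn] = w[troff + y * nlab + yn] + s[t + 1][yn] + beta[t + 1][yn];
        beta[t][y] = logsumexp(tmp);
      }
    }

    // gold score
    double gold = 0.0;
    for (int t = 0; t < T; ++t) {
      gold += s[t][sy[t] - 1];
      if (t > 0) gold += w[troff + (sy[t - 1] - 1) * nlab + (sy[t] - 1)];
    }
    nll += logZ - gold;

    // node marginals -> emission gradient (expected - empirical)
    for (int t = 0; t < T; ++t) {
      IntegerVector fv = sf[t];
      for (int y = 0; y < nlab; ++y) {
        const double p = std::exp(alpha[t][y] + beta[t][y] - logZ);
        const double delta = p - ((sy[t] - 1 == y) ? 1.0 : 0.0);
        if (delta == 0.0) continue;
        for (int k = 0; k < fv.size(); ++k)
          grad[(fv[k] - 1) * nlab + y] += delta;
      }
    }
    // edge marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      for (int y1 = 0; y1 < nlab; ++y1) {
        for (int y2 = 0; y2 < nlab; ++y2) {
          const double lp = alpha[t - 1][y1] + w[troff + y1 * nlab + y2] +
                            s[t][y2] + beta[t][y2] - logZ;
          double delta = std::exp(lp);
          if (sy[t - 1] - 1 == y1 && sy[t] - 1 == y2) delta -= 1.0;
          grad[troff + y1 * nlab + y2] += delta;
        }
      }
    }
  }

  // L2 regularization
  double reg = 0.0;
  for (R_xlen_t i = 0; i < w.size(); ++i) {
    reg += w[i] * w[i];
    grad[i] += lambda * w[i];
  }
  nll += 0.5 * lambda * reg;

  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// Viterbi decode for one sentence; returns 1-based label ids.
// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(List feats, NumericVector w, int nfeat,
                              int nlab) {
  const int T = feats.size();
  if (T == 0) return IntegerVector(0);
  const int troff = nfeat * nlab;

  std::vector<std::vector<double> > s;
  node_scores(feats, w, nlab, s);

  std::vector<std::vector<double> > delta(T, std::vector<double>(nlab));
  std::vector<std::vector<int> > psi(T, std::vector<int>(nlab, 0));
  for (int y = 0; y < nlab; ++y) delta[0][y] = s[0][y];
  for (int t = 1; t < T; ++t) {
    for (int y = 0; y < nlab; ++y) {
      double best = -INFINITY;
      int arg = 0;
      for (int yp = 0; yp < nlab; ++yp) {
        const double v = delta[t - 1][yp] + w[troff + yp * nlab + y];
        if (v > best) {  // strict: ties resolve to the lowest label id
          best = v;
          arg = yp;
        }
      }
      delta[t][y] = best + s[t][y];
      psi[t][y] = arg;
    }
  }
  IntegerVector out(T);
  int best_y = 0;
  double best = -INFINITY;
  for (int y = 0; y < nlab; ++y)
    if (delta[T - 1][y] > best) {
      best = delta[T - 1][y];
      best_y = y;
    }
  out[T - 1] = best_y + 1;
  for (int t = T - 1; t > 0; --t) {
    best_y = psi[t][best_y];
    out[t - 1] = best_y + 1;
  }
  return out;
}
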