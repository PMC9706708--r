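#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for finite profile-mixture models.
//
// Two kernels share the same traversal:
//  * plik_f81: Poisson (equal) exchangeabilities, where each category's
//    process is F81 with profile pi_c and transition probabilities
//    P_ij(t) = e^{-beta t} delta_ij + (1 - e^{-beta t}) pi_j,
//    beta = 1 / (1 - sum pi^2). The matrix-vector product collapses to an
//    O(k) update per pattern.
//  * plik_pmat: arbitrary reversible exchangeabilities with per-edge,
//    per-(category,rate) transition matrices precomputed in R.
//
// Tips are coded 0..k-1, or k for missing (partial vector of ones).
// Edges arrive in postorder (children before parents); node indices are
// 0-based with tips first, so partial-likelihood storage covers internal
// nodes only. Per-pattern log-likelihoods are returned after a log-sum-exp
// over categories and rates.

// [[Rcpp::export]]
NumericVector plik_f81(IntegerMatrix tips, IntegerVector edge_child,
                       IntegerVector edge_parent, int n_nodes, int root,
                       NumericVector blen, NumericMatrix profiles,
                       NumericVector log_weights, NumericVector rates) {
  const int n_tip = tips.nrow();
  const int n_pat = tips.ncol();
  const int n_edge = edge_child.size();
  const int n_int = n_nodes - n_tip;
  const int C = profiles.nrow();
  const int k = profiles.ncol();
  const int G = rates.size();
  const int n_combo = C * G;
  const double log_g = -std::log((double)G);

  NumericMatrix combo_log(n_combo, n_pat);
  std::vector<double> L((size_t)n_int * k * n_pat);
  std::vector<double> scale_log((size_t)n_int * n_pat);
  std::vector<double> prof_col(k);

  for (int c = 0; c < C; ++c) {
    double ssq = 0.0;
    for (int i = 0; i < k; ++i) {
      prof_col[i] = profiles(c, i);
      ssq += prof_col[i] * prof_col[i];
    }
    const double beta = 1.0 / (1.0 - ssq);
    for (int g = 0; g < G; ++g) {
      const double r = rates[g];
      std::fill(L.begin(), L.end(), 1.0);
      std::fill(scale_log.begin(), scale_log.end(), 0.0);
      for (int e = 0; e < n_edge; ++e) {
        const int child = edge_child[e];
        const int parent = edge_parent[e] - n_tip;
        const double eb = std::exp(-beta * r * blen[e]);
        double* Lp = &L[(size_t)parent * k * n_pat];
        double* sp = &scale_log[(size_t)parent * n_pat];
        if (child < n_tip) {
          for (int p = 0; p < n_pat; ++p) {
            const int x = tips(child, p);
            if (x >= k) continue; // missing: multiply by ones
            const double base = (1.0 - eb) * prof_col[x];
            double* col = Lp + (size_t)p * k;
            for (int i = 0; i < k; ++i) col[i] *= (i == x) ? base + eb : base;
          }
        } else {
          const int ci = child - n_tip;
          const double* Lc = &L[(size_t)ci * k * n_pat];
          double* sc = &scale_log[(size_t)ci * n_pat];
          for (int p = 0; p < n_pat; ++p) {
            const double* colc = Lc + (size_t)p * k;
            double dot = 0.0;
            for (int j = 0; j < k; ++j) dot += prof_col[j] * colc[j];
            const double mix = (1.0 - eb) * dot;
            double* col = Lp + (size_t)p * k;
            double mx = 0.0;
            for (int i = 0; i < k; ++i) {
              col[i] *= eb * colc[i] + mix;
              if (col[i] > mx) mx = col[i];
            }
            if (mx > 0 && (mx < 1e-120 || mx > 1e120)) {
              for (int i = 0; i < k; ++i) col[i] /= mx;
              sp[p] += sc[p] + std::log(mx);
            } else {
              sp[p] += sc[p];
            }
            // a child's scale is consumed exactly once (by its parent edge)
            sc[p] = 0.0;
          }
        }
      }
      const double* Lr = &L[(size_t)(root - n_tip) * k * n_pat];
      const double* sr = &scale_log[(size_t)(root - n_tip) * n_pat];
      const int combo = c * G + g;
      for (int p = 0; p < n_pat; ++p) {
        const double* col = Lr + (size_t)p * k;
        double lik = 0.0;
        for (int i = 0; i < k; ++i) lik += prof_col[i] * col[i];
        combo_log(combo, p) = log_weights[c] + log_g +
          (lik > 0 ? std::log(lik) : -1e300) + sr[p];
      }
    }
  }
  NumericVector out(n_pat);
  for (int p = 0; p < n_pat; ++p) {
    double mx = combo_log(0, p);
    for (int m = 1; m < n_combo; ++m)
      if (combo_log(m, p) > mx) mx = combo_log(m, p);
    double s = 0.0;
    for (int m = 0; m < n_combo; ++m) s += std::exp(combo_log(m, p) - mx);
    out[p] = mx + std::log(s);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector plik_pmat(IntegerMatrix tips, IntegerVector edge_child,
                        IntegerVector edge_parent, int n_nodes, int root,
                        List P_by_combo, NumericMatrix profiles,
                        NumericVector log_weights, int G) {
  const int n_tip = tips.nrow();
  const int n_pat = tips.ncol();
  const int n_edge = edge_child.size();
  const int n_int = n_nodes - n_tip;
  const int C = profiles.nrow();
  const int k = profiles.ncol();
  const int n_combo = C * G;
  const double log_g = -std::log((double)G);

  NumericMatrix combo_log(n_combo, n_pat);
  std::vector<double> L((size_t)n_int * k * n_pat);
  std::vector<double> scale_log((size_t)n_int * n_pat);

  for (int combo = 0; combo < n_combo; ++combo) {
    const int c = combo / G;
    List P_edges = P_by_combo[combo]; // list of k x k matrices, one per edge
    std::fill(L.begin(), L.end(), 1.0);
    std::fill(scale_log.begin(), scale_log.end(), 0.0);
    for (int e = 0; e < n_edge; ++e) {
      const int child = edge_child[e];
      const int parent = edge_parent[e] - n_tip;
      NumericMatrix P = P_edges[e];
      double* Lp = &L[(size_t)parent * k * n_pat];
      double* sp = &scale_log[(size_t)parent * n_pat];
      if (child < n_tip) {
        for (int p = 0; p < n_pat; ++p) {
          const int x = tips(child, p);
          if (x >= k) continue;
          double* col = Lp + (size_t)p * k;
          for (int i = 0; i < k; ++i) col[i] *= P(i, x);
        }
      } else {
        const int ci = child - n_tip;
        double* Lc = &L[(size_t)ci * k * n_pat];
        double* sc = &scale_log[(size_t)ci * n_pat];
        for (int p = 0; p < n_pat; ++p) {
          double* colc = Lc + (size_t)p * k;
          double* col = Lp + (size_t)p * k;
          double mx = 0.0;
          for (int i = 0; i < k; ++i) {
            double t = 0.0;
            for (int j = 0; j < k; ++j) t += P(i, j) * colc[j];
            col[i] *= t;
            if (col[i] > mx) mx = col[i];
          }
          if (mx > 0 && (mx < 1e-120 || mx > 1e120)) {
            for (int i = 0; i < k; ++i) col[i] /= mx;
            sp[p] += sc[p] + std::log(mx);
          } else {
            sp[p] += sc[p];
          }
          sc[p] = 0.0;
        }
      }
    }
    const double* Lr = &L[(size_t)(root - n_tip) * k * n_pat];
    const double* sr = &scale_log[(size_t)(root - n_tip) * n_pat];
    for (int p = 0; p < n_pat; ++p) {
      const double* col = Lr + (size_t)p * k;
      double lik = 0.0;
      for (int i = 0; i < k; ++i) lik += profiles(c, i) * col[i];
      combo_log(combo, p) = log_weights[c] + log_g +
        (lik > 0 ? std::log(lik) : -1e300) + sr[p];
    }
  }
  NumericVector out(n_pat);
  for (int p = 0; p < n_pat; ++p) {
    double mx = combo_log(0, p);
    for (int m = 1; m < n_combo; ++m)
      if (combo_log(m, p) > mx) mx = combo_log(m, p);
    double s = 0.0;
    for (int m = 0; m < n_combo; ++m) s += std::exp(combo_log(m, p) - mx);
    out[p] = mx + std::log(s);
  }
  return out;
}
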