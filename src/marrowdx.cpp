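#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global energy of a binary label field under per-site negative log-likelihoods
// and an 8-neighbour Potts prior. Each neighbour pair is counted once.
static double field_energy(const IntegerMatrix &lab, const NumericMatrix &nll0,
                           const NumericMatrix &nll1, double beta) {
  int nr = lab.nrow(), nc = lab.ncol();
  double e = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      e += lab(i, j) == 0 ? nll0(i, j) : nll1(i, j);
  // pairs: right, down, down-right, down-left
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (j + 1 < nc && l != lab(i, j + 1)) e += beta;
      if (i + 1 < nr && l != lab(i + 1, j)) e += beta;
      if (i + 1 < nr && j + 1 < nc && l != lab(i + 1, j + 1)) e += beta;
      if (i + 1 < nr && j > 0 && l != lab(i + 1, j - 1)) e += beta;
    }
  }
  return e;
}

// Iterated conditional modes for a binary MRF. Raster-scan updates; a site
// keeps its current label on ties, so the global energy can never increase.
// [[Rcpp::export]]
List icm_cpp(IntegerMatrix labels, NumericMatrix nll0, NumericMatrix nll1,
             double beta, int max_sweeps) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix lab = clone(labels);
  std::vector<double> trace;
  trace.push_back(field_energy(lab, nll0, nll1, beta));
  int sweeps = 0;
  for (int s = 0; s < max_sweeps; ++s) {
    int flips = 0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        int n1 = 0, ntot = 0; // neighbours with label 1
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            ++ntot;
            n1 += lab(ii, jj);
          }
        }
        double e0 = nll0(i, j) + beta * n1;          // disagree with label-1 nbrs
        double e1 = nll1(i, j) + beta * (ntot - n1); // disagree with label-0 nbrs
        int cur = lab(i, j);
        int nxt = cur;
        if (e0 < e1) nxt = 0;
        else if (e1 < e0) nxt = 1;
        if (nxt != cur) { lab(i, j) = nxt; ++flips; }
      }
    }
    ++sweeps;
    trace.push_back(field_energy(lab, nll0, nll1, beta));
    if (flips == 0) break;
  }
  return List::create(_["labels"] = lab,
                      _["energy"] = NumericVector(trace.begin(), trace.end()),
                      _["sweeps"] = sweeps);
}

// Connected components of a binary mask, 4- or 8-connectivity, labelled
// 1..n in raster-scan discovery order (deterministic).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int dy4[4] = {-1, 0, 0, 1};
  int nn = connectivity == 8 ? 8 : 4;
  const int *dx = connectivity == 8 ? dx8 : dx4;
  const int *dy = connectivity == 8 ? dy8 : dy4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int ii = pi + dx[k], jj = pj + dy[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}
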