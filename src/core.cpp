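#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighbour offsets, fixed scan order for determinism
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Normalized 2-D cross-correlation of an odd-sided template against every
// position where the template fits entirely inside the image. Positions where
// it does not fit are NA. Direct windowed Pearson; zero-variance windows give 0.
// [[Rcpp::export]]
NumericMatrix normxcorr_cpp(NumericMatrix img, NumericMatrix patch) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = patch.nrow(), pc = patch.ncol();
  if (pr % 2 == 0 || pc % 2 == 0) stop("template sides must be odd");
  if (pr > nr || pc > nc) stop("template larger than image");
  const int hr = pr / 2, hc = pc / 2;
  const int n = pr * pc;

  // centre the template once
  double pmean = 0.0;
  for (int j = 0; j < pc; ++j)
    for (int i = 0; i < pr; ++i) pmean += patch(i, j);
  pmean /= n;
  std::vector<double> pz(n);
  double pss = 0.0;
  {
    int k = 0;
    for (int j = 0; j < pc; ++j)
      for (int i = 0; i < pr; ++i) {
        double v = patch(i, j) - pmean;
        pz[k++] = v;
        pss += v * v;
      }
  }
  if (pss <= 0) stop("template has zero variance");
  const double pnorm = std::sqrt(pss);

  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int cc = hc; cc < nc - hc; ++cc) {
    for (int rr = hr; rr < nr - hr; ++rr) {
      // two-pass windowed Pearson: centring before squaring avoids the
      // cancellation of the textbook E[x^2]-E[x]^2 form on bright windows
      double s = 0.0;
      for (int j = cc - hc; j <= cc + hc; ++j)
        for (int i = rr - hr; i <= rr + hr; ++i) s += img(i, j);
      const double wmean = s / n;
      double wvar = 0.0, cross = 0.0;
      int k = 0;
      for (int j = cc - hc; j <= cc + hc; ++j) {
        for (int i = rr - hr; i <= rr + hr; ++i) {
          const double v = img(i, j) - wmean;
          wvar += v * v;
          cross += v * pz[k++];
        }
      }
      double r = 0.0;
      if (wvar > 1e-12) r = cross / (std::sqrt(wvar) * pnorm);
      if (r > 1.0) r = 1.0;
      if (r < -1.0) r = -1.0;
      out(rr, cc) = r;
    }
  }
  return out;
}

// 8-connected labeling of a binary matrix. Labels assigned in column-major
// order of first encounter (deterministic).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          const int qi = pi + DR[k], qj = pj + DC[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct QNode {
  double elev;
  long order;
  int idx;
};
struct QNodeCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // lowest elevation first
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-controlled watershed (Meyer's flooding, 8-connectivity) with
// watershed lines. markers: 0 = unlabeled, k >= 1 = marker of basin k.
// Returns label matrix; ridge pixels (touching two basins at assignment
// time) and never-reached pixels stay 0.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix elev, IntegerMatrix markers) {
  const int nr = elev.nrow(), nc = elev.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("elevation and marker shapes differ");
  const int WSHED = -1;
  IntegerMatrix lab = clone(markers);
  std::vector<char> queued(static_cast<size_t>(nr) * nc, 0);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  long order = 0;

  // seed the queue with unlabeled neighbours of markers
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        const int qi = i + DR[k], qj = j + DC[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        const int q = qi + qj * nr;
        if (lab(qi, qj) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push({elev(qi, qj), order++, q});
        }
      }
    }

  while (!pq.empty()) {
    const QNode nd = pq.top();
    pq.pop();
    const int pi = nd.idx % nr, pj = nd.idx / nr;
    if (lab(pi, pj) != 0) continue;
    int assign = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      const int qi = pi + DR[k], qj = pj + DC[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      const int l = lab(qi, qj);
      if (l > 0) {
        if (assign == 0) assign = l;
        else if (assign != l) conflict = true;
      }
    }
    if (conflict) {
      lab(pi, pj) = WSHED;
    } else if (assign > 0) {
      lab(pi, pj) = assign;
      for (int k = 0; k < 8; ++k) {
        const int qi = pi + DR[k], qj = pj + DC[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        const int q = qi + qj * nr;
        if (lab(qi, qj) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push({elev(qi, qj), order++, q});
        }
      }
    }
  }

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) == WSHED) lab(i, j) = 0;
  return lab;
}
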