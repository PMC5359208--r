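#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Flat morphology, reconstruction and immersion-watershed kernels.
// Matrices are R integer matrices; linear indices are column-major (R's
// native layout), which also fixes the deterministic scan/seed order that
// the watershed and labelling results depend on.

namespace {

struct Neigh {
  int n;
  int dr[8];
  int dc[8];
};

Neigh make_neigh(int conn) {
  Neigh N;
  if (conn == 4) {
    N.n = 4;
    const int r4[4] = {-1, 0, 0, 1};
    const int c4[4] = {0, -1, 1, 0};
    std::copy(r4, r4 + 4, N.dr);
    std::copy(c4, c4 + 4, N.dc);
  } else {
    N.n = 8;
    const int r8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    const int c8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    std::copy(r8, r8 + 8, N.dr);
    std::copy(c8, c8 + 8, N.dc);
  }
  return N;
}

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

} // namespace

// Erosion with border replication: out(p) = min over SE window, where
// out-of-image samples replicate the nearest edge pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_erode(IntegerMatrix img, IntegerVector se_dr, IntegerVector se_dc) {
  const int nr = img.nrow(), nc = img.ncol(), k = se_dr.size();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int m = INT_MAX;
      for (int i = 0; i < k; ++i) {
        const int rr = clampi(r + se_dr[i], 0, nr - 1);
        const int cc = clampi(c + se_dc[i], 0, nc - 1);
        const int v = img(rr, cc);
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Dilation uses the reflected SE (max filter); all SEs shipped by the R
// layer are symmetric, but reflection is applied regardless.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate(IntegerMatrix img, IntegerVector se_dr, IntegerVector se_dc) {
  const int nr = img.nrow(), nc = img.ncol(), k = se_dr.size();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int m = INT_MIN;
      for (int i = 0; i < k; ++i) {
        const int rr = clampi(r - se_dr[i], 0, nr - 1);
        const int cc = clampi(c - se_dc[i], 0, nc - 1);
        const int v = img(rr, cc);
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Morphological reconstruction by dilation (geodesic dilation of `marker`
// under `mask` iterated to stability), computed with the sequential
// forward/backward raster scans plus FIFO propagation. The fixed point is
// unique, so the result is identical to naive iteration until stability.
// [[Rcpp::export]]
IntegerMatrix cpp_reconstruct_dilation(IntegerMatrix marker, IntegerMatrix mask, int conn) {
  const int nr = marker.nrow(), nc = marker.ncol();
  IntegerMatrix J = clone(marker);
  const Neigh N = make_neigh(conn);

  // Predecessors / successors in column-major raster order.
  std::vector<int> pr, pc, sr, sc;
  for (int i = 0; i < N.n; ++i) {
    const int dc = N.dc[i], dr = N.dr[i];
    if (dc < 0 || (dc == 0 && dr < 0)) { pr.push_back(dr); pc.push_back(dc); }
    else { sr.push_back(dr); sc.push_back(dc); }
  }

  // forward scan
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = J(r, c);
      for (size_t i = 0; i < pr.size(); ++i) {
        const int rr = r + pr[i], cc = c + pc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > v) v = J(rr, cc);
      }
      J(r, c) = std::min(v, mask(r, c));
    }
  }

  // backward scan + queue seeding
  std::queue<int> q;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      int v = J(r, c);
      for (size_t i = 0; i < sr.size(); ++i) {
        const int rr = r + sr[i], cc = c + sc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > v) v = J(rr, cc);
      }
      v = std::min(v, mask(r, c));
      J(r, c) = v;
      for (size_t i = 0; i < sr.size(); ++i) {
        const int rr = r + sr[i], cc = c + sc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) < v && J(rr, cc) < mask(rr, cc)) {
          q.push(c * nr + r);
          break;
        }
      }
    }
  }

  while (!q.empty()) {
    const int p = q.front(); q.pop();
    const int r = p % nr, c = p / nr;
    const int vp = J(r, c);
    for (int i = 0; i < N.n; ++i) {
      const int rr = r + N.dr[i], cc = c + N.dc[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < vp && J(rr, cc) != mask(rr, cc)) {
        J(rr, cc) = std::min(vp, mask(rr, cc));
        q.push(cc * nr + rr);
      }
    }
  }
  return J;
}

// Regional minima: connected iso-intensity plateaus with no strictly lower
// neighbour under the given connectivity.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_minima(IntegerMatrix img, int conn) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  const Neigh N = make_neigh(conn);
  LogicalMatrix out(nr, nc);
  std::vector<char> seen(n, 0);
  std::vector<int> plateau;
  std::queue<int> q;

  for (int p0 = 0; p0 < n; ++p0) {
    if (seen[p0]) continue;
    const int v = img[p0];
    bool is_min = true;
    plateau.clear();
    seen[p0] = 1;
    q.push(p0);
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      plateau.push_back(p);
      const int r = p % nr, c = p / nr;
      for (int i = 0; i < N.n; ++i) {
        const int rr = r + N.dr[i], cc = c + N.dc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int pq = cc * nr + rr;
        const int w = img[pq];
        if (w < v) is_min = false;
        else if (w == v && !seen[pq]) { seen[pq] = 1; q.push(pq); }
      }
    }
    if (is_min)
      for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = true;
  }
  return out;
}

// Connected-component labelling of a binary mask, labels assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  const Neigh N = make_neigh(conn);
  IntegerMatrix lab(nr, nc);
  std::queue<int> q;
  int cur = 0;
  for (int p0 = 0; p0 < n; ++p0) {
    if (!mask[p0] || lab[p0] != 0) continue;
    lab[p0] = ++cur;
    q.push(p0);
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      const int r = p % nr, c = p / nr;
      for (int i = 0; i < N.n; ++i) {
        const int rr = r + N.dr[i], cc = c + N.dc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int pq = cc * nr + rr;
        if (mask[pq] && lab[pq] == 0) { lab[pq] = cur; q.push(pq); }
      }
    }
  }
  return lab;
}

// Vincent–Soille watershed by immersion with explicit 0-valued divide
// (watershed-line) pixels. Basins are labelled 1..k, one per regional
// minimum; pixel processing order within a gray level is the column-major
// raster order, and flooding uses a FIFO queue, so the output is fully
// deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(IntegerMatrix img, int conn) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  const Neigh N = make_neigh(conn);
  const int INIT = -2, MASK = -1, WSHED = 0, FICT = -1;

  std::vector<int> lab(n, INIT), dist(n, 0), order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&img](int a, int b) { return img[a] < img[b]; });

  std::queue<int> fifo;
  int curlab = 0;
  int i0 = 0;
  while (i0 < n) {
    const int h = img[order[i0]];
    int i1 = i0;
    // mask all pixels of level h; queue those bordering existing labels
    for (; i1 < n && img[order[i1]] == h; ++i1) {
      const int p = order[i1];
      lab[p] = MASK;
      const int r = p % nr, c = p / nr;
      for (int i = 0; i < N.n; ++i) {
        const int rr = r + N.dr[i], cc = c + N.dc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int pq = cc * nr + rr;
        if (lab[pq] > 0 || lab[pq] == WSHED) { dist[p] = 1; fifo.push(p); break; }
      }
    }
    int curdist = 1;
    fifo.push(FICT);
    // extend existing basins into level h
    while (true) {
      int p = fifo.front(); fifo.pop();
      if (p == FICT) {
        if (fifo.empty()) break;
        fifo.push(FICT);
        ++curdist;
        p = fifo.front(); fifo.pop();
      }
      const int r = p % nr, c = p / nr;
      for (int i = 0; i < N.n; ++i) {
        const int rr = r + N.dr[i], cc = c + N.dc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int pq = cc * nr + rr;
        if (dist[pq] < curdist && (lab[pq] > 0 || lab[pq] == WSHED)) {
          if (lab[pq] > 0) {
            if (lab[p] == MASK || lab[p] == WSHED) lab[p] = lab[pq];
            else if (lab[p] != lab[pq]) lab[p] = WSHED;
          } else if (lab[p] == MASK) {
            lab[p] = WSHED;
          }
        } else if (lab[pq] == MASK && dist[pq] == 0) {
          dist[pq] = curdist + 1;
          fifo.push(pq);
        }
      }
    }
    // new minima at level h get fresh labels
    for (int j = i0; j < i1; ++j) {
      const int p = order[j];
      dist[p] = 0;
      if (lab[p] != MASK) continue;
      lab[p] = ++curlab;
      fifo.push(p);
      while (!fifo.empty()) {
        const int pp = fifo.front(); fifo.pop();
        const int r = pp % nr, c = pp / nr;
        for (int i = 0; i < N.n; ++i) {
          const int rr = r + N.dr[i], cc = c + N.dc[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const int pq = cc * nr + rr;
          if (lab[pq] == MASK) { lab[pq] = curlab; fifo.push(pq); }
        }
      }
    }
    i0 = i1;
  }

  IntegerMatrix out(nr, nc);
  for (int i = 0; i < n; ++i) out[i] = lab[i];
  return out;
}
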