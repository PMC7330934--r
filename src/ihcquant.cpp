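#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra < rb ? rb : ra] = ra < rb ? ra : rb;
}

//' Two-pass connected-component labelling of a logical matrix.
//' connectivity is 4 or 8; labels are 1..n in raster (column-major) order
//' of first occurrence after relabelling.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0); // provisional label 0 unused
  int next = 0;

  // first pass: scan columns then rows (column-major like R storage);
  // neighbours already visited: (r-1,c), (r,c-1), and for 8-connectivity
  // (r-1,c-1), (r+1,c-1)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int lbl = 0;
      if (r > 0 && mask(r - 1, c)) lbl = lab(r - 1, c);
      if (c > 0) {
        if (mask(r, c - 1)) {
          int l2 = lab(r, c - 1);
          if (lbl && l2 != lbl) uf_union(parent, lbl, l2);
          if (!lbl) lbl = l2;
        }
        if (connectivity == 8) {
          if (r > 0 && mask(r - 1, c - 1)) {
            int l2 = lab(r - 1, c - 1);
            if (lbl && l2 != lbl) uf_union(parent, lbl, l2);
            if (!lbl) lbl = l2;
          }
          if (r + 1 < H && mask(r + 1, c - 1)) {
            int l2 = lab(r + 1, c - 1);
            if (lbl && l2 != lbl) uf_union(parent, lbl, l2);
            if (!lbl) lbl = l2;
          }
        }
      }
      if (!lbl) {
        lbl = ++next;
        parent.push_back(lbl);
      }
      lab(r, c) = lbl;
    }
  }

  // second pass: flatten and compact labels
  std::vector<int> remap(next + 1, 0);
  int out = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      if (!l) continue;
      int root = uf_find(parent, l);
      if (!remap[root]) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  }
  lab.attr("n_labels") = out;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) of a
// sampled function f; writes result into d.
static void edt1d(const std::vector<double> &f, std::vector<double> &d) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1; // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // parabola at +inf never contributes
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; s = INF; break; }
      } else break;
    }
    if (s != INF) {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    } else {
      z[1] = INF; // q replaced the sole parabola
    }
  }
  if (k < 0) { // no finite sample anywhere
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double dq = q - (double)v[j];
    d[q] = dq * dq + f[v[j]];
  }
}

//' Exact Euclidean squared distance transform: for each pixel, the squared
//' distance (in pixels) to the nearest TRUE pixel of `feature`.
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix feature) {
  const int H = feature.nrow(), W = feature.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix out(H, W);

  // pass 1: along rows (within each column)
  std::vector<double> f(H), d(H);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = feature(r, c) ? 0.0 : INF;
    edt1d(f, d);
    for (int r = 0; r < H; ++r) out(r, c) = d[r];
  }
  // pass 2: along columns (within each row)
  std::vector<double> f2(W), d2(W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f2[c] = out(r, c);
    edt1d(f2, d2);
    for (int c = 0; c < W; ++c) out(r, c) = d2[c];
  }
  return out;
}
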