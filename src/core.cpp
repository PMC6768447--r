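#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Matrices follow the R convention: rows = y (0-based externally), cols = x.
// All convolutions use replicate ("clamp") borders.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_sepconv2(const NumericMatrix& img,
                           const NumericVector& kx,
                           const NumericVector& ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int lx = kx.size(), ly = ky.size();
  const int cx = lx / 2, cy = ly / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // horizontal pass (along x = columns)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int k = 0; k < lx; ++k) {
        int cc = clampi(c + k - cx, 0, nc - 1);
        acc += img(r, cc) * kx[k];
      }
      tmp(r, c) = acc;
    }
  }
  // vertical pass (along y = rows)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int k = 0; k < ly; ++k) {
        int rr = clampi(r + k - cy, 0, nr - 1);
        acc += tmp(rr, c) * ky[k];
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Local maxima of `resp` over a (2*radius+1)^2 window, value > thresh,
// ignoring a `border` frame. On plateaus only the first pixel in
// column-major order is kept, so no window ever contains two detections.
// [[Rcpp::export]]
IntegerMatrix cpp_local_max(const NumericMatrix& resp, int radius,
                            double thresh, int border) {
  const int nr = resp.nrow(), nc = resp.ncol();
  std::vector<int> rows, cols;
  for (int c = border; c < nc - border; ++c) {
    for (int r = border; r < nr - border; ++r) {
      double v = resp(r, c);
      if (!(v > thresh)) continue;
      bool ok = true;
      for (int dc = -radius; dc <= radius && ok; ++dc) {
        int cc = c + dc;
        if (cc < 0 || cc >= nc) continue;
        for (int dr = -radius; dr <= radius; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= nr || (dr == 0 && dc == 0)) continue;
          double w = resp(rr, cc);
          if (w > v) { ok = false; break; }
          // plateau tie-break: earlier column-major pixel wins
          if (w == v && (cc < c || (cc == c && rr < r))) { ok = false; break; }
        }
      }
      if (ok) { rows.push_back(r); cols.push_back(c); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}

// FAST segment-test score: for every pixel (3-px border excluded) the
// maximal contrast t such that >= arc contiguous pixels of the 16-pixel
// Bresenham circle (radius 3) are all brighter than center+t or all
// darker than center-t. Score 0 where the test fails for every t > 0.
// [[Rcpp::export]]
NumericMatrix cpp_fast_score(const NumericMatrix& img, int arc) {
  static const int dx[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
  static const int dy[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix score(nr, nc); // zero-initialised
  if (nr < 7 || nc < 7) return score;
  double diff[32];
  for (int c = 3; c < nc - 3; ++c) {
    for (int r = 3; r < nr - 3; ++r) {
      const double v = img(r, c);
      for (int k = 0; k < 16; ++k) {
        diff[k] = img(r + dy[k], c + dx[k]) - v;
        diff[k + 16] = diff[k]; // wrap-around for contiguous arcs
      }
      double best = 0.0;
      // brighter arcs: min over window of diff; darker arcs: min of -diff
      for (int s = 0; s < 16; ++s) {
        double mnb = diff[s], mnd = -diff[s];
        for (int k = 1; k < arc; ++k) {
          double d = diff[s + k];
          if (d < mnb) mnb = d;
          if (-d < mnd) mnd = -d;
        }
        if (mnb > best) best = mnb;
        if (mnd > best) best = mnd;
      }
      score(r, c) = best;
    }
  }
  return score;
}

// 4-connected component labelling of a logical matrix (two-pass union-find).
// Returns an integer matrix with labels 1..k, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int up = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
      int lf = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
      if (!up && !lf) {
        parent.push_back(++next);
        lab(r, c) = next;
      } else if (up && lf) {
        int ru = find(up), rl = find(lf);
        int m = std::min(ru, rl);
        parent[ru] = m; parent[rl] = m;
        lab(r, c) = m;
      } else {
        lab(r, c) = up ? up : lf;
      }
    }
  }
  std::vector<int> remap(next + 1, 0);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c)) {
        int root = find(lab(r, c));
        if (!remap[root]) remap[root] = ++k;
        lab(r, c) = remap[root];
      }
  return lab;
}

// ---------------------------------------------------------------------------
// MSER: bright extremal regions by descending quantised threshold sweep.
// Components are grown with union-find; each component keeps a history of
// (level, area, centroid sums); on a merge the larger component's history
// survives. Variation at level l = (A(l-1) - A(l+1)) / A(l) over one
// quantisation step each way; reported regions are history-local minima of
// variation with variation <= max_variation and area inside [min_area,
// max_area], thinned with a relative-area diversity rule.
// Columns of the result: cx, cy, area, variation, level (quantised index).
// ---------------------------------------------------------------------------

struct MserHist {
  std::vector<int> level;
  std::vector<double> area, sx, sy;
  int root; // current union-find root, updated lazily
};

// [[Rcpp::export]]
NumericMatrix cpp_mser(const NumericMatrix& img, int nlevels,
                       int min_area, int max_area,
                       double max_variation, double min_diversity) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  // quantised level per pixel, 0..nlevels-1
  std::vector<int> lvl(n);
  std::vector<std::vector<int>> bucket(nlevels);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int p = c * nr + r;
      int l = (int)std::floor(img(r, c) * (nlevels - 1) + 0.5);
      l = clampi(l, 0, nlevels - 1);
      lvl[p] = l;
      bucket[l].push_back(p);
    }
  std::vector<int> parent(n, -1);        // -1 = not yet added
  std::vector<double> area(n, 0), sx(n, 0), sy(n, 0);
  std::vector<int> hist_of(n, -1);       // root -> history id
  std::vector<MserHist> hists;
  std::vector<int> live;                 // live history ids
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int l = nlevels - 1; l >= 0; --l) {
    for (int p : bucket[l]) {
      parent[p] = p; area[p] = 1;
      int r = p % nr, c = p / nr;
      sx[p] = c; sy[p] = r;
      hist_of[p] = -1;
      const int nb[4] = {
        r > 0 ? p - 1 : -1, r < nr - 1 ? p + 1 : -1,
        c > 0 ? p - nr : -1, c < nc - 1 ? p + nr : -1 };
      for (int q : nb) {
        if (q < 0 || parent[q] == -1) continue;
        int rp = find(p), rq = find(q);
        if (rp == rq) continue;
        // keep the history of the larger component
        int keep = (area[rp] >= area[rq]) ? rp : rq;
        int drop = (keep == rp) ? rq : rp;
        parent[drop] = keep;
        area[keep] += area[drop];
        sx[keep] += sx[drop];
        sy[keep] += sy[drop];
        int hk = hist_of[keep], hd = hist_of[drop];
        if (hk == -1 && hd != -1) { hist_of[keep] = hd; hists[hd].root = keep; }
        // hd dies implicitly: its root no longer maps to it
      }
    }
    // record history entries for live components
    std::vector<int> still;
    still.reserve(live.size());
    for (int h : live) {
      int r = find(hists[h].root);
      if (hist_of[r] != h) continue; // lost a merge
      hists[h].root = r;
      hists[h].level.push_back(l);
      hists[h].area.push_back(area[r]);
      hists[h].sx.push_back(sx[r]);
      hists[h].sy.push_back(sy[r]);
      still.push_back(h);
    }
    live.swap(still);
    // components with no history yet get one (born at this level)
    for (int p : bucket[l]) {
      int r = find(p);
      if (hist_of[r] != -1) continue;
      MserHist h;
      h.root = r;
      h.level.push_back(l);
      h.area.push_back(area[r]);
      h.sx.push_back(sx[r]);
      h.sy.push_back(sy[r]);
      hist_of[r] = (int)hists.size();
      live.push_back((int)hists.size());
      hists.push_back(std::move(h));
    }
  }
  // select stable entries
  std::vector<double> ocx, ocy, oarea, ovar, olev;
  for (const MserHist& h : hists) {
    const int m = (int)h.level.size();
    if (m < 3) continue;
    std::vector<double> var(m, R_PosInf);
    // entries are at consecutive descending levels: entry i-1 has level+1
    for (int i = 1; i < m - 1; ++i)
      var[i] = (h.area[i + 1] - h.area[i - 1]) / h.area[i];
    double last_area = -1.0;
    for (int i = 1; i < m - 1; ++i) {
      if (var[i] > max_variation) continue;
      if (!(var[i] <= var[i - 1] && var[i] <= var[i + 1])) continue;
      double a = h.area[i];
      if (a < min_area || a > max_area) continue;
      if (last_area > 0 && (a - last_area) / a < min_diversity) continue;
      last_area = a;
      ocx.push_back(h.sx[i] / a);
      ocy.push_back(h.sy[i] / a);
      oarea.push_back(a);
      ovar.push_back(var[i]);
      olev.push_back(h.level[i]);
    }
  }
  NumericMatrix out((int)ocx.size(), 5);
  for (size_t i = 0; i < ocx.size(); ++i) {
    out(i, 0) = ocx[i]; out(i, 1) = ocy[i]; out(i, 2) = oarea[i];
    out(i, 3) = ovar[i]; out(i, 4) = olev[i];
  }
  return out;
}

// Inverse-mapped affine warp. `tinv` (2x3) maps output (x,y) -> source (x,y),
// 0-based pixel-centre coordinates. Bilinear when bilinear=true, else
// nearest-neighbour. Out-of-source pixels are `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp(const NumericMatrix& src,
                              const NumericMatrix& tinv,
                              int out_h, int out_w,
                              bool bilinear, double fill) {
  const int nr = src.nrow(), nc = src.ncol();
  NumericMatrix out(out_h, out_w);
  const double a = tinv(0, 0), b = tinv(0, 1), tx = tinv(0, 2);
  const double c = tinv(1, 0), d = tinv(1, 1), ty = tinv(1, 2);
  for (int xo = 0; xo < out_w; ++xo) {
    for (int yo = 0; yo < out_h; ++yo) {
      double xs = a * xo + b * yo + tx;
      double ys = c * xo + d * yo + ty;
      double v = fill;
      if (bilinear) {
        int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        if (x0 >= 0 && x0 < nc - 1 && y0 >= 0 && y0 < nr - 1) {
          double fx = xs - x0, fy = ys - y0;
          v = (1 - fx) * (1 - fy) * src(y0, x0)
            + fx * (1 - fy) * src(y0, x0 + 1)
            + (1 - fx) * fy * src(y0 + 1, x0)
            + fx * fy * src(y0 + 1, x0 + 1);
        } else if (xs >= -0.5 && xs <= nc - 0.5 && ys >= -0.5 && ys <= nr - 0.5) {
          // within half a pixel of the border: clamp
          int xc = clampi((int)std::lround(xs), 0, nc - 1);
          int yc = clampi((int)std::lround(ys), 0, nr - 1);
          v = src(yc, xc);
        }
      } else {
        int xn = (int)std::lround(xs), yn = (int)std::lround(ys);
        if (xn >= 0 && xn < nc && yn >= 0 && yn < nr) v = src(yn, xn);
      }
      out(yo, xo) = v;
    }
  }
  return out;
}

// Greedy deduplication for the combined-detector merge: points are visited
// in the given (strength-descending) order; a point is dropped when an
// already-kept point lies closer than `radius` px and the scale ratio of
// the two is below `max_scale_ratio`.
// [[Rcpp::export]]
LogicalVector cpp_dedupe(const NumericVector& x, const NumericVector& y,
                         const NumericVector& scale,
                         double radius, double max_scale_ratio) {
  const int n = x.size();
  LogicalVector keep(n);
  std::vector<int> kept;
  kept.reserve(n);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (int j : kept) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy >= r2) continue;
      double sr = scale[i] > scale[j] ? scale[i] / scale[j] : scale[j] / scale[i];
      if (sr < max_scale_ratio) { ok = false; break; }
    }
    keep[i] = ok;
    if (ok) kept.push_back(i);
  }
  return keep;
}

// Gradient-orientation patch descriptors: for each point a square patch of
// side 4*max(scale, 2.5) px is bilinearly resampled to 16x16, split into
// 4x4 cells, and each cell contributes a 4-bin gradient-orientation
// histogram weighted by gradient magnitude -> 64 values, L2-normalised
// (zero vector for constant patches). Sampling outside the image replicates
// the nearest edge pixel.
// [[Rcpp::export]]
NumericMatrix cpp_descriptors(const NumericMatrix& img,
                              const NumericVector& x,
                              const NumericVector& y,
                              const NumericVector& scale) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = x.size();
  const int G = 16;          // resampled grid
  NumericMatrix out(n, 64);
  double patch[18][18];      // grid + 1-px border for central differences
  for (int i = 0; i < n; ++i) {
    double side = 4.0 * std::max(scale[i], 2.5);
    double step = side / G;
    for (int gx = -1; gx <= G; ++gx) {
      for (int gy = -1; gy <= G; ++gy) {
        double xs = x[i] + (gx + 0.5 - G / 2.0) * step;
        double ys = y[i] + (gy + 0.5 - G / 2.0) * step;
        // bilinear with edge replication
        double xcl = std::min(std::max(xs, 0.0), (double)(nc - 1));
        double ycl = std::min(std::max(ys, 0.0), (double)(nr - 1));
        int x0 = std::min((int)std::floor(xcl), nc - 2 < 0 ? 0 : nc - 2);
        int y0 = std::min((int)std::floor(ycl), nr - 2 < 0 ? 0 : nr - 2);
        double fx = xcl - x0, fy = ycl - y0;
        int x1 = std::min(x0 + 1, nc - 1), y1 = std::min(y0 + 1, nr - 1);
        patch[gy + 1][gx + 1] =
          (1 - fx) * (1 - fy) * img(y0, x0) + fx * (1 - fy) * img(y0, x1)
          + (1 - fx) * fy * img(y1, x0) + fx * fy * img(y1, x1);
      }
    }
    double desc[64] = {0};
    for (int gx = 0; gx < G; ++gx) {
      for (int gy = 0; gy < G; ++gy) {
        double dxv = 0.5 * (patch[gy + 1][gx + 2] - patch[gy + 1][gx]);
        double dyv = 0.5 * (patch[gy + 2][gx + 1] - patch[gy][gx + 1]);
        double mag = std::sqrt(dxv * dxv + dyv * dyv);
        if (mag <= 0) continue;
        double ang = std::atan2(dyv, dxv); // [-pi, pi]
        int bin = (int)std::floor((ang + M_PI) / (M_PI / 2.0));
        if (bin > 3) bin = 3;
        int cell = (gy / 4) * 4 + (gx / 4);
        desc[cell * 4 + bin] += mag;
      }
    }
    double nrm = 0;
    for (int k = 0; k < 64; ++k) nrm += desc[k] * desc[k];
    if (nrm > 0) {
      nrm = std::sqrt(nrm);
      for (int k = 0; k < 64; ++k) out(i, k) = desc[k] / nrm;
    }
  }
  return out;
}
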