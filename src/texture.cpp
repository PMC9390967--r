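// Texture-matrix builders, mesh-based shape primitives and a small CART
// learner. Arrays arrive flattened in R's column-major order with dims
// (nx, ny, nz); gray levels are 1..Ng inside the ROI and 0 outside.

#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lv, IntegerVector dims, int ng) {
  // symmetric co-occurrence counts, distance 1, 13 unique 3-D directions;
  // returns ng x ng x 13 counts (unnormalized)
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = lv[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        int b = lv[idx3(x2, y2, z2, nx, ny)];
        if (b == 0) continue;
        out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1.0;
        out[(b - 1) + ng * (a - 1) + ng * ng * d] += 1.0;  // symmetric
      }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lv, IntegerVector dims, int ng) {
  // run-length counts per direction: ng x maxlen x 13
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(std::max(nx, ny), nz);
  NumericVector out(ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = lv[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        // run start iff predecessor is out of grid, out of mask, or differs
        int px = x - dx, py = y - dy, pz = z - dz;
        if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
            lv[idx3(px, py, pz, nx, ny)] == a)
          continue;
        int len = 1;
        int cx = x + dx, cy = y + dy, cz = z + dz;
        while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
               lv[idx3(cx, cy, cz, nx, ny)] == a) {
          ++len; cx += dx; cy += dy; cz += dz;
        }
        out[(a - 1) + ng * (len - 1) + ng * maxlen * d] += 1.0;
      }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector lv, IntegerVector dims, int ng) {
  // 26-connected equal-level zones; returns ng x maxsize zone counts
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<std::pair<int,int> > zones;  // (level, size)
  int maxsize = 1;
  for (int i = 0; i < n; ++i) {
    if (lv[i] == 0 || lab[i]) continue;
    int level = lv[i], size = 0;
    std::queue<int> q; q.push(i); lab[i] = 1;
    while (!q.empty()) {
      int c = q.front(); q.pop(); ++size;
      int cz = c / (nx * ny), cy = (c / nx) % ny, cx = c % nx;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int j = idx3(x2, y2, z2, nx, ny);
          if (!lab[j] && lv[j] == level) { lab[j] = 1; q.push(j); }
        }
    }
    zones.push_back(std::make_pair(level, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix out(ng, maxsize);
  for (size_t k = 0; k < zones.size(); ++k)
    out(zones[k].first - 1, zones[k].second - 1) += 1.0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lv, IntegerVector dims, int ng, int alpha) {
  // dependence counts: 26-neighbourhood, |level difference| <= alpha.
  // Column j = 1 + number of dependent neighbours (centre counts itself).
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);  // dependence size 1..27
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int a = lv[idx3(x, y, z, nx, ny)];
      if (a == 0) continue;
      int dep = 0;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int b = lv[idx3(x2, y2, z2, nx, ny)];
          if (b != 0 && std::abs(b - a) <= alpha) ++dep;
        }
      out(a - 1, dep) += 1.0;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector lv, IntegerVector dims, int ng) {
  // per gray level: voxel count n_i and sum s_i of |i - mean(valid nbrs)|
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector ni(ng), si(ng);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int a = lv[idx3(x, y, z, nx, ny)];
      if (a == 0) continue;
      double sum = 0.0; int cnt = 0;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int b = lv[idx3(x2, y2, z2, nx, ny)];
          if (b != 0) { sum += b; ++cnt; }
        }
      ni[a - 1] += 1.0;
      if (cnt > 0) si[a - 1] += std::fabs((double)a - sum / cnt);
    }
  return List::create(_["n"] = ni, _["s"] = si);
}

// ---- shape primitives -------------------------------------------------------

// 6-tetrahedra decomposition of the unit cube around the v0-v7 diagonal;
// cube corners indexed b = x + 2y + 4z.
static const int TETS[6][4] = {
  {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
};
static const double CORNER[8][3] = {
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
};

static double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double w[3] = { u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0] };
  return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
}

// [[Rcpp::export]]
List cpp_mesh_area_volume(LogicalVector mask, IntegerVector dims,
                          NumericVector spacing) {
  // marching-tetrahedra iso-surface of a binary mask at level 0.5: cube
  // cells split into 6 tets, surface vertices at edge midpoints. Returns
  // total surface area (mm^2) and enclosed volume (mm^3). Inside-fractions
  // per tet by #inside corners: {0, 1/8, 1/2, 7/8, 1} (exact for midpoint
  // cuts).
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double tetvol = sx * sy * sz / 6.0;
  static const double FRAC[5] = {0.0, 0.125, 0.5, 0.875, 1.0};
  double area = 0.0, vol = 0.0;

  // iterate cells of the 1-voxel zero-padded grid: corner (x+i, y+j, z+k)
  for (int z = -1; z < nz; ++z) for (int y = -1; y < ny; ++y)
    for (int x = -1; x < nx; ++x) {
      int inside[8];
      int any = 0, all = 1;
      for (int b = 0; b < 8; ++b) {
        int cx = x + (b & 1), cy = y + ((b >> 1) & 1), cz = z + ((b >> 2) & 1);
        int in = (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz)
          ? (mask[idx3(cx, cy, cz, nx, ny)] ? 1 : 0) : 0;
        inside[b] = in; any |= in; all &= in;
      }
      if (!any) continue;
      if (all) { vol += 6.0 * tetvol; continue; }
      for (int t = 0; t < 6; ++t) {
        const int *tv = TETS[t];
        int ins[4], nin = 0;
        for (int k = 0; k < 4; ++k) { ins[k] = inside[tv[k]]; nin += ins[k]; }
        vol += FRAC[nin] * tetvol;
        if (nin == 0 || nin == 4) continue;
        // physical corner coordinates of this tet
        double P[4][3];
        for (int k = 0; k < 4; ++k) {
          P[k][0] = (x + CORNER[tv[k]][0]) * sx;
          P[k][1] = (y + CORNER[tv[k]][1]) * sy;
          P[k][2] = (z + CORNER[tv[k]][2]) * sz;
        }
        int in_id[4], out_id[4], ni = 0, no = 0;
        for (int k = 0; k < 4; ++k) { if (ins[k]) in_id[ni++] = k; else out_id[no++] = k; }
        double M[4][3];  // cut polygon vertices (edge midpoints)
        if (nin == 1 || nin == 3) {
          int apex = (nin == 1) ? in_id[0] : out_id[0];
          int oth[3], c = 0;
          for (int k = 0; k < 4; ++k) if (k != apex) oth[c++] = k;
          for (int m = 0; m < 3; ++m) for (int d = 0; d < 3; ++d)
            M[m][d] = 0.5 * (P[apex][d] + P[oth[m]][d]);
          area += tri_area(M[0], M[1], M[2]);
        } else {  // nin == 2: quad across the 4 mixed edges
          int a0 = in_id[0], a1 = in_id[1], b0 = out_id[0], b1 = out_id[1];
          int pairs[4][2] = { {a0,b0},{a0,b1},{a1,b1},{a1,b0} };  // cyclic
          for (int m = 0; m < 4; ++m) for (int d = 0; d < 3; ++d)
            M[m][d] = 0.5 * (P[pairs[m][0]][d] + P[pairs[m][1]][d]);
          area += tri_area(M[0], M[1], M[2]) + tri_area(M[0], M[2], M[3]);
        }
      }
    }
  return List::create(_["area"] = area, _["volume"] = vol);
}

// [[Rcpp::export]]
NumericVector cpp_max_diameters(LogicalVector mask, IntegerVector dims,
                                NumericVector spacing) {
  // max pairwise distances between boundary-voxel centres: 3-D, and 2-D
  // within slice (fixed z, xy-plane), column (fixed y, xz), row (fixed x, yz)
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> bx, by, bz;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      if (!mask[idx3(x, y, z, nx, ny)]) continue;
      bool edge = (x == 0 || x == nx-1 || y == 0 || y == ny-1 ||
                   z == 0 || z == nz-1);
      if (!edge) {
        edge = !mask[idx3(x-1,y,z,nx,ny)] || !mask[idx3(x+1,y,z,nx,ny)] ||
               !mask[idx3(x,y-1,z,nx,ny)] || !mask[idx3(x,y+1,z,nx,ny)] ||
               !mask[idx3(x,y,z-1,nx,ny)] || !mask[idx3(x,y,z+1,nx,ny)];
      }
      if (edge) { bx.push_back(x); by.push_back(y); bz.push_back(z); }
    }
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double d3 = 0, dsl = 0, dcol = 0, drow = 0;
  size_t n = bx.size();
  for (size_t i = 0; i < n; ++i) for (size_t j = i + 1; j < n; ++j) {
    double dx = (bx[i]-bx[j]) * sx, dy = (by[i]-by[j]) * sy,
           dz = (bz[i]-bz[j]) * sz;
    double q3 = dx*dx + dy*dy + dz*dz;
    if (q3 > d3) d3 = q3;
    if (bz[i] == bz[j]) { double q = dx*dx + dy*dy; if (q > dsl) dsl = q; }
    if (by[i] == by[j]) { double q = dx*dx + dz*dz; if (q > dcol) dcol = q; }
    if (bx[i] == bx[j]) { double q = dy*dy + dz*dz; if (q > drow) drow = q; }
  }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dsl),
                               std::sqrt(dcol), std::sqrt(drow));
}

// ---- CART (classification/regression trees) --------------------------------
// Minimal depth-limited CART used by the decision-tree, random-forest,
// gradient-boosting and AdaBoost classifiers. Splits minimize weighted Gini
// (classification) or SSE (regression). Features may be subsampled per tree
// (random-subspace).

struct TreeNode {
  int feat; double thr;        // internal node
  double value;                // leaf prediction
  int left, right;             // child indices; -1 for leaf
};

static void grow_tree(const NumericMatrix &X, const NumericVector &y,
                      const NumericVector &w, std::vector<int> &rows,
                      const std::vector<int> &feats, int depth, int max_depth,
                      int min_leaf, bool classify, std::vector<TreeNode> &nodes) {
  TreeNode node; node.feat = -1; node.thr = 0; node.left = node.right = -1;
  double wsum = 0, wy = 0;
  for (size_t i = 0; i < rows.size(); ++i) { wsum += w[rows[i]]; wy += w[rows[i]] * y[rows[i]]; }
  double mean = (wsum > 0) ? wy / wsum : 0.0;
  node.value = mean;
  int self = (int)nodes.size();
  nodes.push_back(node);
  if (depth >= max_depth || (int)rows.size() < 2 * min_leaf) return;

  // impurity: Gini for classification on y in {0,1} equals p(1-p); SSE uses
  // variance — both reduce to the same weighted-variance split criterion
  double best_gain = 1e-12; int best_f = -1; double best_thr = 0;
  int nrows = (int)rows.size();
  std::vector<std::pair<double,int> > ord(nrows);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    for (int i = 0; i < nrows; ++i)
      ord[i] = std::make_pair(X(rows[i], f), rows[i]);
    std::sort(ord.begin(), ord.end());
    double wl = 0, wyl = 0, wy2l = 0;
    double wr = wsum, wyr = wy, wy2r = 0;
    for (int i = 0; i < nrows; ++i) wy2r += w[ord[i].second] * y[ord[i].second] * y[ord[i].second];
    double tot_imp = wy2r - wy * wy / std::max(wsum, 1e-300);
    for (int i = 0; i < nrows - 1; ++i) {
      int r = ord[i].second;
      double wi = w[r], yi = y[r];
      wl += wi; wyl += wi * yi; wy2l += wi * yi * yi;
      wr -= wi; wyr -= wi * yi; wy2r -= wi * yi * yi;
      if (ord[i + 1].first <= ord[i].first) continue;   // no valid threshold
      if (i + 1 < min_leaf || nrows - i - 1 < min_leaf) continue;
      double impl = wy2l - wyl * wyl / std::max(wl, 1e-300);
      double impr = wy2r - wyr * wyr / std::max(wr, 1e-300);
      double gain = tot_imp - impl - impr;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (ord[i].first + ord[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;
  std::vector<int> lrows, rrows;
  for (int i = 0; i < nrows; ++i) {
    if (X(rows[i], best_f) <= best_thr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  if (lrows.empty() || rrows.empty()) return;
  nodes[self].feat = best_f; nodes[self].thr = best_thr;
  nodes[self].left = (int)nodes.size();
  grow_tree(X, y, w, lrows, feats, depth + 1, max_depth, min_leaf, classify, nodes);
  nodes[self].right = (int)nodes.size();
  grow_tree(X, y, w, rrows, feats, depth + 1, max_depth, min_leaf, classify, nodes);
}

// [[Rcpp::export]]
List cpp_cart_fit(NumericMatrix X, NumericVector y, NumericVector w,
                  IntegerVector rows, IntegerVector feats, int max_depth,
                  int min_leaf, bool classify) {
  std::vector<int> rv(rows.begin(), rows.end());
  std::vector<int> fv(feats.begin(), feats.end());
  std::vector<TreeNode> nodes;
  grow_tree(X, y, w, rv, fv, 0, max_depth, min_leaf, classify, nodes);
  int n = (int)nodes.size();
  IntegerVector feat(n), left(n), right(n);
  NumericVector thr(n), value(n);
  for (int i = 0; i < n; ++i) {
    feat[i] = nodes[i].feat; thr[i] = nodes[i].thr; value[i] = nodes[i].value;
    left[i] = nodes[i].left; right[i] = nodes[i].right;
  }
  return List::create(_["feat"] = feat, _["thr"] = thr, _["value"] = value,
                      _["left"] = left, _["right"] = right);
}

// [[Rcpp::export]]
NumericVector cpp_cart_predict(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feat"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
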