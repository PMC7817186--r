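// Classical 3D volume operations used across the pipeline: exact Euclidean
// distance transform, binary morphology, connected components, separable
// Gaussian smoothing, marker-based watershed, quality-guided 2D phase
// unwrapping. Volumes are R arrays with dim (z, y, x), column-major.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double DT_INF = 1e15;

// Felzenszwalb & Huttenlocher 1-D squared-distance transform.
// f: input squared distances, d: output, n: length, w2: axis spacing^2.
static void dt1d(const double* f, double* d, int n, double w2,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int i = 0; i < n; ++i) {
    while (z[k + 1] < i) ++k;
    double di = i - v[k];
    d[i] = w2 * di * di + f[v[k]];
  }
}

// Squared EDT of the foreground (nonzero) voxels to the nearest zero voxel.
// spacing: per-axis physical voxel size, order (z, y, x).
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? DT_INF : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), f(nmax), d(nmax);

  // pass along z (stride 1)
  double w2 = spacing[0] * spacing[0];
  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y) {
      double* col = &out[0] + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x);
      dt1d(col, d.data(), n1, w2, v, z);
      std::copy(d.begin(), d.begin() + n1, col);
    }
  // pass along y (stride n1)
  w2 = spacing[1] * spacing[1];
  for (int x = 0; x < n3; ++x)
    for (int zz = 0; zz < n1; ++zz) {
      double* base = &out[0] + zz + (R_xlen_t)n1 * n2 * x;
      for (int y = 0; y < n2; ++y) f[y] = base[(R_xlen_t)n1 * y];
      dt1d(f.data(), d.data(), n2, w2, v, z);
      for (int y = 0; y < n2; ++y) base[(R_xlen_t)n1 * y] = d[y];
    }
  // pass along x (stride n1*n2)
  w2 = spacing[2] * spacing[2];
  for (int y = 0; y < n2; ++y)
    for (int zz = 0; zz < n1; ++zz) {
      double* base = &out[0] + zz + (R_xlen_t)n1 * y;
      for (int x = 0; x < n3; ++x) f[x] = base[(R_xlen_t)n1 * n2 * x];
      dt1d(f.data(), d.data(), n3, w2, v, z);
      for (int x = 0; x < n3; ++x) base[(R_xlen_t)n1 * n2 * x] = d[x];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= DT_INF * 0.5) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// Binary dilation/erosion with an explicit structuring element given as an
// m x 3 matrix of integer offsets (z, y, x). Out-of-bounds voxels count as
// background.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets, bool dilate) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int m = offsets.nrow();
  LogicalVector out((R_xlen_t)n1 * n2 * n3);
  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y)
      for (int zz = 0; zz < n1; ++zz) {
        bool acc = dilate ? false : true;
        for (int j = 0; j < m; ++j) {
          int az = zz + offsets(j, 0), ay = y + offsets(j, 1),
              ax = x + offsets(j, 2);
          bool val = false;
          if (az >= 0 && az < n1 && ay >= 0 && ay < n2 && ax >= 0 && ax < n3)
            val = mask[az + (R_xlen_t)n1 * (ay + (R_xlen_t)n2 * ax)];
          if (dilate) { if (val) { acc = true; break; } }
          else        { if (!val) { acc = false; break; } }
        }
        out[zz + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x)] = acc;
      }
  return out;
}

static void neighbor_offsets(int conn, std::vector<int>& dz,
                             std::vector<int>& dy, std::vector<int>& dx) {
  if (conn == 6) {
    int z6[] = {1, -1, 0, 0, 0, 0}, y6[] = {0, 0, 1, -1, 0, 0},
        x6[] = {0, 0, 0, 0, 1, -1};
    dz.assign(z6, z6 + 6); dy.assign(y6, y6 + 6); dx.assign(x6, x6 + 6);
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dz.push_back(a); dy.push_back(b); dx.push_back(c);
        }
  }
}

// Connected-component labelling (conn = 6 or 26), labels in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int conn) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(conn, dz, dy, dx);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cx = (int)(cur / ((R_xlen_t)n1 * n2));
      int rem = (int)(cur % ((R_xlen_t)n1 * n2));
      int cy = rem / n1, cz = rem % n1;
      for (size_t j = 0; j < dz.size(); ++j) {
        int az = cz + dz[j], ay = cy + dy[j], ax = cx + dx[j];
        if (az < 0 || az >= n1 || ay < 0 || ay >= n2 || ax < 0 || ax >= n3)
          continue;
        R_xlen_t ai = az + (R_xlen_t)n1 * (ay + (R_xlen_t)n2 * ax);
        if (mask[ai] && !lab[ai]) { lab[ai] = next; stack.push_back(ai); }
      }
    }
  }
  return lab;
}

static void gauss1d(const double* in, double* out, int n, R_xlen_t stride,
                    const std::vector<double>& ker) {
  int R = (int)(ker.size() / 2);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, wsum = 0.0;
    for (int j = -R; j <= R; ++j) {
      int p = i + j;
      if (p < 0 || p >= n) continue;  // truncated kernel, renormalized
      double w = ker[j + R];
      s += w * in[(R_xlen_t)p * stride];
      wsum += w;
    }
    out[(R_xlen_t)i * stride] = s / wsum;
  }
}

// Separable Gaussian smoothing with sigma in voxels; borders use a
// renormalized truncated kernel so constant volumes stay constant.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, double sigma) {
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int R = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * R + 1);
  for (int j = -R; j <= R; ++j)
    ker[j + R] = std::exp(-0.5 * j * j / (sigma * sigma));
  std::vector<double> buf(std::max(n1, std::max(n2, n3)));

  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y) {
      double* col = &out[0] + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * x);
      std::copy(col, col + n1, buf.begin());
      gauss1d(buf.data(), col, n1, 1, ker);
    }
  for (int x = 0; x < n3; ++x)
    for (int zz = 0; zz < n1; ++zz) {
      double* base = &out[0] + zz + (R_xlen_t)n1 * n2 * x;
      for (int y = 0; y < n2; ++y) buf[y] = base[(R_xlen_t)n1 * y];
      gauss1d(buf.data(), buf.data(), n2, 1, ker);
      for (int y = 0; y < n2; ++y) base[(R_xlen_t)n1 * y] = buf[y];
    }
  for (int y = 0; y < n2; ++y)
    for (int zz = 0; zz < n1; ++zz) {
      double* base = &out[0] + zz + (R_xlen_t)n1 * y;
      for (int x = 0; x < n3; ++x) buf[x] = base[(R_xlen_t)n1 * n2 * x];
      gauss1d(buf.data(), buf.data(), n3, 1, ker);
      for (int x = 0; x < n3; ++x) base[(R_xlen_t)n1 * n2 * x] = buf[x];
    }
  return out;
}

struct WsNode {
  double prio;
  double d2seed;
  unsigned long order;
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;      // min-heap on priority
    if (a.d2seed != b.d2seed) return a.d2seed > b.d2seed;  // nearer seed wins
    return a.order > b.order;                          // then FIFO
  }
};

// Marker-based watershed by priority flooding (6-connectivity) restricted to
// `mask`. Lower priority floods first. The priority image (a quantized
// distance transform) has large plateaus of tied values; on ties, the flood
// whose seed centroid is nearest claims the voxel (then insertion order), so
// plateau claims do not inherit the voxel scan order's directional bias.
// seed_centroids: one (z, y, x) row per marker label, 0-based voxel units.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim,
                            NumericMatrix seed_centroids) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  unsigned long counter = 0;
  std::vector<int> dz, dy, dx;
  neighbor_offsets(6, dz, dy, dx);

  auto d2seed = [&](R_xlen_t i, int label) {
    int vx = (int)(i / ((R_xlen_t)n1 * n2));
    int rem = (int)(i % ((R_xlen_t)n1 * n2));
    int vy = rem / n1, vz = rem % n1;
    double a = vz - seed_centroids(label - 1, 0);
    double b = vy - seed_centroids(label - 1, 1);
    double c = vx - seed_centroids(label - 1, 2);
    return a * a + b * b + c * c;
  };

  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push({priority[i], 0.0, counter++, i, markers[i]});
    }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    R_xlen_t cur = nd.idx;
    int cx = (int)(cur / ((R_xlen_t)n1 * n2));
    int rem = (int)(cur % ((R_xlen_t)n1 * n2));
    int cy = rem / n1, cz = rem % n1;
    for (int j = 0; j < 6; ++j) {
      int az = cz + dz[j], ay = cy + dy[j], ax = cx + dx[j];
      if (az < 0 || az >= n1 || ay < 0 || ay >= n2 || ax < 0 || ax >= n3)
        continue;
      R_xlen_t ai = az + (R_xlen_t)n1 * (ay + (R_xlen_t)n2 * ax);
      if (!mask[ai] || lab[ai]) continue;
      lab[ai] = lab[cur];
      pq.push({priority[ai], d2seed(ai, lab[cur]), counter++, ai,
               lab[cur]});
    }
  }
  return lab;
}

struct UwNode {
  double qual;
  unsigned long order;
  int idx;
  int from;
};
struct UwCmp {
  bool operator()(const UwNode& a, const UwNode& b) const {
    if (a.qual != b.qual) return a.qual < b.qual;  // max-heap on quality
    return a.order > b.order;
  }
};

static inline double wrap_pi(double x) {
  const double TWO_PI = 2.0 * M_PI;
  return x - TWO_PI * std::floor((x + M_PI) / TWO_PI);
}

// Quality-guided 2D phase unwrapping: grow a region from the highest-quality
// pixel, unwrapping each new pixel against the already-unwrapped neighbour
// that enqueued it. `phase` and `quality` are ny x nx matrices.
// [[Rcpp::export]]
NumericMatrix cpp_unwrap2(NumericMatrix phase, NumericMatrix quality) {
  const int ny = phase.nrow(), nx = phase.ncol();
  const int n = ny * nx;
  NumericMatrix out(ny, nx);
  std::vector<char> done(n, 0);
  std::priority_queue<UwNode, std::vector<UwNode>, UwCmp> pq;
  unsigned long counter = 0;

  int best = 0;
  for (int i = 1; i < n; ++i)
    if (quality[i] > quality[best]) best = i;
  out[best] = phase[best];
  done[best] = 1;
  const int dys[] = {1, -1, 0, 0}, dxs[] = {0, 0, 1, -1};
  auto push_nb = [&](int idx) {
    int iy = idx % ny, ix = idx / ny;
    for (int j = 0; j < 4; ++j) {
      int ay = iy + dys[j], ax = ix + dxs[j];
      if (ay < 0 || ay >= ny || ax < 0 || ax >= nx) continue;
      int ai = ay + ny * ax;
      if (!done[ai]) pq.push({quality[ai], counter++, ai, idx});
    }
  };
  push_nb(best);
  while (!pq.empty()) {
    UwNode nd = pq.top();
    pq.pop();
    if (done[nd.idx]) continue;
    out[nd.idx] = out[nd.from] + wrap_pi(phase[nd.idx] - phase[nd.from]);
    done[nd.idx] = 1;
    push_nb(nd.idx);
  }
  return out;
}
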