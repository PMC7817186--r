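// 3D convolution primitives for the signed-distance regression network.
// Feature maps are R arrays with dim (z, y, x, channels); weights have dim
// (kz, ky, kx, c_in, c_out). "Same" padding; stride 1 or 2. Implemented as
// im2col + BLAS GEMM; the backward pass returns exact gradients.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int s) { return (n + s - 1) / s; }

static void im2col(const double* x, int n1, int n2, int n3, int cin,
                   int k1, int k2, int k3, int s, arma::mat& Xc) {
  const int o1 = out_size(n1, s), o2 = out_size(n2, s), o3 = out_size(n3, s);
  const int p1 = ((o1 - 1) * s + k1 - n1) / 2;
  const int p2 = ((o2 - 1) * s + k2 - n2) / 2;
  const int p3 = ((o3 - 1) * s + k3 - n3) / 2;
  const arma::uword nout = (arma::uword)o1 * o2 * o3;
  Xc.zeros(nout, (arma::uword)k1 * k2 * k3 * cin);
  arma::uword col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (size_t)n1 * n2 * n3 * ci;
    for (int c3 = 0; c3 < k3; ++c3)
      for (int c2 = 0; c2 < k2; ++c2)
        for (int c1 = 0; c1 < k1; ++c1) {
          double* dst = Xc.colptr(col);
          // stride 1: the z-run is contiguous in both source and
          // destination, so copy whole runs
          const bool fast = (s == 1);
          int oz_lo = fast ? std::max(0, p1 - c1) : 0;
          int oz_hi = fast ? std::min(o1 - 1, n1 - 1 + p1 - c1) : o1 - 1;
          for (int ox = 0; ox < o3; ++ox) {
            int ix = ox * s - p3 + c3;
            if (ix < 0 || ix >= n3) continue;
            for (int oy = 0; oy < o2; ++oy) {
              int iy = oy * s - p2 + c2;
              if (iy < 0 || iy >= n2) continue;
              const double* src =
                  xc + (size_t)n1 * (iy + (size_t)n2 * ix);
              double* drow =
                  dst + (size_t)o1 * (oy + (size_t)o2 * ox);
              if (fast) {
                if (oz_hi >= oz_lo)
                  std::memcpy(drow + oz_lo, src + (oz_lo - p1 + c1),
                              (size_t)(oz_hi - oz_lo + 1) * sizeof(double));
              } else {
                for (int oz = 0; oz < o1; ++oz) {
                  int iz = oz * s - p1 + c1;
                  if (iz < 0 || iz >= n1) continue;
                  drow[oz] = src[iz];
                }
              }
            }
          }
          ++col;
        }
  }
  // column order: c1 fastest, then c2, c3, ci -- matches the column-major
  // layout of the weight array (kz, ky, kx, c_in, c_out).
}

static void col2im(const arma::mat& Gc, int n1, int n2, int n3, int cin,
                   int k1, int k2, int k3, int s, double* gx) {
  const int o1 = out_size(n1, s), o2 = out_size(n2, s), o3 = out_size(n3, s);
  const int p1 = ((o1 - 1) * s + k1 - n1) / 2;
  const int p2 = ((o2 - 1) * s + k2 - n2) / 2;
  const int p3 = ((o3 - 1) * s + k3 - n3) / 2;
  std::fill(gx, gx + (size_t)n1 * n2 * n3 * cin, 0.0);
  arma::uword col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = gx + (size_t)n1 * n2 * n3 * ci;
    for (int c3 = 0; c3 < k3; ++c3)
      for (int c2 = 0; c2 < k2; ++c2)
        for (int c1 = 0; c1 < k1; ++c1) {
          const double* src = Gc.colptr(col);
          const bool fast = (s == 1);
          int oz_lo = fast ? std::max(0, p1 - c1) : 0;
          int oz_hi = fast ? std::min(o1 - 1, n1 - 1 + p1 - c1) : o1 - 1;
          for (int ox = 0; ox < o3; ++ox) {
            int ix = ox * s - p3 + c3;
            if (ix < 0 || ix >= n3) continue;
            for (int oy = 0; oy < o2; ++oy) {
              int iy = oy * s - p2 + c2;
              if (iy < 0 || iy >= n2) continue;
              double* drow = xc + (size_t)n1 * (iy + (size_t)n2 * ix);
              const double* srow =
                  src + (size_t)o1 * (oy + (size_t)o2 * ox);
              if (fast) {
                double* d = drow + (c1 - p1);
                for (int oz = oz_lo; oz <= oz_hi; ++oz)
                  d[oz] += srow[oz];
              } else {
                for (int oz = 0; oz < o1; ++oz) {
                  int iz = oz * s - p1 + c1;
                  if (iz < 0 || iz >= n1) continue;
                  drow[iz] += srow[oz];
                }
              }
            }
          }
          ++col;
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, int stride) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], cin = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], cout = wdim[4];
  const int o1 = out_size(n1, stride), o2 = out_size(n2, stride),
            o3 = out_size(n3, stride);
  arma::mat Xc;
  im2col(&x[0], n1, n2, n3, cin, k1, k2, k3, stride, Xc);
  const arma::mat Wm(const_cast<double*>(&w[0]),
                     (arma::uword)k1 * k2 * k3 * cin, cout, false, true);
  arma::mat Y = Xc * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(&b[0]), cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(o1, o2, o3, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdim, NumericVector w,
                   IntegerVector wdim, NumericVector gy, int stride) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], cin = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], cout = wdim[4];
  const int o1 = out_size(n1, stride), o2 = out_size(n2, stride),
            o3 = out_size(n3, stride);
  const arma::uword nout = (arma::uword)o1 * o2 * o3;
  const arma::uword K = (arma::uword)k1 * k2 * k3 * cin;

  arma::mat Xc;
  im2col(&x[0], n1, n2, n3, cin, k1, k2, k3, stride, Xc);
  const arma::mat Gy(const_cast<double*>(&gy[0]), nout, cout, false, true);
  const arma::mat Wm(const_cast<double*>(&w[0]), K, cout, false, true);

  arma::mat Gw = Xc.t() * Gy;                 // K x cout
  arma::rowvec Gb = arma::sum(Gy, 0);         // 1 x cout
  arma::mat Gc = Gy * Wm.t();                 // nout x K

  NumericVector gx((R_xlen_t)n1 * n2 * n3 * cin);
  col2im(Gc, n1, n2, n3, cin, k1, k2, k3, stride, &gx[0]);
  gx.attr("dim") = xdim;
  NumericVector gw(Gw.begin(), Gw.end());
  gw.attr("dim") = wdim;
  NumericVector gb(Gb.begin(), Gb.end());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Nearest-neighbour 2x upsampling to an explicit target shape.
// [[Rcpp::export]]
NumericVector cpp_upsample_nn(NumericVector x, IntegerVector xdim,
                              IntegerVector tdim) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], nc = xdim[3];
  const int t1 = tdim[0], t2 = tdim[1], t3 = tdim[2];
  NumericVector out((R_xlen_t)t1 * t2 * t3 * nc);
  for (int c = 0; c < nc; ++c)
    for (int x3 = 0; x3 < t3; ++x3)
      for (int x2 = 0; x2 < t2; ++x2)
        for (int x1 = 0; x1 < t1; ++x1) {
          int s1 = std::min(x1 / 2, n1 - 1), s2 = std::min(x2 / 2, n2 - 1),
              s3 = std::min(x3 / 2, n3 - 1);
          out[(R_xlen_t)x1 +
              (R_xlen_t)t1 * (x2 + (R_xlen_t)t2 * (x3 + (R_xlen_t)t3 * c))] =
              x[(R_xlen_t)s1 +
                (R_xlen_t)n1 * (s2 + (R_xlen_t)n2 * (s3 + (R_xlen_t)n3 * c))];
        }
  out.attr("dim") = IntegerVector::create(t1, t2, t3, nc);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bw(NumericVector gy, IntegerVector tdim,
                                 IntegerVector xdim) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], nc = xdim[3];
  const int t1 = tdim[0], t2 = tdim[1], t3 = tdim[2];
  NumericVector gx((R_xlen_t)n1 * n2 * n3 * nc);
  for (int c = 0; c < nc; ++c)
    for (int x3 = 0; x3 < t3; ++x3)
      for (int x2 = 0; x2 < t2; ++x2)
        for (int x1 = 0; x1 < t1; ++x1) {
          int s1 = std::min(x1 / 2, n1 - 1), s2 = std::min(x2 / 2, n2 - 1),
              s3 = std::min(x3 / 2, n3 - 1);
          gx[(R_xlen_t)s1 +
             (R_xlen_t)n1 * (s2 + (R_xlen_t)n2 * (s3 + (R_xlen_t)n3 * c))] +=
              gy[(R_xlen_t)x1 +
                 (R_xlen_t)t1 * (x2 + (R_xlen_t)t2 * (x3 + (R_xlen_t)t3 * c))];
        }
  gx.attr("dim") = xdim;
  return gx;
}
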