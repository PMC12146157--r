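#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are R arrays with dim (C, H, W): element (c, y, x) at
// c + C*(y + H*x), zero-based.  Dense kernels have dim (O, C, kh, kw),
// snake kernels (O, C, k).  All convolutions zero-pad outside the grid.

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad_y, int pad_x) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int O = wd[0], kh = wd[2], kw = wd[3];
  if (wd[1] != C) stop("channel mismatch: input has %d channels, kernel expects %d", C, wd[1]);
  int Ho = (H + 2 * pad_y - kh) / stride + 1;
  int Wo = (W + 2 * pad_x - kw) / stride + 1;
  NumericVector out(O * Ho * Wo);
  const double *px = REAL(x), *pw = REAL(w), *pb = REAL(b);
  double *po = REAL(out);
  for (int xo = 0; xo < Wo; ++xo) {
    int x0 = xo * stride - pad_x;
    for (int yo = 0; yo < Ho; ++yo) {
      int y0 = yo * stride - pad_y;
      for (int o = 0; o < O; ++o) {
        double s = pb[o];
        for (int kx = 0; kx < kw; ++kx) {
          int xi = x0 + kx;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            int yi = y0 + ky;
            if (yi < 0 || yi >= H) continue;
            const double *wrow = pw + o + O * (C * (ky + kh * kx));
            const double *xrow = px + C * (yi + H * xi);
            for (int c = 0; c < C; ++c)
              s += wrow[O * c] * xrow[c];
          }
        }
        po[o + O * (yo + Ho * xo)] = s;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(O, Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad_y, int pad_x) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int O = wd[0], kh = wd[2], kw = wd[3];
  int Ho = gd[1], Wo = gd[2];
  NumericVector gx(C * H * W), gw(O * C * kh * kw), gb(O);
  const double *px = REAL(x), *pw = REAL(w), *pg = REAL(gout);
  double *pgx = REAL(gx), *pgw = REAL(gw), *pgb = REAL(gb);
  for (int xo = 0; xo < Wo; ++xo) {
    int x0 = xo * stride - pad_x;
    for (int yo = 0; yo < Ho; ++yo) {
      int y0 = yo * stride - pad_y;
      for (int o = 0; o < O; ++o) {
        double g = pg[o + O * (yo + Ho * xo)];
        if (g == 0.0) continue;
        pgb[o] += g;
        for (int kx = 0; kx < kw; ++kx) {
          int xi = x0 + kx;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            int yi = y0 + ky;
            if (yi < 0 || yi >= H) continue;
            double *gwrow = pgw + o + O * (C * (ky + kh * kx));
            const double *wrow = pw + o + O * (C * (ky + kh * kx));
            const double *xrow = px + C * (yi + H * xi);
            double *gxrow = pgx + C * (yi + H * xi);
            for (int c = 0; c < C; ++c) {
              gwrow[O * c] += g * xrow[c];
              gxrow[c] += g * wrow[O * c];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Snake (serpentine) convolution: k taps march along one axis while a
// learnable fractional offset displaces each tap along the other axis;
// sampling is linear interpolation with zero padding.  axis 1 = taps along
// x with offsets in y, axis 2 = taps along y with offsets in x.  Stride 1.

static inline double samp_lin(const NumericVector &x, int c, double yf, int xi,
                              int C, int H, int W, int axis) {
  // axis 1: fractional coordinate is y (row); axis 2: fractional is x (col)
  if (axis == 1) {
    if (xi < 0 || xi >= W) return 0.0;
    int y0 = (int)std::floor(yf);
    double f = yf - y0;
    double v0 = (y0 >= 0 && y0 < H) ? x[c + C * (y0 + H * xi)] : 0.0;
    double v1 = (y0 + 1 >= 0 && y0 + 1 < H) ? x[c + C * (y0 + 1 + H * xi)] : 0.0;
    return (1 - f) * v0 + f * v1;
  } else {
    if (xi < 0 || xi >= H) return 0.0;  // xi holds the integer row here
    int x0 = (int)std::floor(yf);
    double f = yf - x0;
    double v0 = (x0 >= 0 && x0 < W) ? x[c + C * (xi + H * x0)] : 0.0;
    double v1 = (x0 + 1 >= 0 && x0 + 1 < W) ? x[c + C * (xi + H * (x0 + 1))] : 0.0;
    return (1 - f) * v0 + f * v1;
  }
}

// [[Rcpp::export]]
NumericVector cpp_snake(NumericVector x, NumericVector w, NumericVector b,
                        NumericVector off, int axis) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int O = wd[0], k = wd[2];
  if (wd[1] != C) stop("channel mismatch in snake convolution");
  int ctr = (k - 1) / 2;
  NumericVector out(O * H * W);
  for (int xc = 0; xc < W; ++xc) {
    for (int y = 0; y < H; ++y) {
      for (int o = 0; o < O; ++o) out[o + O * (y + H * xc)] = b[o];
      for (int t = 0; t < k; ++t) {
        int ii;
        double ff;
        if (axis == 1) { ii = xc + t - ctr; ff = y + off[t]; }
        else           { ii = y + t - ctr;  ff = xc + off[t]; }
        for (int c = 0; c < C; ++c) {
          double v = samp_lin(x, c, ff, ii, C, H, W, axis);
          if (v == 0.0) continue;
          for (int o = 0; o < O; ++o)
            out[o + O * (y + H * xc)] += w[o + O * (c + C * t)] * v;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(O, H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_snake_bwd(NumericVector x, NumericVector w, NumericVector off,
                   int axis, NumericVector gout) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int O = wd[0], k = wd[2];
  int ctr = (k - 1) / 2;
  NumericVector gx(C * H * W), gw(O * C * k), gb(O), goff(k);
  for (int xc = 0; xc < W; ++xc) {
    for (int y = 0; y < H; ++y) {
      for (int t = 0; t < k; ++t) {
        int ii;
        double ff;
        if (axis == 1) { ii = xc + t - ctr; ff = y + off[t]; }
        else           { ii = y + t - ctr;  ff = xc + off[t]; }
        bool inplane = (axis == 1) ? (ii >= 0 && ii < W) : (ii >= 0 && ii < H);
        if (!inplane) continue;
        int p0 = (int)std::floor(ff);
        double f = ff - p0;
        int lim = (axis == 1) ? H : W;
        bool ok0 = p0 >= 0 && p0 < lim, ok1 = p0 + 1 >= 0 && p0 + 1 < lim;
        int i0, i1;
        if (axis == 1) { i0 = C * (p0 + H * ii); i1 = C * (p0 + 1 + H * ii); }
        else           { i0 = C * (ii + H * p0); i1 = C * (ii + H * (p0 + 1)); }
        for (int c = 0; c < C; ++c) {
          double v0 = ok0 ? x[c + i0] : 0.0;
          double v1 = ok1 ? x[c + i1] : 0.0;
          double v = (1 - f) * v0 + f * v1;
          double gsum = 0.0;
          for (int o = 0; o < O; ++o) {
            double g = gout[o + O * (y + H * xc)];
            if (g == 0.0) continue;
            gw[o + O * (c + C * t)] += g * v;
            gsum += g * w[o + O * (c + C * t)];
          }
          if (gsum != 0.0) {
            if (ok0) gx[c + i0] += gsum * (1 - f);
            if (ok1) gx[c + i1] += gsum * f;
            goff[t] += gsum * (v1 - v0);
          }
        }
      }
      for (int o = 0; o < O; ++o) gb[o] += gout[o + O * (y + H * xc)];
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb, _["goff"] = goff);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  NumericVector out(C * 2 * H * 2 * W);
  int H2 = 2 * H;
  for (int xc = 0; xc < 2 * W; ++xc)
    for (int y = 0; y < H2; ++y) {
      int src = C * ((y / 2) + H * (xc / 2));
      int dst = C * (y + H2 * xc);
      for (int c = 0; c < C; ++c) out[c + dst] = x[c + src];
    }
  out.attr("dim") = IntegerVector::create(C, H2, 2 * W);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_bwd(NumericVector g) {
  IntegerVector gd = g.attr("dim");
  int C = gd[0], H2 = gd[1], W2 = gd[2];
  int H = H2 / 2, W = W2 / 2;
  NumericVector gx(C * H * W);
  for (int xc = 0; xc < W2; ++xc)
    for (int y = 0; y < H2; ++y) {
      int dst = C * ((y / 2) + H * (xc / 2));
      int src = C * (y + H2 * xc);
      for (int c = 0; c < C; ++c) gx[c + dst] += g[c + src];
    }
  gx.attr("dim") = IntegerVector::create(C, H, W);
  return gx;
}
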