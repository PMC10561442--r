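// Low-level numeric kernels for the network: 2-D convolution (with dilation,
// via im2col + BLAS matrix products), 2x2 max pooling, and bilinear resize,
// each with the adjoints needed for reverse-mode differentiation. Tensors
// are R arrays in column-major (H, W, C, N) layout; all kernels are
// stride-1 and deterministic.
#include <RcppArmadillo.h>
#include <cfloat>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int i, int j, int c, int n, int H, int W, int C) {
  return i + H * (j + W * (c + C * n));
}

// Patch matrix for one sample: rows index output pixels (io + Ho*jo),
// columns index kernel taps (ki + kh*(kj + kw*ci)) — matching the
// column-major layout of the (kh, kw, Cin, Cout) weight array.
static void im2col(const double *x, int H, int W, int Cin,
                   int kh, int kw, int ph, int pw, int dh, int dw,
                   int Ho, int Wo, arma::mat &A) {
  for (int ci = 0; ci < Cin; ++ci)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * ci);
        double *a = A.colptr(col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo - pw + dw * kj;
          if (j < 0 || j >= W) {
            for (int io = 0; io < Ho; ++io) a[io + Ho * jo] = 0.0;
            continue;
          }
          const double *xc = x + H * (j + W * ci);
          for (int io = 0; io < Ho; ++io) {
            const int i = io - ph + dh * ki;
            a[io + Ho * jo] = (i < 0 || i >= H) ? 0.0 : xc[i];
          }
        }
      }
}

static void col2im_add(const arma::mat &A, double *gx, int H, int W, int Cin,
                       int kh, int kw, int ph, int pw, int dh, int dw,
                       int Ho, int Wo) {
  for (int ci = 0; ci < Cin; ++ci)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * ci);
        const double *a = A.colptr(col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo - pw + dw * kj;
          if (j < 0 || j >= W) continue;
          double *gc = gx + H * (j + W * ci);
          for (int io = 0; io < Ho; ++io) {
            const int i = io - ph + dh * ki;
            if (i >= 0 && i < H) gc[i] += a[io + Ho * jo];
          }
        }
      }
}

// y[Ho,Wo,Cout,N]; Ho = H + 2*ph - dh*(kh-1), likewise Wo.
// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xd,
                        NumericVector w, IntegerVector wd,
                        NumericVector b, int ph, int pw, int dh, int dw) {
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = H + 2 * ph - dh * (kh - 1);
  const int Wo = W + 2 * pw - dw * (kw - 1);
  const int K = kh * kw * Cin, P = Ho * Wo;
  NumericVector y(R_xlen_t(P) * Cout * N);
  const arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  const arma::rowvec bv(const_cast<double *>(b.begin()), Cout, false, true);
  arma::mat A(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + R_xlen_t(n) * H * W * Cin, H, W, Cin,
           kh, kw, ph, pw, dh, dw, Ho, Wo, A);
    arma::mat Y(y.begin() + R_xlen_t(n) * P * Cout, P, Cout, false, true);
    Y = A * Wm;
    Y.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// Gradient w.r.t. the input of conv2d_fw.
// [[Rcpp::export]]
NumericVector conv2d_bw_x(NumericVector gy, IntegerVector xd,
                          NumericVector w, IntegerVector wd,
                          int ph, int pw, int dh, int dw) {
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = H + 2 * ph - dh * (kh - 1);
  const int Wo = W + 2 * pw - dw * (kw - 1);
  const int K = kh * kw * Cin, P = Ho * Wo;
  NumericVector gx(R_xlen_t(H) * W * Cin * N);
  const arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    const arma::mat G(const_cast<double *>(gy.begin()) + R_xlen_t(n) * P * Cout,
                      P, Cout, false, true);
    arma::mat GA = G * Wm.t();
    col2im_add(GA, gx.begin() + R_xlen_t(n) * H * W * Cin, H, W, Cin,
               kh, kw, ph, pw, dh, dw, Ho, Wo);
  }
  gx.attr("dim") = xd;
  return gx;
}

// Gradients w.r.t. weights and bias; returns list(gw, gb).
// [[Rcpp::export]]
List conv2d_bw_w(NumericVector x, IntegerVector xd,
                 NumericVector gy, IntegerVector wd,
                 int ph, int pw, int dh, int dw) {
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = H + 2 * ph - dh * (kh - 1);
  const int Wo = W + 2 * pw - dw * (kw - 1);
  const int K = kh * kw * Cin, P = Ho * Wo;
  NumericVector gw(R_xlen_t(K) * Cout), gb(Cout);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::rowvec GB(gb.begin(), Cout, false, true);
  arma::mat A(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + R_xlen_t(n) * H * W * Cin, H, W, Cin,
           kh, kw, ph, pw, dh, dw, Ho, Wo, A);
    const arma::mat G(const_cast<double *>(gy.begin()) + R_xlen_t(n) * P * Cout,
                      P, Cout, false, true);
    GW += A.t() * G;
    GB += arma::sum(G, 0);
  }
  gw.attr("dim") = wd;
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pool, stride 2; H and W must be even. Returns y plus the flat
// (1-based) argmax index into x for the adjoint.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  IntegerVector idx(R_xlen_t(Ho) * Wo * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double best = -DBL_MAX; int bidx = -1;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int k = idx4(2 * io + di, 2 * jo + dj, c, n, H, W, C);
              if (px[k] > best) { best = px[k]; bidx = k; }
            }
          const int o = idx4(io, jo, c, n, Ho, Wo, C);
          py[o] = best; pi[o] = bidx + 1;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector gy, IntegerVector idx, IntegerVector xd) {
  NumericVector gx(R_xlen_t(xd[0]) * xd[1] * xd[2] * xd[3]);
  const double *pgy = gy.begin();
  const int *pi = idx.begin();
  double *pgx = gx.begin();
  const R_xlen_t m = gy.size();
  for (R_xlen_t k = 0; k < m; ++k) pgx[pi[k] - 1] += pgy[k];
  gx.attr("dim") = xd;
  return gx;
}

// Bilinear resize with half-pixel centers; linear in x so the adjoint is the
// transpose scatter.
static void bilin_coef(int o, int I, int O, int &i0, int &i1, double &t) {
  double s = (o + 0.5) * (double)I / O - 0.5;
  if (s < 0) s = 0;
  if (s > I - 1) s = I - 1;
  i0 = (int)s;
  i1 = i0 + 1 < I ? i0 + 1 : I - 1;
  t = s - i0;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_fw(NumericVector x, IntegerVector xd, int Ho, int Wo) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int jo = 0; jo < Wo; ++jo) {
        int j0, j1; double tj;
        bilin_coef(jo, W, Wo, j0, j1, tj);
        for (int io = 0; io < Ho; ++io) {
          int i0, i1; double ti;
          bilin_coef(io, H, Ho, i0, i1, ti);
          const double v =
            (1 - ti) * (1 - tj) * px[idx4(i0, j0, c, n, H, W, C)] +
            ti * (1 - tj) * px[idx4(i1, j0, c, n, H, W, C)] +
            (1 - ti) * tj * px[idx4(i0, j1, c, n, H, W, C)] +
            ti * tj * px[idx4(i1, j1, c, n, H, W, C)];
          py[idx4(io, jo, c, n, Ho, Wo, C)] = v;
        }
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bw(NumericVector gy, IntegerVector xd, int Ho, int Wo) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector gx(R_xlen_t(H) * W * C * N);
  const double *pgy = gy.begin();
  double *pgx = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int jo = 0; jo < Wo; ++jo) {
        int j0, j1; double tj;
        bilin_coef(jo, W, Wo, j0, j1, tj);
        for (int io = 0; io < Ho; ++io) {
          int i0, i1; double ti;
          bilin_coef(io, H, Ho, i0, i1, ti);
          const double g = pgy[idx4(io, jo, c, n, Ho, Wo, C)];
          pgx[idx4(i0, j0, c, n, H, W, C)] += (1 - ti) * (1 - tj) * g;
          pgx[idx4(i1, j0, c, n, H, W, C)] += ti * (1 - tj) * g;
          pgx[idx4(i0, j1, c, n, H, W, C)] += (1 - ti) * tj * g;
          pgx[idx4(i1, j1, c, n, H, W, C)] += ti * tj * g;
        }
      }
  gx.attr("dim") = xd;
  return gx;
}
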