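#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Symmetric (edge-inclusive) boundary extension:
//   ... x2 x1 x0 | x0 x1 ... x(n-1) | x(n-1) x(n-2) ...
static inline int reflect_sym(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 2-D multi-channel cross-correlation with symmetric boundary extension.
// x: H x W x Cin array, w: kh x kw x Cin x Cout, b: length Cout.
// Output has the same spatial dimensions as the input.
// [[Rcpp::export]]
NumericVector conv2d_sym(NumericVector x, NumericVector w, NumericVector b,
                         bool relu) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 3 || wd.size() != 4) stop("bad array ranks");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("input channel mismatch");
  if (b.size() != Cout) stop("bias length mismatch");
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel sides must be odd");
  const int rh = (kh - 1) / 2, rw = (kw - 1) / 2;
  if (rh >= H || rw >= W) stop("image smaller than kernel radius");

  NumericVector y((R_xlen_t)H * W * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout);

  std::vector<int> ridx((size_t)kh * H), cidx((size_t)kw * W);
  for (int ki = 0; ki < kh; ++ki)
    for (int i = 0; i < H; ++i)
      ridx[(size_t)ki * H + i] = reflect_sym(i + ki - rh, H);
  for (int kj = 0; kj < kw; ++kj)
    for (int j = 0; j < W; ++j)
      cidx[(size_t)kj * W + j] = reflect_sym(j + kj - rw, W);

  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;

  for (int co = 0; co < Cout; ++co) {
    double *yc = yp + co * plane;
    for (R_xlen_t t = 0; t < plane; ++t) yc[t] = b[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xp + ci * plane;
      const double *wk = wp + (R_xlen_t)kh * kw * (ci + (R_xlen_t)Cin * co);
      for (int kj = 0; kj < kw; ++kj) {
        const int *cj = &cidx[(size_t)kj * W];
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wk[ki + kh * kj];
          if (wv == 0.0) continue;
          const int *ri = &ridx[(size_t)ki * H];
          for (int j = 0; j < W; ++j) {
            const double *xcol = xc + (R_xlen_t)cj[j] * H;
            double *ycol = yc + (R_xlen_t)j * H;
            for (int i = 0; i < H; ++i) ycol[i] += wv * xcol[ri[i]];
          }
        }
      }
    }
    if (relu)
      for (R_xlen_t t = 0; t < plane; ++t)
        if (yc[t] < 0) yc[t] = 0;
  }
  return y;
}

// Gradients of conv2d_sym (pre-activation) w.r.t. input, weights, biases.
// dy: H x W x Cout upstream gradient. Padding gradients fold back onto the
// mirrored source pixels.
// [[Rcpp::export]]
List conv2d_sym_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("input channel mismatch");
  if (yd[0] != H || yd[1] != W || yd[2] != Cout) stop("dy shape mismatch");
  const int rh = (kh - 1) / 2, rw = (kw - 1) / 2;

  NumericVector dx((R_xlen_t)H * W * Cin);
  dx.attr("dim") = IntegerVector::create(H, W, Cin);
  NumericVector dw((R_xlen_t)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);

  std::vector<int> ridx((size_t)kh * H), cidx((size_t)kw * W);
  for (int ki = 0; ki < kh; ++ki)
    for (int i = 0; i < H; ++i)
      ridx[(size_t)ki * H + i] = reflect_sym(i + ki - rh, H);
  for (int kj = 0; kj < kw; ++kj)
    for (int j = 0; j < W; ++j)
      cidx[(size_t)kj * W + j] = reflect_sym(j + kj - rw, W);

  const double *xp = x.begin(), *wp = w.begin(), *dyp = dy.begin();
  double *dxp = dx.begin(), *dwp = dw.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;

  for (int co = 0; co < Cout; ++co) {
    const double *dyc = dyp + co * plane;
    double acc = 0.0;
    for (R_xlen_t t = 0; t < plane; ++t) acc += dyc[t];
    db[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xp + ci * plane;
      double *dxc = dxp + ci * plane;
      const R_xlen_t wbase = (R_xlen_t)kh * kw * (ci + (R_xlen_t)Cin * co);
      for (int kj = 0; kj < kw; ++kj) {
        const int *cj = &cidx[(size_t)kj * W];
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wp[wbase + ki + kh * kj];
          const int *ri = &ridx[(size_t)ki * H];
          double g = 0.0;
          for (int j = 0; j < W; ++j) {
            const double *xcol = xc + (R_xlen_t)cj[j] * H;
            double *dxcol = dxc + (R_xlen_t)cj[j] * H;
            const double *dycol = dyc + (R_xlen_t)j * H;
            for (int i = 0; i < H; ++i) {
              const double dv = dycol[i];
              g += dv * xcol[ri[i]];
              dxcol[ri[i]] += dv * wv;
            }
          }
          dwp[wbase + ki + kh * kj] = g;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
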