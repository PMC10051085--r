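// Low-level tensor primitives for the segmentation networks.
//
// All tensors are R arrays with dim = (H, W, C, N), column-major, so the
// height axis has unit stride. Convolutions are computed by explicit
// im2col lowering followed by a BLAS matrix product (through Armadillo).
// The backward passes are the exact adjoints of the forward lowerings.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims {
  int h, w, c, n;
};

Dims get_dims(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return Dims{d[0], d[1], d[2], d[3]};
}

// Zero-padded copy of x along the two spatial axes.
arma::vec pad_spatial(const NumericVector &x, const Dims &d, int pad,
                      int &hp, int &wp) {
  hp = d.h + 2 * pad;
  wp = d.w + 2 * pad;
  arma::vec xp(static_cast<size_t>(hp) * wp * d.c * d.n, arma::fill::zeros);
  const double *src = x.begin();
  double *dst = xp.memptr();
  for (long cn = 0; cn < static_cast<long>(d.c) * d.n; ++cn) {
    const double *s = src + cn * static_cast<long>(d.h) * d.w;
    double *t = dst + cn * static_cast<long>(hp) * wp;
    for (int j = 0; j < d.w; ++j)
      std::memcpy(t + (j + pad) * static_cast<long>(hp) + pad,
                  s + j * static_cast<long>(d.h), sizeof(double) * d.h);
  }
  return xp;
}

// Lower the padded input to the im2col matrix M of size
// (ho*wo*n) x (kh*kw*c); column index = ci + c*(ky + kh*kx).
arma::mat im2col(const double *xp, const Dims &d, int hp, int wp,
                 int kh, int kw, int ho, int wo, int stride) {
  arma::mat M(static_cast<size_t>(ho) * wo * d.n,
              static_cast<size_t>(kh) * kw * d.c);
  const long plane = static_cast<long>(hp) * wp;
  for (int kx = 0; kx < kw; ++kx) {
    for (int ky = 0; ky < kh; ++ky) {
      for (int ci = 0; ci < d.c; ++ci) {
        double *col = M.colptr(ci + static_cast<long>(d.c) * (ky + kh * kx));
        for (int ni = 0; ni < d.n; ++ni) {
          const double *img = xp + (static_cast<long>(ni) * d.c + ci) * plane;
          double *out = col + static_cast<long>(ni) * ho * wo;
          for (int ix = 0; ix < wo; ++ix) {
            const double *s = img + (kx + ix * stride) * static_cast<long>(hp) + ky;
            double *t = out + static_cast<long>(ix) * ho;
            if (stride == 1) {
              std::memcpy(t, s, sizeof(double) * ho);
            } else {
              for (int iy = 0; iy < ho; ++iy) t[iy] = s[iy * stride];
            }
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter-add the column matrix back onto the
// padded input gradient.
void col2im(const arma::mat &M, double *dxp, const Dims &d, int hp, int wp,
            int kh, int kw, int ho, int wo, int stride) {
  const long plane = static_cast<long>(hp) * wp;
  for (int kx = 0; kx < kw; ++kx) {
    for (int ky = 0; ky < kh; ++ky) {
      for (int ci = 0; ci < d.c; ++ci) {
        const double *col = M.colptr(ci + static_cast<long>(d.c) * (ky + kh * kx));
        for (int ni = 0; ni < d.n; ++ni) {
          double *img = dxp + (static_cast<long>(ni) * d.c + ci) * plane;
          const double *in = col + static_cast<long>(ni) * ho * wo;
          for (int ix = 0; ix < wo; ++ix) {
            double *t = img + (kx + ix * stride) * static_cast<long>(hp) + ky;
            const double *s = in + static_cast<long>(ix) * ho;
            for (int iy = 0; iy < ho; ++iy) t[iy * stride] += s[iy];
          }
        }
      }
    }
  }
}

// Reshape kernel array (kh, kw, ci, co) to the (ci*kh*kw) x co matrix
// whose row order matches the im2col column order.
arma::mat kernel_matrix(const NumericVector &w, int kh, int kw, int ci, int co) {
  arma::mat Wm(static_cast<size_t>(kh) * kw * ci, co);
  const double *src = w.begin();
  for (int o = 0; o < co; ++o)
    for (int c = 0; c < ci; ++c)
      for (int kx = 0; kx < kw; ++kx)
        for (int ky = 0; ky < kh; ++ky)
          Wm(c + static_cast<long>(ci) * (ky + kh * kx), o) =
              src[ky + static_cast<long>(kh) * (kx + static_cast<long>(kw) * (c + static_cast<long>(ci) * o))];
  return Wm;
}

// (ho*wo*n) x co matrix -> (ho, wo, co, n) array
NumericVector spatial_to_array(const arma::mat &Y, int ho, int wo, int co, int n) {
  NumericVector out(static_cast<long>(ho) * wo * co * n);
  double *dst = out.begin();
  const long plane = static_cast<long>(ho) * wo;
  for (int o = 0; o < co; ++o) {
    const double *col = Y.colptr(o);
    for (int ni = 0; ni < n; ++ni)
      std::memcpy(dst + (static_cast<long>(ni) * co + o) * plane,
                  col + static_cast<long>(ni) * plane, sizeof(double) * plane);
  }
  out.attr("dim") = IntegerVector::create(ho, wo, co, n);
  return out;
}

// (h, w, c, n) array -> (h*w*n) x c matrix (adjoint of spatial_to_array)
arma::mat array_to_spatial(const NumericVector &x, const Dims &d) {
  arma::mat M(static_cast<size_t>(d.h) * d.w * d.n, d.c);
  const double *src = x.begin();
  const long plane = static_cast<long>(d.h) * d.w;
  for (int o = 0; o < d.c; ++o) {
    double *col = M.colptr(o);
    for (int ni = 0; ni < d.n; ++ni)
      std::memcpy(col + static_cast<long>(ni) * plane,
                  src + (static_cast<long>(ni) * d.c + o) * plane,
                  sizeof(double) * plane);
  }
  return M;
}

} // namespace

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  Dims d = get_dims(x);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], ci = wd[2], co = wd[3];
  if (ci != d.c) stop("input has %d channels but kernel expects %d", d.c, ci);
  int hp, wp;
  arma::vec xp = pad_spatial(x, d, pad, hp, wp);
  int ho = (d.h + 2 * pad - kh) / stride + 1;
  int wo = (d.w + 2 * pad - kw) / stride + 1;
  arma::mat M = im2col(xp.memptr(), d, hp, wp, kh, kw, ho, wo, stride);
  arma::mat Wm = kernel_matrix(w, kh, kw, ci, co);
  arma::mat Y = M * Wm;
  Y.each_row() += arma::rowvec(b.begin(), co);
  return spatial_to_array(Y, ho, wo, co, d.n);
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  Dims d = get_dims(x);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], ci = wd[2], co = wd[3];
  Dims dd = get_dims(dy);
  int ho = dd.h, wo = dd.w;
  int hp, wp;
  arma::vec xp = pad_spatial(x, d, pad, hp, wp);
  arma::mat M = im2col(xp.memptr(), d, hp, wp, kh, kw, ho, wo, stride);
  arma::mat dY = array_to_spatial(dy, dd);
  arma::mat dWm = M.t() * dY;                 // (ci*kh*kw) x co
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * kernel_matrix(w, kh, kw, ci, co).t();
  arma::vec dxp(static_cast<size_t>(hp) * wp * d.c * d.n, arma::fill::zeros);
  col2im(dM, dxp.memptr(), d, hp, wp, kh, kw, ho, wo, stride);

  // strip padding
  NumericVector dx(static_cast<long>(d.h) * d.w * d.c * d.n);
  const long plane = static_cast<long>(hp) * wp;
  for (long cn = 0; cn < static_cast<long>(d.c) * d.n; ++cn) {
    const double *s = dxp.memptr() + cn * plane;
    double *t = dx.begin() + cn * static_cast<long>(d.h) * d.w;
    for (int j = 0; j < d.w; ++j)
      std::memcpy(t + j * static_cast<long>(d.h),
                  s + (j + pad) * static_cast<long>(hp) + pad,
                  sizeof(double) * d.h);
  }
  dx.attr("dim") = IntegerVector::create(d.h, d.w, d.c, d.n);

  // kernel gradient back to (kh, kw, ci, co)
  NumericVector dW(static_cast<long>(kh) * kw * ci * co);
  for (int o = 0; o < co; ++o)
    for (int c = 0; c < ci; ++c)
      for (int kx = 0; kx < kw; ++kx)
        for (int ky = 0; ky < kh; ++ky)
          dW[ky + static_cast<long>(kh) * (kx + static_cast<long>(kw) * (c + static_cast<long>(ci) * o))] =
              dWm(c + static_cast<long>(ci) * (ky + kh * kx), o);
  dW.attr("dim") = IntegerVector::create(kh, kw, ci, co);

  return List::create(Named("dx") = dx, Named("dw") = dW,
                      Named("db") = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  Dims d = get_dims(x);
  if (d.h % 2 || d.w % 2) stop("maxpool2 requires even spatial dims");
  int ho = d.h / 2, wo = d.w / 2;
  NumericVector y(static_cast<long>(ho) * wo * d.c * d.n);
  IntegerVector arg(y.size());
  const double *src = x.begin();
  for (long cn = 0; cn < static_cast<long>(d.c) * d.n; ++cn) {
    const double *img = src + cn * static_cast<long>(d.h) * d.w;
    double *out = y.begin() + cn * static_cast<long>(ho) * wo;
    int *am = arg.begin() + cn * static_cast<long>(ho) * wo;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        long base = static_cast<long>(2 * j) * d.h + 2 * i;
        // candidates: (0,0), (1,0), (0,1), (1,1) offsets in (row, col)
        long idx[4] = {base, base + 1, base + d.h, base + d.h + 1};
        int best = 0;
        for (int k = 1; k < 4; ++k)
          if (img[idx[k]] > img[idx[best]]) best = k;
        out[static_cast<long>(j) * ho + i] = img[idx[best]];
        am[static_cast<long>(j) * ho + i] = static_cast<int>(idx[best]);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(ho, wo, d.c, d.n);
  arg.attr("dim") = IntegerVector::create(ho, wo, d.c, d.n);
  return List::create(Named("y") = y, Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector argmax,
                                int h, int w) {
  Dims d = get_dims(dy);
  NumericVector dx(static_cast<long>(h) * w * d.c * d.n);
  const double *g = dy.begin();
  const int *am = argmax.begin();
  for (long cn = 0; cn < static_cast<long>(d.c) * d.n; ++cn) {
    double *img = dx.begin() + cn * static_cast<long>(h) * w;
    long off = cn * static_cast<long>(d.h) * d.w;
    for (long k = 0; k < static_cast<long>(d.h) * d.w; ++k)
      img[am[off + k]] += g[off + k];
  }
  dx.attr("dim") = IntegerVector::create(h, w, d.c, d.n);
  return dx;
}

// [[Rcpp::export(name = ".upsample2_forward")]]
NumericVector upsample2_forward(NumericVector x) {
  Dims d = get_dims(x);
  int ho = 2 * d.h, wo = 2 * d.w;
  NumericVector y(static_cast<long>(ho) * wo * d.c * d.n);
  const double *src = x.begin();
  for (long cn = 0; cn < static_cast<long>(d.c) * d.n; ++cn) {
    const double *img = src + cn * static_cast<long>(d.h) * d.w;
    double *out = y.begin() + cn * static_cast<long>(ho) * wo;
    for (int j = 0; j < d.w; ++j) {
      for (int i = 0; i < d.h; ++i) {
        double v = img[static_cast<long>(j) * d.h + i];
        long b = static_cast<long>(2 * j) * ho + 2 * i;
        out[b] = v;
        out[b + 1] = v;
        out[b + ho] = v;
        out[b + ho + 1] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(ho, wo, d.c, d.n);
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
NumericVector upsample2_backward(NumericVector dy) {
  Dims d = get_dims(dy);
  if (d.h % 2 || d.w % 2) stop("gradient dims must be even");
  int ho = d.h / 2, wo = d.w / 2;
  NumericVector dx(static_cast<long>(ho) * wo * d.c * d.n);
  const double *g = dy.begin();
  for (long cn = 0; cn < static_cast<long>(d.c) * d.n; ++cn) {
    const double *img = g + cn * static_cast<long>(d.h) * d.w;
    double *out = dx.begin() + cn * static_cast<long>(ho) * wo;
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        long b = static_cast<long>(2 * j) * d.h + 2 * i;
        out[static_cast<long>(j) * ho + i] =
            img[b] + img[b + 1] + img[b + d.h] + img[b + d.h + 1];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(ho, wo, d.c, d.n);
  return dx;
}
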