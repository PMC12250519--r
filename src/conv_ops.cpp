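// Compiled numerical kernels: 2-D convolution (im2col + BLAS gemm),
// 2x2 transposed convolution, 2x2 max pooling, and BM3D block matching.
//
// Array layout follows R's column-major convention throughout:
// feature maps are (H, W, C, N), convolution weights (kh, kw, Cin/groups, Cout).

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void check_dims4(const NumericVector &x, const char *what) {
  if (Rf_isNull(x.attr("dim")) || IntegerVector(x.attr("dim")).size() != 4)
    stop("%s must be a 4-d array (H, W, C, N)", what);
}

// Fill the im2col matrix for one image and one channel group.
// col is (Ho*Wo) x (kh*kw*Cin_pg); column q = ki + kh*kj + kh*kw*cl matches
// the memory order of the (kh, kw, Cin_pg, Cout) weight array.
static void im2col(const double *x, int H, int W,
                   int c0, int Cin_pg, int kh, int kw, int pad,
                   arma::mat &col) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int cl = 0; cl < Cin_pg; ++cl) {
    const double *xc = x + (size_t)(c0 + cl) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * kj + kh * kw * cl;
        double *dst = col.colptr(q);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow - pad + kj;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < Ho; ++oh) dst[oh + (size_t)Ho * ow] = 0.0;
            continue;
          }
          const double *src = xc + (size_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh - pad + ki;
            dst[oh + (size_t)Ho * ow] =
                (ih < 0 || ih >= H) ? 0.0 : src[ih];
          }
        }
      }
    }
  }
}

// Scatter-add the columns back into the (padded) input gradient.
static void col2im_add(const arma::mat &col, double *dx, int H, int W,
                       int c0, int Cin_pg, int kh, int kw, int pad) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int cl = 0; cl < Cin_pg; ++cl) {
    double *xc = dx + (size_t)(c0 + cl) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * kj + kh * kw * cl;
        const double *src = col.colptr(q);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow - pad + kj;
          if (iw < 0 || iw >= W) continue;
          double *dcol = xc + (size_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh - pad + ki;
            if (ih >= 0 && ih < H) dcol[ih] += src[oh + (size_t)Ho * ow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int pad, int groups) {
  check_dims4(x, "x"); check_dims4(w, "w");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin_pg = wd[2], Cout = wd[3];
  if (groups < 1 || C % groups || Cout % groups)
    stop("channel counts (%d in, %d out) not divisible by groups=%d", C, Cout, groups);
  if (Cin_pg != C / groups) stop("weight in-channels do not match input");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int Cout_pg = Cout / groups;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  NumericVector y(Ho * (size_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(Ho * (size_t)Wo, (size_t)kh * kw * Cin_pg);

  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * H * W * C;
    double *yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cin_pg, Cin_pg, kh, kw, pad, col);
      const arma::mat wmat(const_cast<double *>(w.begin()) +
                               (size_t)g * Cout_pg * kh * kw * Cin_pg,
                           (size_t)kh * kw * Cin_pg, Cout_pg, false, true);
      arma::mat ymat(yn + (size_t)g * Cout_pg * Ho * Wo,
                     (size_t)Ho * Wo, Cout_pg, false, true);
      ymat = col * wmat;
      for (int co = 0; co < Cout_pg; ++co)
        ymat.col(co) += bias[g * Cout_pg + co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int pad, int groups) {
  check_dims4(x, "x"); check_dims4(w, "w"); check_dims4(dy, "dy");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin_pg = wd[2], Cout = wd[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int Cout_pg = Cout / groups;

  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat col(Ho * (size_t)Wo, (size_t)kh * kw * Cin_pg);

  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * H * W * C;
    const double *dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    double *dxn = dx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cin_pg, Cin_pg, kh, kw, pad, col);
      const arma::mat wmat(const_cast<double *>(w.begin()) +
                               (size_t)g * Cout_pg * kh * kw * Cin_pg,
                           (size_t)kh * kw * Cin_pg, Cout_pg, false, true);
      arma::mat dwmat(dw.begin() + (size_t)g * Cout_pg * kh * kw * Cin_pg,
                      (size_t)kh * kw * Cin_pg, Cout_pg, false, true);
      const arma::mat dymat(const_cast<double *>(dyn) +
                                (size_t)g * Cout_pg * Ho * Wo,
                            (size_t)Ho * Wo, Cout_pg, false, true);
      dwmat += col.t() * dymat;
      arma::mat dcol = dymat * wmat.t();
      col2im_add(dcol, dxn, H, W, g * Cin_pg, Cin_pg, kh, kw, pad);
      for (int co = 0; co < Cout_pg; ++co)
        db[g * Cout_pg + co] += arma::accu(dymat.col(co));
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed 2x2 stride-2 convolution (the UNet upsampling operator).
// Weight layout (2, 2, Cout, Cin): y(2h+i, 2w+j, co) = sum_ci x(h,w,ci) w(i,j,co,ci).
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w,
                             NumericVector bias) {
  check_dims4(x, "x"); check_dims4(w, "w");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[2], Cin = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || Cin != C) stop("weight must be (2,2,Cout,Cin)");
  const int Ho = 2 * H, Wo = 2 * W;

  // M: (Cin) x (4*Cout) from the (4*Cout) x Cin memory view.
  const arma::mat wv(const_cast<double *>(w.begin()), 4 * (size_t)Cout, Cin,
                     false, true);
  arma::mat M = wv.t();

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    const arma::mat xmat(const_cast<double *>(x.begin()) + (size_t)n * H * W * C,
                         (size_t)H * W, C, false, true);
    arma::mat R = xmat * M;  // (H*W) x (4*Cout)
    double *yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double *yc = yn + (size_t)co * Ho * Wo;
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          const double *src = R.colptr(i + 2 * j + 4 * co);
          for (int wcol = 0; wcol < W; ++wcol)
            for (int h = 0; h < H; ++h)
              yc[(2 * h + i) + (size_t)Ho * (2 * wcol + j)] =
                  src[h + (size_t)H * wcol] + bias[co];
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[2];
  const int Ho = 2 * H, Wo = 2 * W;

  const arma::mat wv(const_cast<double *>(w.begin()), 4 * (size_t)Cout, C,
                     false, true);
  arma::mat M = wv.t();  // Cin x 4Cout

  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dM(C, 4 * (size_t)Cout, arma::fill::zeros);
  arma::mat dR((size_t)H * W, 4 * (size_t)Cout);

  for (int n = 0; n < N; ++n) {
    const double *dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double *dyc = dyn + (size_t)co * Ho * Wo;
      double s = 0.0;
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          double *dst = dR.colptr(i + 2 * j + 4 * co);
          for (int wcol = 0; wcol < W; ++wcol)
            for (int h = 0; h < H; ++h) {
              const double v = dyc[(2 * h + i) + (size_t)Ho * (2 * wcol + j)];
              dst[h + (size_t)H * wcol] = v;
              s += v;
            }
        }
      db[co] += s;
    }
    const arma::mat xmat(const_cast<double *>(x.begin()) + (size_t)n * H * W * C,
                         (size_t)H * W, C, false, true);
    arma::mat dxmat(dx.begin() + (size_t)n * H * W * C, (size_t)H * W, C,
                    false, true);
    dxmat = dR * M.t();
    dM += xmat.t() * dR;
  }
  arma::mat dwv(dw.begin(), 4 * (size_t)Cout, C, false, true);
  dwv = dM.t();
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  check_dims4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("max pooling requires even H and W (got %d x %d)", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 1-based linear index into x of each max
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double *xc = x.begin() + (size_t)cn * H * W;
    const size_t base = (size_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        size_t p = 2 * oh + (size_t)H * (2 * ow);
        double best = xc[p]; size_t bi = p;
        if (xc[p + 1] > best) { best = xc[p + 1]; bi = p + 1; }
        if (xc[p + H] > best) { best = xc[p + H]; bi = p + H; }
        if (xc[p + H + 1] > best) { best = xc[p + H + 1]; bi = p + H + 1; }
        y[o] = best;
        idx[o] = (int)(base + bi + 1);
        ++o;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Exhaustive similar-block search for BM3D. Candidates are block top-left
// positions within Chebyshev distance `half` of the reference top-left, fully
// inside the image; ranked by squared distance to the reference block with
// ties broken by scan order (rows fastest), reference always first.
// [[Rcpp::export]]
List cpp_block_match(NumericMatrix img, int ref_r, int ref_c, int block,
                     int search, int max_group) {
  const int H = img.nrow(), W = img.ncol();
  if (ref_r < 1 || ref_c < 1 || ref_r + block - 1 > H || ref_c + block - 1 > W)
    stop("reference block (%d,%d) not fully inside the image", ref_r, ref_c);
  const int half = (search - block) / 2;
  const int r0 = std::max(1, ref_r - half), r1 = std::min(H - block + 1, ref_r + half);
  const int c0 = std::max(1, ref_c - half), c1 = std::min(W - block + 1, ref_c + half);

  std::vector<int> rr, cc;
  std::vector<double> dd;
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r) {
      if (r == ref_r && c == ref_c) continue;
      double d = 0.0;
      for (int j = 0; j < block; ++j)
        for (int i = 0; i < block; ++i) {
          const double v = img(r - 1 + i, c - 1 + j) -
                           img(ref_r - 1 + i, ref_c - 1 + j);
          d += v * v;
        }
      rr.push_back(r); cc.push_back(c); dd.push_back(d);
    }
  std::vector<size_t> ord(dd.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return dd[a] < dd[b]; });
  const int keep = std::min((int)ord.size(), max_group - 1);
  IntegerVector rows(keep + 1), cols(keep + 1);
  NumericVector dist(keep + 1);
  rows[0] = ref_r; cols[0] = ref_c; dist[0] = 0.0;
  for (int i = 0; i < keep; ++i) {
    rows[i + 1] = rr[ord[i]];
    cols[i + 1] = cc[ord[i]];
    dist[i + 1] = dd[ord[i]];
  }
  return List::create(_["rows"] = rows, _["cols"] = cols, _["dist"] = dist);
}
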