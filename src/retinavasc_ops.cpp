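// Low-level numerical kernels: GEMM-style convolution lowering (im2col /
// col2im), max pooling with argmax bookkeeping, Zhang-Suen skeletonization,
// and anti-aliased vascular-segment rasterization.
//
// Array layout convention throughout: batches are column-major R arrays with
// dim (H, W, C, N); image coordinates are 0-based with x = column, y = row.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Lower a (H, W, C, N) batch into a (k*k*C) x (Ho*Wo*N) matrix so that
// convolution becomes a single GEMM. Row order: (dh, dw, c), dh fastest;
// column order: (ho, wo, n), ho fastest.
// [[Rcpp::export(name = ".im2col_cpp")]]
arma::mat im2col_cpp(const arma::vec& x, int H, int W, int C, int N,
                     int k, int pad, int stride) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat out(k * k * C, (size_t)Ho * Wo * N, arma::fill::zeros);
  const double* xp = x.memptr();
  const size_t planeHW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * n;
        double* op = out.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + planeHW * ((size_t)c + (size_t)C * n);
          for (int dw = 0; dw < k; ++dw) {
            const int w = wo * stride - pad + dw;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * stride - pad + dh;
              const size_t row = (size_t)dh + (size_t)k * dw + (size_t)k * k * c;
              if (h >= 0 && h < H && w >= 0 && w < W)
                op[row] = xc[(size_t)h + (size_t)H * w];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: accumulate a (k*k*C) x (Ho*Wo*N) matrix of column
// gradients back into a (H, W, C, N) batch gradient.
// [[Rcpp::export(name = ".col2im_cpp")]]
arma::vec col2im_cpp(const arma::mat& cols, int H, int W, int C, int N,
                     int k, int pad, int stride) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::vec out((size_t)H * W * C * N, arma::fill::zeros);
  double* xp = out.memptr();
  const size_t planeHW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * n;
        const double* cp = cols.colptr(col);
        for (int c = 0; c < C; ++c) {
          double* xc = xp + planeHW * ((size_t)c + (size_t)C * n);
          for (int dw = 0; dw < k; ++dw) {
            const int w = wo * stride - pad + dw;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * stride - pad + dh;
              if (h >= 0 && h < H && w >= 0 && w < W) {
                const size_t row = (size_t)dh + (size_t)k * dw + (size_t)k * k * c;
                xc[(size_t)h + (size_t)H * w] += cp[row];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Non-overlapping p x p max pooling; returns pooled values and the 1-based
// linear argmax indices into the input (for the backward scatter).
// [[Rcpp::export(name = ".maxpool_cpp")]]
List maxpool_cpp(const arma::vec& x, int H, int W, int C, int N, int p) {
  const int Ho = H / p, Wo = W / p;
  arma::vec y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  const double* xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dw = 0; dw < p; ++dw) {
            for (int dh = 0; dh < p; ++dh) {
              const size_t idx = base + (size_t)(ho * p + dh) +
                                 (size_t)H * (wo * p + dw);
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          // output layout (Ho, Wo, C, N): ho fastest, then wo
          const size_t oi = (size_t)ho + (size_t)Ho * wo +
                            (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
          y(oi) = best;
          arg[oi] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
arma::vec maxpool_bwd_cpp(const arma::vec& dy, const IntegerVector& arg,
                          size_t input_len) {
  arma::vec dx(input_len, arma::fill::zeros);
  for (R_xlen_t i = 0; i < arg.size(); ++i) dx(arg[i] - 1) += dy(i);
  return dx;
}

// Layout shuffles between the GEMM result (C x Ho*Wo*N, channel-first)
// and the (Ho, Wo, C, N) activation layout, avoiding R-level aperm.
// [[Rcpp::export(name = ".chw_to_hwc_cpp")]]
NumericVector chw_to_hwc_cpp(const NumericMatrix& ymat, int Ho, int Wo,
                             int N) {
  const int C = ymat.nrow();
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  double* op = REAL(out);
  const double* yp = ymat.begin();
  const size_t HW = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const double* ycol = yp + (size_t)C * HW * n;
    double* obase = op + HW * (size_t)C * n;
    for (int c = 0; c < C; ++c) {
      double* oc = obase + HW * c;
      const double* yc = ycol + c;
      for (size_t i = 0; i < HW; ++i) oc[i] = yc[(size_t)C * i];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".hwc_to_chw_cpp")]]
NumericMatrix hwc_to_chw_cpp(const NumericVector& x, int Ho, int Wo, int C,
                             int N) {
  NumericMatrix out(C, (R_xlen_t)Ho * Wo * N);
  double* op = out.begin();
  const double* xp = REAL(x);
  const size_t HW = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const double* xbase = xp + HW * (size_t)C * n;
    double* ocol = op + (size_t)C * HW * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xbase + HW * c;
      double* oc = ocol + c;
      for (size_t i = 0; i < HW; ++i) oc[(size_t)C * i] = xc[i];
    }
  }
  return out;
}

static inline int px(const IntegerMatrix& M, int r, int c) {
  if (r < 0 || c < 0 || r >= M.nrow() || c >= M.ncol()) return 0;
  return M(r, c);
}

// Zhang-Suen thinning of a binary matrix (1 = foreground).
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  IntegerMatrix M = clone(mask);
  const int nr = M.nrow(), nc = M.ncol();
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<std::pair<int, int> > kill;
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!M(r, c)) continue;
          // neighbours p2..p9 clockwise starting north
          int p2 = px(M, r - 1, c),     p3 = px(M, r - 1, c + 1);
          int p4 = px(M, r, c + 1),     p5 = px(M, r + 1, c + 1);
          int p6 = px(M, r + 1, c),     p7 = px(M, r + 1, c - 1);
          int p8 = px(M, r, c - 1),     p9 = px(M, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int nb[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int i = 0; i < 8; ++i) if (nb[i] == 0 && nb[i + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        M(kill[i].first, kill[i].second) = 0;
    }
  }
  return M;
}

// Rasterize vessel segments. `segs` has columns x0, y0, x1, y1, width at
// the (x0, y0) end and width at the (x1, y1) end (0-based coordinates,
// x = column, y = row); the width tapers linearly along the segment.
// Returns the anti-aliased coverage field (max over segments, in [0,1])
// and the exact binary mask (distance to any centerline <= local width/2).
// [[Rcpp::export(name = ".render_segments_cpp")]]
List render_segments_cpp(const NumericMatrix& segs, int size) {
  NumericMatrix cov(size, size);
  IntegerMatrix mask(size, size);
  for (int s = 0; s < segs.nrow(); ++s) {
    const double x0 = segs(s, 0), y0 = segs(s, 1);
    const double x1 = segs(s, 2), y1 = segs(s, 3);
    const double w0 = segs(s, 4);
    const double w1 = segs.ncol() > 5 ? segs(s, 5) : w0;
    const double hwmax = std::max(w0, w1) / 2.0;
    const double dx = x1 - x0, dy = y1 - y0;
    const double len2 = dx * dx + dy * dy;
    const int cmin = std::max(0, (int)std::floor(std::min(x0, x1) - hwmax - 1));
    const int cmax = std::min(size - 1, (int)std::ceil(std::max(x0, x1) + hwmax + 1));
    const int rmin = std::max(0, (int)std::floor(std::min(y0, y1) - hwmax - 1));
    const int rmax = std::min(size - 1, (int)std::ceil(std::max(y0, y1) + hwmax + 1));
    for (int c = cmin; c <= cmax; ++c) {
      for (int r = rmin; r <= rmax; ++r) {
        double t = 0.0;
        if (len2 > 0)
          t = std::max(0.0, std::min(1.0, ((c - x0) * dx + (r - y0) * dy) / len2));
        const double ex = x0 + t * dx - c, ey = y0 + t * dy - r;
        const double d = std::sqrt(ex * ex + ey * ey);
        const double hw = (w0 + t * (w1 - w0)) / 2.0;
        const double a = std::max(0.0, std::min(1.0, hw + 0.5 - d));
        if (a > cov(r, c)) cov(r, c) = a;
        if (d <= hw) mask(r, c) = 1;
      }
    }
  }
  return List::create(_["coverage"] = cov, _["mask"] = mask);
}
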