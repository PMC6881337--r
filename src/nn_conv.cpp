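// Dilated "same" 2-D convolution kernels for the residual network.
//
// Layout conventions (match the R driver in R/residual_model.R):
//   x  : numeric array [H, W, Cin, N]  (column-major, R semantics)
//   wt : matrix (Cin*k*k) x Cout; row index q = (kj*k + ki)*Cin + c,
//        where (ki, kj) index the kernel tap and c the input channel
//   y  : numeric array [H, W, Cout, N]
// Zero padding of dil*(k-1)/2 on each side keeps spatial size unchanged.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C, int k, int dil,
                       arma::mat& col) {
  const int half = (k - 1) / 2;
  const int npix = H * W;
  col.zeros();
  for (int kj = 0; kj < k; ++kj) {
    const int dj = (kj - half) * dil;
    for (int ki = 0; ki < k; ++ki) {
      const int di = (ki - half) * dil;
      for (int c = 0; c < C; ++c) {
        const int q = (kj * k + ki) * C + c;
        double* dst = col.colptr(q);
        const double* src = x + (std::size_t)c * npix;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(H, H - di);
          const double* s = src + (std::size_t)sj * H + i0 + di;
          double* d = dst + (std::size_t)j * H + i0;
          std::copy(s, s + (i1 - i0), d);
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& col, int H, int W, int C, int k,
                       int dil, double* dx) {
  const int half = (k - 1) / 2;
  const int npix = H * W;
  for (int kj = 0; kj < k; ++kj) {
    const int dj = (kj - half) * dil;
    for (int ki = 0; ki < k; ++ki) {
      const int di = (ki - half) * dil;
      for (int c = 0; c < C; ++c) {
        const int q = (kj * k + ki) * C + c;
        const double* src = col.colptr(q);
        double* dst = dx + (std::size_t)c * npix;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(H, H - di);
          const double* s = src + (std::size_t)j * H + i0;
          double* d = dst + (std::size_t)sj * H + i0 + di;
          for (int i = 0; i < i1 - i0; ++i) d[i] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".nn_conv_fwd")]]
NumericVector nn_conv_fwd(NumericVector x, const arma::mat& wt,
                          const arma::vec& bias, int k, int dil) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], Cin = dm[2], N = dm[3];
  const int Cout = wt.n_cols;
  const int npix = H * W;
  NumericVector y((std::size_t)npix * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(npix, Cin * k * k);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * npix * Cin;
    im2col_one(xn, H, W, Cin, k, dil, col);
    arma::mat ymat(y.begin() + (std::size_t)n * npix * Cout, npix, Cout,
                   false, true);
    ymat = col * wt;
    ymat.each_row() += bias.t();
  }
  return y;
}

// [[Rcpp::export(name = ".nn_conv_bwd")]]
List nn_conv_bwd(NumericVector x, const arma::mat& wt, NumericVector dy,
                 int k, int dil) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], Cin = dm[2], N = dm[3];
  const int Cout = wt.n_cols;
  const int npix = H * W;
  NumericVector dx((std::size_t)npix * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dwt(Cin * k * k, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(npix, Cin * k * k);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * npix * Cin;
    im2col_one(xn, H, W, Cin, k, dil, col);
    arma::mat dymat(dy.begin() + (std::size_t)n * npix * Cout, npix, Cout,
                    false, true);
    dwt += col.t() * dymat;
    db += arma::sum(dymat, 0).t();
    arma::mat dcol = dymat * wt.t();
    col2im_one(dcol, H, W, Cin, k, dil,
               dx.begin() + (std::size_t)n * npix * Cin);
  }
  return List::create(Named("dx") = dx, Named("dwt") = dwt,
                      Named("db") = db);
}

// Median filter with symmetric-reflect borders (edge pixel included in the
// reflection: index -1 maps to 0, index H maps to H-1, etc.).
// [[Rcpp::export(name = ".nn_median_filter")]]
NumericMatrix nn_median_filter(const NumericMatrix& x, int k) {
  const int H = x.nrow(), W = x.ncol();
  const int half = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> win((std::size_t)k * k);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int dj = -half; dj <= half; ++dj) {
        int sj = j + dj;
        while (sj < 0 || sj >= W) sj = (sj < 0) ? (-1 - sj) : (2 * W - 1 - sj);
        for (int di = -half; di <= half; ++di) {
          int si = i + di;
          while (si < 0 || si >= H) si = (si < 0) ? (-1 - si) : (2 * H - 1 - si);
          win[m++] = x(si, sj);
        }
      }
      std::nth_element(win.begin(), win.begin() + m / 2, win.begin() + m);
      out(i, j) = win[m / 2];
    }
  }
  return out;
}
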