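// Dense kernels for the multi-path U-Net: same-padding convolution (im2col +
// GEMM), non-overlapping transposed convolution (kernel == stride), max
// pooling with argmax bookkeeping, and connected-component labeling.
// Feature maps are arma::cube with dims (row, col, channel), one example at a
// time; weights are flat GEMM matrices (see R/layers.R for the layouts).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// im2col for odd k, stride 1, zero "same" padding.
// Output: (H*W) x (k*k*C); column index ((c*k + dj)*k + di) holds
// x(i + di - pad, j + dj - pad, c) for output pixel (i, j) at row i + j*H.
static mat im2col_same(const cube &x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  mat out(H * W, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = (c * k + dj) * k + di;
        const int oi = di - pad, oj = dj - pad;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi) - 1;
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj) - 1;
        if (i0 > i1 || j0 > j1) continue;
        mat view(out.colptr(col), H, W, false, true);
        view.submat(i0, j0, i1, j1) =
            x.slice(c).submat(i0 + oi, j0 + oj, i1 + oi, j1 + oj);
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col_same.
static cube col2im_same(const mat &cols, const int H, const int W,
                        const int C, const int k) {
  const int pad = k / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = (c * k + dj) * k + di;
        const int oi = di - pad, oj = dj - pad;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi) - 1;
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj) - 1;
        if (i0 > i1 || j0 > j1) continue;
        const mat view(const_cast<double *>(cols.colptr(col)), H, W, false,
                       true);
        x.slice(c).submat(i0 + oi, j0 + oj, i1 + oi, j1 + oj) +=
            view.submat(i0, j0, i1, j1);
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".cpp_conv2d")]]
arma::cube cpp_conv2d(const arma::cube &x, const arma::mat &w,
                      const arma::vec &b, const int k) {
  if ((uword)k * k * x.n_slices != w.n_rows)
    stop("conv2d: weight rows do not match k*k*C_in");
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat y = im2col_same(x, k) * w;
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Cout);
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
Rcpp::List cpp_conv2d_backward(const arma::cube &x, const arma::mat &w,
                               const arma::cube &gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const mat gy_mat(const_cast<double *>(gy.memptr()), (uword)H * W,
                   gy.n_slices, false, true);
  const mat cols = im2col_same(x, k);
  mat gw = cols.t() * gy_mat;
  vec gb = sum(gy_mat, 0).t();
  cube gx = col2im_same(gy_mat * w.t(), H, W, Cin, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cpp_maxpool")]]
Rcpp::List cpp_maxpool(const arma::cube &x, const int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % p != 0 || W % p != 0) stop("maxpool: dims not divisible by window");
  const int h = H / p, w = W / p;
  cube y(h, w, C);
  ucube idx(h, w, C); // linear index within the slice of the max element
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < p; ++dj) {
          for (int di = 0; di < p; ++di) {
            const uword ii = i * p + di, jj = j * p + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bi = ii + jj * H;
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
arma::cube cpp_maxpool_backward(const arma::ucube &idx, const arma::cube &gy,
                                const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double *slice = gx.slice_memptr(c);
    for (uword t = 0; t < gy.n_rows * gy.n_cols; ++t)
      slice[idx.slice(c)(t)] += gy.slice(c)(t);
  }
  return gx;
}

// Transposed convolution with kernel size == stride == p (blocks do not
// overlap). w: C_in x (p*p*C_out), column index ((co*p + dj)*p + di).
// [[Rcpp::export(name = ".cpp_deconv")]]
arma::cube cpp_deconv(const arma::cube &x, const arma::mat &w,
                      const arma::vec &b, const int p) {
  const int h = x.n_rows, wd = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols / (p * p);
  if ((uword)Cin != w.n_rows || (int)w.n_cols != p * p * Cout)
    stop("deconv: weight shape mismatch");
  const mat x_mat(const_cast<double *>(x.memptr()), (uword)h * wd, Cin, false,
                  true);
  const mat y_mat = x_mat * w; // (h*w) x (p*p*Cout)
  cube y(h * p, wd * p, Cout);
  for (int co = 0; co < Cout; ++co) {
    y.slice(co).fill(b(co));
    for (int dj = 0; dj < p; ++dj) {
      for (int di = 0; di < p; ++di) {
        const int col = (co * p + dj) * p + di;
        const mat view(const_cast<double *>(y_mat.colptr(col)), h, wd, false,
                       true);
        for (int j = 0; j < wd; ++j)
          for (int i = 0; i < h; ++i)
            y(i * p + di, j * p + dj, co) += view(i, j);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_deconv_backward")]]
Rcpp::List cpp_deconv_backward(const arma::cube &x, const arma::mat &w,
                               const arma::cube &gy, const int p) {
  const int h = x.n_rows, wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat g((uword)h * wd, (uword)p * p * Cout);
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    gb(co) = accu(gy.slice(co));
    for (int dj = 0; dj < p; ++dj) {
      for (int di = 0; di < p; ++di) {
        const int col = (co * p + dj) * p + di;
        mat view(g.colptr(col), h, wd, false, true);
        for (int j = 0; j < wd; ++j)
          for (int i = 0; i < h; ++i)
            view(i, j) = gy(i * p + di, j * p + dj, co);
      }
    }
  }
  const mat x_mat(const_cast<double *>(x.memptr()), (uword)h * wd, Cin, false,
                  true);
  mat gw = x_mat.t() * g;
  mat gx_mat = g * w.t();
  cube gx(gx_mat.memptr(), h, wd, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Connected-component labeling of a binary mask by iterative flood fill.
// connectivity: 4 or 8. Returns integer label matrix (0 = background).
// [[Rcpp::export(name = ".cpp_label_components")]]
Rcpp::IntegerMatrix cpp_label_components(const Rcpp::IntegerMatrix &mask,
                                         const int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  const int n_off = connectivity;
  const int off4[4][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1}};
  const int off8[8][2] = {{1, 0},  {-1, 0}, {0, 1},  {0, -1},
                          {1, 1},  {1, -1}, {-1, 1}, {-1, -1}};
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        const auto cur = stack.back();
        stack.pop_back();
        for (int o = 0; o < n_off; ++o) {
          const int ni = cur.first + (connectivity == 4 ? off4[o][0] : off8[o][0]);
          const int nj = cur.second + (connectivity == 4 ? off4[o][1] : off8[o][1]);
          if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back({ni, nj});
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
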