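// Performance kernels: BFS region growing / component labelling on rasters,
// and im2col-based convolution + max-pooling forward/backward passes used by
// the network trainer. Tensor layout throughout is the column-major R array
// (h, w, c, n); weights are (k, k, c_in, c_out).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int OFF8R[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int OFF8C[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int N4R[4] = {-1, 1, 0, 0};
static const int N4C[4] = {0, 0, -1, 1};

// Region growing: a pixel joins the region grown from seed s iff it is
// connected to s through pixels whose gray distance to the *seed's* value is
// <= thr. Result is the union over seeds; visit order cannot change it.
// [[Rcpp::export]]
LogicalMatrix cpp_region_grow(NumericMatrix img, IntegerMatrix seeds,
                              double thr, int connectivity) {
  const int h = img.nrow(), w = img.ncol();
  LogicalMatrix out(h, w);
  const int nn = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? N4R : OFF8R;
  const int *dc = (connectivity == 4) ? N4C : OFF8C;
  std::vector<char> visited((size_t)h * w, 0);
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int sr = seeds(s, 0), sc = seeds(s, 1); // 0-based
    if (sr < 0 || sr >= h || sc < 0 || sc >= w)
      stop("seed out of image bounds");
    const double sv = img(sr, sc);
    std::fill(visited.begin(), visited.end(), 0);
    std::queue<int> q;
    q.push(sr + h * sc);
    visited[sr + (size_t)h * sc] = 1;
    out(sr, sc) = true;
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      const int pr = p % h, pc = p / h;
      for (int k = 0; k < nn; ++k) {
        const int r = pr + dr[k], c = pc + dc[k];
        if (r < 0 || r >= h || c < 0 || c >= w) continue;
        const size_t li = r + (size_t)h * c;
        if (visited[li]) continue;
        visited[li] = 1;
        if (std::abs(img(r, c) - sv) <= thr) {
          out(r, c) = true;
          q.push(r + h * c);
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (labels 1..n, 0 outside).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int nn = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? N4R : OFF8R;
  const int *dc = (connectivity == 4) ? N4C : OFF8C;
  int next = 0;
  for (int c0 = 0; c0 < w; ++c0) {
    for (int r0 = 0; r0 < h; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      std::queue<int> q;
      q.push(r0 + h * c0);
      lab(r0, c0) = next;
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int pr = p % h, pc = p / h;
        for (int k = 0; k < nn; ++k) {
          const int r = pr + dr[k], c = pc + dc[k];
          if (r < 0 || r >= h || c < 0 || c >= w) continue;
          if (mask(r, c) && lab(r, c) == 0) {
            lab(r, c) = next;
            q.push(r + h * c);
          }
        }
      }
    }
  }
  return lab;
}

static inline arma::mat im2col_same(const double *x, int h, int w, int ci,
                                    int k, int pad) {
  // rows: output positions (h*w), cols: (ki, kj, c) flattened column-major
  arma::mat col(h * w, k * k * ci, arma::fill::zeros);
  for (int c = 0; c < ci; ++c) {
    const double *plane = x + (size_t)h * w * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int colidx = ki + k * kj + k * k * c;
        for (int j = 0; j < w; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= w) continue;
          for (int i = 0; i < h; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= h) continue;
            col(i + h * j, colidx) = plane[si + (size_t)h * sj];
          }
        }
      }
    }
  }
  return col;
}

// 'same' cross-correlation, stride 1, odd kernel, zero padding.
// x: (h, w, ci, n); wgt: (k, k, ci, co); bias: co.
// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericVector wgt,
                               NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");
  const int h = xd[0], w = xd[1], ci = xd[2], n = xd[3];
  const int k = wd[0], co = wd[3];
  if (wd[1] != k || wd[2] != ci) stop("kernel dims mismatch");
  const int pad = (k - 1) / 2;
  arma::mat W(const_cast<double *>(wgt.begin()), (size_t)k * k * ci, co,
              false, true);
  NumericVector y((size_t)h * w * co * n);
  y.attr("dim") = IntegerVector::create(h, w, co, n);
  for (int s = 0; s < n; ++s) {
    arma::mat col = im2col_same(x.begin() + (size_t)h * w * ci * s,
                                h, w, ci, k, pad);
    arma::mat out = col * W; // (h*w, co)
    double *yp = y.begin() + (size_t)h * w * co * s;
    for (int c = 0; c < co; ++c) {
      const double b = bias[c];
      for (int p = 0; p < h * w; ++p) yp[p + (size_t)h * w * c] = out(p, c) + b;
    }
  }
  return y;
}

// Backward pass for the same convolution. Returns list(dx, dw, db).
// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericVector wgt, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");
  const int h = xd[0], w = xd[1], ci = xd[2], n = xd[3];
  const int k = wd[0], co = wd[3];
  const int pad = (k - 1) / 2;
  arma::mat W(const_cast<double *>(wgt.begin()), (size_t)k * k * ci, co,
              false, true);
  NumericVector dx((size_t)h * w * ci * n);
  dx.attr("dim") = IntegerVector::create(h, w, ci, n);
  arma::mat dW((size_t)k * k * ci, co, arma::fill::zeros);
  arma::vec db(co, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    arma::mat col = im2col_same(x.begin() + (size_t)h * w * ci * s,
                                h, w, ci, k, pad);
    arma::mat dY(const_cast<double *>(dy.begin()) + (size_t)h * w * co * s,
                 (size_t)h * w, co, false, true);
    dW += col.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dcol = dY * W.t(); // (h*w, k*k*ci)
    double *dxp = dx.begin() + (size_t)h * w * ci * s;
    for (int c = 0; c < ci; ++c) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int colidx = ki + k * kj + k * k * c;
          for (int j = 0; j < w; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= w) continue;
            for (int i = 0; i < h; ++i) {
              const int si = i + ki - pad;
              if (si < 0 || si >= h) continue;
              dxp[si + (size_t)h * sj + (size_t)h * w * c] +=
                dcol(i + h * j, colidx);
            }
          }
        }
      }
    }
  }
  NumericVector dwR(dW.begin(), dW.end());
  dwR.attr("dim") = IntegerVector::create(k, k, ci, co);
  return List::create(_["dx"] = dx, _["dw"] = dwR,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling, floor semantics on trailing rows/cols.
// Returns list(y, argmax) where argmax holds 1-based linear indices into the
// input plane stack (h, w, c, n).
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int kernel, int stride) {
  IntegerVector xd = x.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const int ho = (h - kernel) / stride + 1, wo = (w - kernel) / stride + 1;
  if (ho < 1 || wo < 1) stop("pooling window larger than input");
  NumericVector y((size_t)ho * wo * c * n);
  IntegerVector arg((size_t)ho * wo * c * n);
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  arg.attr("dim") = IntegerVector::create(ho, wo, c, n);
  const double *xp = x.begin();
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const size_t base = (size_t)h * w * (ch + (size_t)c * s);
      const size_t obase = (size_t)ho * wo * (ch + (size_t)c * s);
      for (int j = 0; j < wo; ++j) {
        for (int i = 0; i < ho; ++i) {
          double best = -HUGE_VAL; size_t bestidx = 0;
          for (int kj = 0; kj < kernel; ++kj) {
            for (int ki = 0; ki < kernel; ++ki) {
              const int r = i * stride + ki, cc = j * stride + kj;
              const size_t li = base + r + (size_t)h * cc;
              if (xp[li] > best) { best = xp[li]; bestidx = li; }
            }
          }
          y[obase + i + (size_t)ho * j] = best;
          arg[obase + i + (size_t)ho * j] = (int)(bestidx + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector argmax, NumericVector dy,
                                   IntegerVector xdim) {
  size_t len = 1;
  for (int i = 0; i < xdim.size(); ++i) len *= (size_t)xdim[i];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}
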