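// Numerical kernels for the CNN engine and the lesion-wise metrics.
//
// Feature maps are R arrays with dim (H, W, C, N) in column-major order;
// convolution weights have dim (k, k, C_in, C_out).  "Same" padding follows
// the usual deep-learning convention: odd kernels pad (k-1)/2 on every side,
// even kernels pad only at the bottom/right.

#include <RcppArmadillo.h>
#include <array>
#include <functional>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int pad_offset(int k) { return -((k - 1) / 2); }

// Build the im2col matrix for one sample: (H*W) x (k*k*Cin).
// Column index = dy + k*dx + k*k*c, matching the R flattening of the
// (k, k, Cin, Cout) weight array.
static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& col) {
  const int off = pad_offset(k);
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int j = dy + k * dx + k * k * c;
        double* dst = col.colptr(j);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dx + off;
          if (sw < 0 || sw >= W) continue;
          const int h_lo = std::max(0, -(0 + off + dy));
          const int h_hi = std::min(H, H - (dy + off));
          const double* src = xc + (size_t)sw * H + (h_lo + dy + off);
          std::copy(src, src + (h_hi - h_lo), dst + (size_t)w * H + h_lo);
        }
      }
    }
  }
}

// Scatter-add a column matrix back into an image (adjoint of im2col).
static void col2im(const arma::mat& col, int H, int W, int C, int k,
                   double* x) {
  const int off = pad_offset(k);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int j = dy + k * dx + k * k * c;
        const double* src0 = col.colptr(j);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dx + off;
          if (sw < 0 || sw >= W) continue;
          const int h_lo = std::max(0, -(0 + off + dy));
          const int h_hi = std::min(H, H - (dy + off));
          double* dst = xc + (size_t)sw * H + (h_lo + dy + off);
          const double* src = src0 + (size_t)w * H + h_lo;
          for (int h = 0; h < h_hi - h_lo; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// act: 0 = linear, 1 = ReLU, 2 = sigmoid (applied in place on the output).
// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         bool use_bias, int act) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d_fwd: channel mismatch");
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat col;
  if (k > 1) col.set_size(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat ym(y.begin() + (size_t)n * H * W * Cout, H * W, Cout, false,
                 true);
    if (k == 1) {
      // 1x1 convolution is a plain channel-mixing GEMM; no im2col needed
      arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                   H * W, C, false, true);
      ym = xm * wm;
    } else {
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, col);
      ym = col * wm;
    }
    if (use_bias)
      for (int o = 0; o < Cout; ++o) ym.col(o) += b[o];
  }
  double* p = y.begin();
  const size_t ny = y.size();
  if (act == 1) {
    for (size_t i = 0; i < ny; ++i) if (p[i] < 0) p[i] = 0;
  } else if (act == 2) {
    for (size_t i = 0; i < ny; ++i) p[i] = 1.0 / (1.0 + std::exp(-p[i]));
  }
  return y;
}

// Backward pass; `out` is the forward activation output, used to fold the
// activation derivative into dy without extra R-side allocations.
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                NumericVector out, bool use_bias, int act) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  NumericVector dx((size_t)H * W * C * N), dw(w.size()), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat dwm(dw.begin(), k * k * C, Cout, false, true);
  arma::mat col, dcol;
  if (k > 1) { col.set_size(H * W, k * k * C); dcol.set_size(H * W, k * k * C); }
  arma::mat dz(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const size_t yoff = (size_t)n * H * W * Cout;
    const double* pdy = dy.begin() + yoff;
    const double* pout = out.begin() + yoff;
    double* pdz = dz.memptr();
    const size_t m = (size_t)H * W * Cout;
    if (act == 1) {
      for (size_t i = 0; i < m; ++i) pdz[i] = pout[i] > 0 ? pdy[i] : 0.0;
    } else if (act == 2) {
      for (size_t i = 0; i < m; ++i)
        pdz[i] = pdy[i] * pout[i] * (1.0 - pout[i]);
    } else {
      std::copy(pdy, pdy + m, pdz);
    }
    if (k == 1) {
      arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                   H * W, C, false, true);
      arma::mat dxm(dx.begin() + (size_t)n * H * W * C, H * W, C, false,
                    true);
      dwm += xm.t() * dz;
      dxm = dz * wm.t();
    } else {
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, col);
      dwm += col.t() * dz;
      dcol = dz * wm.t();
      col2im(dcol, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
    }
    if (use_bias)
      for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dz.col(o));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Channel-wise concatenation of feature maps and its adjoint split.
// [[Rcpp::export]]
NumericVector concat_fwd(List xs) {
  const int K = xs.size();
  std::vector<NumericVector> v;
  int Ctot = 0, H = 0, W = 0, N = 0;
  for (int j = 0; j < K; ++j) {
    NumericVector a(xs[j]);
    IntegerVector d = a.attr("dim");
    if (j == 0) { H = d[0]; W = d[1]; N = d[3]; }
    Ctot += d[2];
    v.push_back(a);
  }
  NumericVector y((size_t)H * W * Ctot * N);
  y.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    size_t at = 0;
    for (int j = 0; j < K; ++j) {
      IntegerVector d = v[j].attr("dim");
      const size_t blk = hw * d[2];
      std::copy(v[j].begin() + (size_t)n * blk,
                v[j].begin() + (size_t)(n + 1) * blk,
                y.begin() + (size_t)n * hw * Ctot + at);
      at += blk;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector concat_slice(NumericVector dy, int from, int count) {
  IntegerVector d = dy.attr("dim");
  const int H = d[0], W = d[1], Ctot = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector dx(hw * count * N);
  dx.attr("dim") = IntegerVector::create(H, W, count, N);
  for (int n = 0; n < N; ++n)
    std::copy(dy.begin() + (size_t)n * hw * Ctot + hw * from,
              dy.begin() + (size_t)n * hw * Ctot + hw * (from + count),
              dx.begin() + (size_t)n * hw * count);
  return dx;
}

// 2x2 max-pooling with stride 2; records argmax offsets for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  double* py = y.begin();
  int* pa = arg.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = px + s * H * W;
    double* ys = py + s * Ho * Wo;
    int* as = pa + s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho, w = 2 * wo;
        int best = h + H * w;
        double v = xs[best];
        const int cand[3] = {h + 1 + H * w, h + H * (w + 1),
                             h + 1 + H * (w + 1)};
        for (int i = 0; i < 3; ++i)
          if (xs[cand[i]] > v) { v = xs[cand[i]]; best = cand[i]; }
        ys[ho + Ho * wo] = v;
        as[ho + Ho * wo] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector arg,
                           IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double* pdx = dx.begin();
  const double* pdy = dy.begin();
  const int* pa = arg.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    double* dxs = pdx + s * H * W;
    const double* dys = pdy + s * Ho * Wo;
    const int* as = pa + s * Ho * Wo;
    for (int i = 0; i < Ho * Wo; ++i) dxs[as[i]] += dys[i];
  }
  return dx;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            Nullable<NumericVector> mean_, Nullable<NumericVector> var_,
            double eps) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mu(C), va(C);
  if (mean_.isNotNull()) {          // inference: moving statistics
    mu = NumericVector(mean_);
    va = NumericVector(var_);
  } else {                          // training: batch statistics
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + hw * (c + (size_t)C * n);
        for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double m = s / (hw * N);
      mu[c] = m;
      va[c] = std::max(s2 / (hw * N) - m * m, 0.0);
    }
  }
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(va[c] + eps);
    const double a = gamma[c] * is, b = beta[c] - gamma[c] * is * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double* q = y.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) q[i] = a * p[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
            NumericVector mu, NumericVector va, double eps) {
  IntegerVector xd = x.attr("dim");
  const size_t hw = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double m = (double)hw * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(va[c] + eps);
    double sd = 0, sdx = 0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + hw * (c + (size_t)C * n);
      const double* pd = dy.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        sd += pd[i];
        sdx += pd[i] * (px[i] - mu[c]) * is;
      }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double k = gamma[c] * is;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + hw * (c + (size_t)C * n);
      const double* pd = dy.begin() + hw * (c + (size_t)C * n);
      double* pq = dx.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (px[i] - mu[c]) * is;
        pq[i] = k * (pd[i] - sd / m - xh * sdx / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  const size_t planes = (size_t)xd[2] * xd[3];
  NumericVector y((size_t)4 * H * W * planes);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, xd[2], xd[3]);
  for (size_t s = 0; s < planes; ++s) {
    const double* xs = x.begin() + s * H * W;
    double* ys = y.begin() + s * 4 * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = xs[h + H * w];
        double* q = ys + 2 * h + 2 * H * (2 * w);
        q[0] = v; q[1] = v;
        q[2 * H] = v; q[2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int H = yd[0] / 2, W = yd[1] / 2;
  const size_t planes = (size_t)yd[2] * yd[3];
  NumericVector dx((size_t)H * W * planes);
  dx.attr("dim") = IntegerVector::create(H, W, yd[2], yd[3]);
  for (size_t s = 0; s < planes; ++s) {
    const double* ds = dy.begin() + s * 4 * H * W;
    double* xs = dx.begin() + s * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* q = ds + 2 * h + 2 * H * (2 * w);
        xs[h + H * w] = q[0] + q[1] + q[2 * H] + q[2 * H + 1];
      }
  }
  return dx;
}

// 3D connected components over a binary mask, configurable connectivity
// (6 = faces, 18 = faces+edges, 26 = faces+edges+corners).  Labels are
// renumbered by the scan-order position of each component's first voxel.
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<int> parent(n, -1);
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  // half-neighbourhood: offsets strictly "before" the voxel in scan order
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz > 0) continue;
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * (y + ny * z);
        if (!mask[i]) continue;
        parent[i] = i;
        for (auto& o : offs) {
          const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0) continue;
          const int j = xx + nx * (yy + ny * zz);
          if (parent[j] < 0) continue;
          const int ri = find(i), rj = find(j);
          if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
        }
      }
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::unordered_map<int, int> remap;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (parent[i] < 0) continue;
    const int r = find((int)i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
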