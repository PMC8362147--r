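#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// DSSIM: structural dissimilarity (1 - SSIM)/2 with an 11x11 Gaussian window
// (sigma 1.5), SSIM constants k1 = 0.01, k2 = 0.03 on data range 1, local
// statistics computed with periodic boundary so that the convolution is
// self-adjoint (exact analytic gradient).
// ---------------------------------------------------------------------------

static const int WIN_R = 5;
static const double SSIM_C1 = 1e-4;   // (0.01)^2
static const double SSIM_C2 = 9e-4;   // (0.03)^2

static arma::vec gauss_kernel() {
  arma::vec g(2 * WIN_R + 1);
  const double s2 = 2.0 * 1.5 * 1.5;
  for (int k = -WIN_R; k <= WIN_R; ++k) g[k + WIN_R] = std::exp(-k * k / s2);
  return g / arma::accu(g);
}

// separable periodic Gaussian filtering
static arma::mat gfilt(const arma::mat& x) {
  static arma::vec g = gauss_kernel();
  const int n = (int)x.n_rows, m = (int)x.n_cols;
  arma::mat tmp(n, m), out(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = -WIN_R; k <= WIN_R; ++k) {
        int ii = (i + k) % n;
        if (ii < 0) ii += n;
        acc += g[k + WIN_R] * x(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int k = -WIN_R; k <= WIN_R; ++k) {
        int jj = (j + k) % m;
        if (jj < 0) jj += m;
        acc += g[k + WIN_R] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

struct SsimParts {
  arma::mat mux, muy, l, cs, b1, b2;
  double mssim;
};

static SsimParts ssim_parts(const arma::mat& x, const arma::mat& y) {
  SsimParts p;
  p.mux = gfilt(x);
  p.muy = gfilt(y);
  arma::mat sx = gfilt(x % x) - p.mux % p.mux;
  arma::mat sy = gfilt(y % y) - p.muy % p.muy;
  arma::mat sxy = gfilt(x % y) - p.mux % p.muy;
  arma::mat a1 = 2.0 * p.mux % p.muy + SSIM_C1;
  arma::mat a2 = 2.0 * sxy + SSIM_C2;
  p.b1 = p.mux % p.mux + p.muy % p.muy + SSIM_C1;
  p.b2 = sx + sy + SSIM_C2;
  p.l = a1 / p.b1;
  p.cs = a2 / p.b2;
  p.mssim = arma::accu(p.l % p.cs) / (double)x.n_elem;
  return p;
}

//' @noRd
// [[Rcpp::export(name = ".dssim")]]
double dssim_cpp(const arma::mat& x, const arma::mat& y) {
  return 0.5 * (1.0 - ssim_parts(x, y).mssim);
}

// d(dssim)/dx given precomputed parts
static arma::mat dssim_grad_parts(const SsimParts& p, const arma::mat& x,
                                  const arma::mat& y) {
  const double n = (double)x.n_elem;
  arma::mat t0 = gfilt(2.0 * (p.muy - p.mux % p.l) % p.cs / p.b1);
  arma::mat f1 = gfilt(2.0 * p.l / p.b2);
  arma::mat g1 = gfilt(2.0 * p.l % p.muy / p.b2);
  arma::mat f2 = gfilt(2.0 * p.l % p.cs / p.b2);
  arma::mat g2 = gfilt(2.0 * p.l % p.cs % p.mux / p.b2);
  arma::mat dm = (t0 + y % f1 - g1 - x % f2 + g2) / n;
  return -0.5 * dm;
}

//' @noRd
// [[Rcpp::export(name = ".dssim_grad")]]
arma::mat dssim_grad_cpp(const arma::mat& x, const arma::mat& y) {
  SsimParts p = ssim_parts(x, y);
  return dssim_grad_parts(p, x, y);
}

// ---------------------------------------------------------------------------
// Small U-Net (3 resolution levels, 3x3 convolutions, leaky-ReLU, average
// pooling, nearest-neighbour upsampling, skip concatenation, residual
// output).  Weights are passed from R as a list of (W, b) pairs; W has one
// row per output channel and C_in*9 (or C_in for the 1x1 head) columns.
// ---------------------------------------------------------------------------

// transposed im2col: output is (h*w) x (c*9); column (ch*9 + (dw+1)*3 +
// (dh+1)) holds the zero-padded shift of channel ch, so each (j, dh, dw)
// run over i is a contiguous copy
static arma::mat im2col3(const arma::cube& a) {
  const int h = (int)a.n_rows, w = (int)a.n_cols, c = (int)a.n_slices;
  arma::mat out(h * w, c * 9, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const double* src = a.slice_memptr(ch);
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        double* dst = out.colptr(ch * 9 + (dw + 1) * 3 + (dh + 1));
        const int i0 = std::max(0, -dh), i1 = std::min(h, h - dh);
        for (int j = 0; j < w; ++j) {
          const int jj = j + dw;
          if (jj < 0 || jj >= w) continue;
          std::memcpy(dst + j * h + i0, src + jj * h + i0 + dh,
                      (i1 - i0) * sizeof(double));
        }
      }
  }
  return out;
}

// adjoint of im2col3: cols is (h*w) x (c*9)
static arma::cube col2im3(const arma::mat& cols, int h, int w, int c) {
  arma::cube out(h, w, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    double* dst = out.slice_memptr(ch);
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        const double* src = cols.colptr(ch * 9 + (dw + 1) * 3 + (dh + 1));
        const int i0 = std::max(0, -dh), i1 = std::min(h, h - dh);
        for (int j = 0; j < w; ++j) {
          const int jj = j + dw;
          if (jj < 0 || jj >= w) continue;
          const double* s = src + j * h + i0;
          double* d = dst + jj * h + i0 + dh;
          for (int i = 0; i < i1 - i0; ++i) d[i] += s[i];
        }
      }
  }
  return out;
}

// (h*w) x c matrix and h x w x c cube share the same memory layout
static arma::cube mat2cube(const arma::mat& m, int h, int w) {
  arma::cube out(h, w, m.n_cols);
  std::memcpy(out.memptr(), m.memptr(), m.n_elem * sizeof(double));
  return out;
}

static arma::mat cube2mat(const arma::cube& a) {
  arma::mat out(a.n_rows * a.n_cols, a.n_slices);
  std::memcpy(out.memptr(), a.memptr(), a.n_elem * sizeof(double));
  return out;
}

struct ConvW {
  arma::mat w;
  arma::vec b;
};

static std::vector<ConvW> unpack_weights(const List& weights) {
  std::vector<ConvW> out;
  for (int i = 0; i < weights.size(); ++i) {
    List li = weights[i];
    ConvW cw;
    cw.w = as<arma::mat>(li["W"]);
    cw.b = as<arma::vec>(li["b"]);
    out.push_back(cw);
  }
  return out;
}

static arma::cube conv3_fwd(const arma::cube& a, const ConvW& cw,
                            arma::mat& acol_store) {
  acol_store = im2col3(a);
  arma::mat y = acol_store * cw.w.t();    // (h*w) x c_out
  y.each_row() += cw.b.t();
  return mat2cube(y, a.n_rows, a.n_cols);
}

static arma::cube lrelu(const arma::cube& x, double s) {
  arma::cube y = x;
  y.transform([s](double v) { return v > 0 ? v : s * v; });
  return y;
}

static arma::cube lrelu_bwd(const arma::cube& dy, const arma::cube& ypost,
                            double s) {
  arma::cube dx = dy;
  for (arma::uword i = 0; i < dx.n_elem; ++i)
    if (ypost[i] <= 0) dx[i] *= s;
  return dx;
}

static arma::cube avgpool2(const arma::cube& x) {
  arma::cube y(x.n_rows / 2, x.n_cols / 2, x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c)
    for (arma::uword j = 0; j < y.n_cols; ++j)
      for (arma::uword i = 0; i < y.n_rows; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) +
                             x(2 * i + 1, 2 * j + 1, c));
  return y;
}

static arma::cube avgpool2_bwd(const arma::cube& dy, int h, int w) {
  arma::cube dx(h, w, dy.n_slices);
  for (arma::uword c = 0; c < dy.n_slices; ++c)
    for (arma::uword j = 0; j < dy.n_cols; ++j)
      for (arma::uword i = 0; i < dy.n_rows; ++i) {
        const double v = 0.25 * dy(i, j, c);
        dx(2 * i, 2 * j, c) = v;
        dx(2 * i + 1, 2 * j, c) = v;
        dx(2 * i, 2 * j + 1, c) = v;
        dx(2 * i + 1, 2 * j + 1, c) = v;
      }
  return dx;
}

static arma::cube upsample2(const arma::cube& x) {
  arma::cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c)
    for (arma::uword j = 0; j < x.n_cols; ++j)
      for (arma::uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

static arma::cube upsample2_bwd(const arma::cube& dy) {
  arma::cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (arma::uword c = 0; c < dx.n_slices; ++c)
    for (arma::uword j = 0; j < dx.n_cols; ++j)
      for (arma::uword i = 0; i < dx.n_rows; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

static arma::cube concat_ch(const arma::cube& a, const arma::cube& b) {
  arma::cube y(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  y.slices(0, a.n_slices - 1) = a;
  y.slices(a.n_slices, y.n_slices - 1) = b;
  return y;
}

struct Acts {
  // post-activation outputs and im2col caches for every conv layer
  std::vector<arma::cube> post;   // per conv, post-lrelu (or linear for head)
  std::vector<arma::mat> acol;
  arma::cube e1, e2, d2, c1, c2, p1, p2;
  arma::mat x, out;
};

// forward pass for one sample; fills acts when keep = true
static arma::mat unet_fwd_one(const arma::mat& x,
                              const std::vector<ConvW>& w, double slope,
                              Acts* acts) {
  const int h = (int)x.n_rows, wd = (int)x.n_cols;
  std::vector<arma::cube> post(11);
  std::vector<arma::mat> acol(11);
  arma::cube a0(h, wd, 1);
  a0.slice(0) = x;

  post[0] = lrelu(conv3_fwd(a0, w[0], acol[0]), slope);
  post[1] = lrelu(conv3_fwd(post[0], w[1], acol[1]), slope);
  arma::cube p1 = avgpool2(post[1]);
  post[2] = lrelu(conv3_fwd(p1, w[2], acol[2]), slope);
  post[3] = lrelu(conv3_fwd(post[2], w[3], acol[3]), slope);
  arma::cube p2 = avgpool2(post[3]);
  post[4] = lrelu(conv3_fwd(p2, w[4], acol[4]), slope);
  post[5] = lrelu(conv3_fwd(post[4], w[5], acol[5]), slope);
  arma::cube c2 = concat_ch(upsample2(post[5]), post[3]);
  post[6] = lrelu(conv3_fwd(c2, w[6], acol[6]), slope);
  post[7] = lrelu(conv3_fwd(post[6], w[7], acol[7]), slope);
  arma::cube c1 = concat_ch(upsample2(post[7]), post[1]);
  post[8] = lrelu(conv3_fwd(c1, w[8], acol[8]), slope);
  post[9] = lrelu(conv3_fwd(post[8], w[9], acol[9]), slope);
  // 1x1 head, linear
  acol[10] = cube2mat(post[9]);           // (h*w) x base
  arma::mat yhead = acol[10] * w[10].w.t();
  yhead.each_row() += w[10].b.t();
  arma::mat out = arma::reshape(yhead.col(0), h, wd) + x;

  if (acts) {
    acts->post = std::move(post);
    acts->acol = std::move(acol);
    acts->x = x;
    acts->out = out;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".unet_forward")]]
arma::cube unet_forward_cpp(const arma::cube& x, const List& weights,
                            double slope) {
  std::vector<ConvW> w = unpack_weights(weights);
  arma::cube out(x.n_rows, x.n_cols, x.n_slices);
  for (arma::uword n = 0; n < x.n_slices; ++n)
    out.slice(n) = unet_fwd_one(x.slice(n), w, slope, nullptr);
  return out;
}

// backward through one conv3 + lrelu given upstream grad on post-activation
static arma::cube conv3_bwd(const arma::cube& dpost, const arma::cube& post,
                            const arma::mat& acol, const ConvW& cw,
                            double slope, int cin, arma::mat& dw,
                            arma::vec& db) {
  arma::cube dpre = lrelu_bwd(dpost, post, slope);
  arma::mat dpre_m = cube2mat(dpre);      // (h*w) x c_out
  dw += dpre_m.t() * acol;
  db += arma::sum(dpre_m, 0).t();
  arma::mat dcol = dpre_m * cw.w;         // (h*w) x (cin*9)
  return col2im3(dcol, dpre.n_rows, dpre.n_cols, cin);
}

//' @noRd
// [[Rcpp::export(name = ".unet_loss_grad")]]
List unet_loss_grad_cpp(const arma::cube& x, const arma::cube& t,
                        const List& weights, double slope) {
  std::vector<ConvW> w = unpack_weights(weights);
  const int nlay = (int)w.size();
  const int nb = (int)x.n_slices;
  std::vector<arma::mat> dw(nlay);
  std::vector<arma::vec> db(nlay);
  for (int i = 0; i < nlay; ++i) {
    dw[i] = arma::mat(arma::size(w[i].w), arma::fill::zeros);
    db[i] = arma::vec(w[i].b.n_elem, arma::fill::zeros);
  }
  double loss = 0.0;
  const int base = (int)w[0].b.n_elem;   // base channel count

  for (int n = 0; n < nb; ++n) {
    Acts acts;
    arma::mat out = unet_fwd_one(x.slice(n), w, slope, &acts);
    SsimParts parts = ssim_parts(out, t.slice(n));
    loss += 0.5 * (1.0 - parts.mssim);
    arma::mat dout = dssim_grad_parts(parts, out, t.slice(n));

    // head (linear 1x1)
    arma::mat dhead(dout.n_elem, 1);
    dhead.col(0) = arma::vectorise(dout);
    dw[10] += dhead.t() * acts.acol[10];
    db[10] += arma::sum(dhead, 0).t();
    arma::mat dm = dhead * w[10].w;       // (h*w) x base
    arma::cube d9 = mat2cube(dm, out.n_rows, out.n_cols);

    arma::cube d8 = conv3_bwd(d9, acts.post[9], acts.acol[9], w[9], slope,
                              base, dw[9], db[9]);
    arma::cube dc1 = conv3_bwd(d8, acts.post[8], acts.acol[8], w[8], slope,
                               3 * base, dw[8], db[8]);
    // split c1 = [up(post7) | post1]
    arma::cube du1 = dc1.slices(0, 2 * base - 1);
    arma::cube dskip1 = dc1.slices(2 * base, 3 * base - 1);
    arma::cube d7 = upsample2_bwd(du1);
    arma::cube d6 = conv3_bwd(d7, acts.post[7], acts.acol[7], w[7], slope,
                              2 * base, dw[7], db[7]);
    arma::cube dc2 = conv3_bwd(d6, acts.post[6], acts.acol[6], w[6], slope,
                               6 * base, dw[6], db[6]);
    arma::cube du2 = dc2.slices(0, 4 * base - 1);
    arma::cube dskip2 = dc2.slices(4 * base, 6 * base - 1);
    arma::cube d5 = upsample2_bwd(du2);
    arma::cube d4 = conv3_bwd(d5, acts.post[5], acts.acol[5], w[5], slope,
                              4 * base, dw[5], db[5]);
    arma::cube dp2 = conv3_bwd(d4, acts.post[4], acts.acol[4], w[4], slope,
                               2 * base, dw[4], db[4]);
    arma::cube d3 = avgpool2_bwd(dp2, acts.post[3].n_rows,
                                 acts.post[3].n_cols) +
                    dskip2;
    arma::cube d2 = conv3_bwd(d3, acts.post[3], acts.acol[3], w[3], slope,
                              2 * base, dw[3], db[3]);
    arma::cube dp1 = conv3_bwd(d2, acts.post[2], acts.acol[2], w[2], slope,
                               base, dw[2], db[2]);
    arma::cube d1 = avgpool2_bwd(dp1, acts.post[1].n_rows,
                                 acts.post[1].n_cols) +
                    dskip1;
    arma::cube d0 = conv3_bwd(d1, acts.post[1], acts.acol[1], w[1], slope,
                              base, dw[1], db[1]);
    conv3_bwd(d0, acts.post[0], acts.acol[0], w[0], slope, 1, dw[0], db[0]);
  }

  List grads(nlay);
  for (int i = 0; i < nlay; ++i)
    grads[i] = List::create(_["W"] = dw[i] / nb, _["b"] = db[i] / nb);
  return List::create(_["loss"] = loss / nb, _["grads"] = grads);
}
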