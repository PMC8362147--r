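#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Bilinear sample of img at physical position (x, y).  img(ix, iy) sits at
// (x0 + ix*dx, y0 + iy*dx), 0-based.  Outside the grid the value is 0
// (mu of air).
static inline double sample_bilinear(const arma::mat& img, double x0,
                                     double y0, double dx, double x,
                                     double y) {
  const double fx = (x - x0) / dx;
  const double fy = (y - y0) / dx;
  const int ix = (int)std::floor(fx);
  const int iy = (int)std::floor(fy);
  const int nx = (int)img.n_rows;
  const int ny = (int)img.n_cols;
  if (ix < -1 || iy < -1 || ix > nx - 1 || iy > ny - 1) return 0.0;
  const double wx = fx - ix;
  const double wy = fy - iy;
  double v00 = 0.0, v10 = 0.0, v01 = 0.0, v11 = 0.0;
  if (ix >= 0 && iy >= 0) v00 = img(ix, iy);
  if (ix + 1 < nx && iy >= 0) v10 = img(ix + 1, iy);
  if (ix >= 0 && iy + 1 < ny) v01 = img(ix, iy + 1);
  if (ix + 1 < nx && iy + 1 < ny) v11 = img(ix + 1, iy + 1);
  return (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
         (1 - wx) * wy * v01 + wx * wy * v11;
}

//' @noRd
// [[Rcpp::export(name = ".fp_slice")]]
arma::mat fp_slice(const arma::mat& img, double x0, double y0, double dx,
                   const arma::vec& angles, const arma::vec& uoff, double rf,
                   double rfd, double step, double clip_r) {
  const int na = (int)angles.n_elem;
  const int nu = (int)uoff.n_elem;
  arma::mat out(na, nu, arma::fill::zeros);

  // bounding circle of the pixel grid (centre of grid, half diagonal);
  // clip_r > 0 intersects rays with a circle of that radius around the
  // isocentre instead (valid when the object is known to lie inside it)
  double cx = x0 + 0.5 * (img.n_rows - 1) * dx;
  double cy = y0 + 0.5 * (img.n_cols - 1) * dx;
  double rimg =
      0.5 * std::sqrt(2.0) * (double)std::max(img.n_rows, img.n_cols) * dx +
      dx;
  if (clip_r > 0 && clip_r < rimg +
          std::sqrt(cx * cx + cy * cy)) {
    cx = 0.0;
    cy = 0.0;
    rimg = clip_r;
  }

  for (int a = 0; a < na; ++a) {
    const double cb = std::cos(angles[a]);
    const double sb = std::sin(angles[a]);
    const double sx = rf * cb, sy = rf * sb;       // source
    const double dxv = -cb, dyv = -sb;             // toward isocentre
    const double ex = -sb, ey = cb;                // detector tangent
    for (int u = 0; u < nu; ++u) {
      // ray from source through detector element
      double rx = rfd * dxv + uoff[u] * ex;
      double ry = rfd * dyv + uoff[u] * ey;
      const double rn = std::sqrt(rx * rx + ry * ry);
      rx /= rn;
      ry /= rn;
      // clip against bounding circle: |S + t r - C|^2 = rimg^2
      const double ox = sx - cx, oy = sy - cy;
      const double b = ox * rx + oy * ry;
      const double c = ox * ox + oy * oy - rimg * rimg;
      const double disc = b * b - c;
      if (disc <= 0) continue;
      const double sq = std::sqrt(disc);
      double t0 = -b - sq, t1 = -b + sq;
      if (t1 <= 0) continue;
      if (t0 < 0) t0 = 0;
      const int nstep = (int)std::ceil((t1 - t0) / step);
      double acc = 0.0;
      for (int k = 0; k < nstep; ++k) {
        const double t = t0 + (k + 0.5) * step;
        if (t >= t1) break;
        acc += sample_bilinear(img, x0, y0, dx, sx + t * rx, sy + t * ry);
      }
      out(a, u) = acc * step;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".bp_slice")]]
arma::mat bp_slice(const arma::mat& q, const arma::vec& angles, double s0,
                   double ds, double rf, int nmat, double fov, int jlo,
                   int jhi) {
  // q: n_angles x n_s filtered projections on the virtual detector through
  // the isocentre (s_j = s0 + j*ds).  Backprojection restricted to channel
  // interval [jlo, jhi] (0-based, inclusive); pass 0, n_s-1 for all.
  const int na = (int)angles.n_elem;
  arma::mat img(nmat, nmat, arma::fill::zeros);
  const double px = fov / nmat;
  const double xorig = -0.5 * fov + 0.5 * px;
  const double dbeta = 2.0 * M_PI / na;

  std::vector<double> cb(na), sb(na);
  for (int a = 0; a < na; ++a) {
    cb[a] = std::cos(angles[a]);
    sb[a] = std::sin(angles[a]);
  }
  for (int iy = 0; iy < nmat; ++iy) {
    const double y = xorig + iy * px;
    for (int ix = 0; ix < nmat; ++ix) {
      const double x = xorig + ix * px;
      double acc = 0.0;
      for (int a = 0; a < na; ++a) {
        const double L = rf - x * cb[a] - y * sb[a];
        if (L < 1e-6) continue;
        const double s = rf * (-x * sb[a] + y * cb[a]) / L;
        const double f = (s - s0) / ds;
        const int j = (int)std::floor(f);
        if (j < jlo || j + 1 > jhi) continue;
        const double w = f - j;
        const double val = (1 - w) * q(a, j) + w * q(a, j + 1);
        acc += val * rf * rf / (L * L);
      }
      img(ix, iy) = acc * 0.5 * dbeta;
    }
  }
  return img;
}
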