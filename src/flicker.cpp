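#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur with reflective padding.  Kernel truncated at
// 4 sigma, renormalized.  Matrices are image rows (y) x cols (x).
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // blur along rows (y direction)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  // blur along columns (x direction)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= nc) cc = 2 * nc - cc - 1;
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// 4-point Lagrange (cubic, O(h^4)) interpolation weights at fractional t
// in [0,1] between nodes 1 and 2 of a 4-node stencil {0,1,2,3}.
static inline void lagrange4(double t, double w[4]) {
  // nodes at -1, 0, 1, 2 relative to floor point; evaluate at t
  w[0] = -t * (t - 1.0) * (t - 2.0) / 6.0;
  w[1] = (t + 1.0) * (t - 1.0) * (t - 2.0) / 2.0;
  w[2] = -(t + 1.0) * t * (t - 2.0) / 2.0;
  w[3] = (t + 1.0) * t * (t - 1.0) / 6.0;
}

// Sample field F (rows = y, cols = x, 0-based pixel centers at integer
// coordinates) at points (x, y) by separable 4-point Lagrange
// interpolation.  Points whose 4x4 stencil leaves the image return NA.
// [[Rcpp::export]]
NumericVector cpp_bicubic(const NumericMatrix& F, const NumericVector& x,
                          const NumericVector& y) {
  int n = x.size();
  int nr = F.nrow(), nc = F.ncol();
  NumericVector out(n);
  double wx[4], wy[4];
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
    if (x0 < 1 || y0 < 1 || x0 + 2 >= nc || y0 + 2 >= nr) {
      out[i] = NA_REAL;
      continue;
    }
    lagrange4(xi - x0, wx);
    lagrange4(yi - y0, wy);
    double acc = 0.0;
    for (int b = 0; b < 4; ++b) {
      double rowacc = 0.0;
      for (int a = 0; a < 4; ++a)
        rowacc += wx[a] * F(y0 - 1 + b, x0 - 1 + a);
      acc += wy[b] * rowacc;
    }
    out[i] = acc;
  }
  return out;
}

// Cast n_rays rays from (cx, cy); sample field at radii r0, r0+step, ...
// <= r1 by bicubic interpolation; return per-ray argmax radius, its value
// and an end-cap/NA flag.
// [[Rcpp::export]]
List cpp_trace_rays(const NumericMatrix& F, double cx, double cy,
                    int n_rays, double r0, double r1, double step) {
  int nsamp = (int)std::floor((r1 - r0) / step) + 1;
  NumericVector rad(n_rays), val(n_rays);
  LogicalVector flag(n_rays);
  std::vector<double> xs(nsamp), ys(nsamp);
  for (int k = 0; k < n_rays; ++k) {
    double phi = 2.0 * M_PI * k / n_rays;
    double cphi = std::cos(phi), sphi = std::sin(phi);
    for (int j = 0; j < nsamp; ++j) {
      double r = r0 + j * step;
      xs[j] = cx + r * cphi;
      ys[j] = cy + r * sphi;
    }
    NumericVector v =
        cpp_bicubic(F, NumericVector(xs.begin(), xs.end()),
                    NumericVector(ys.begin(), ys.end()));
    int best = -1;
    double bv = -INFINITY;
    bool anyna = false;
    for (int j = 0; j < nsamp; ++j) {
      if (NumericVector::is_na(v[j])) { anyna = true; continue; }
      if (v[j] > bv) { bv = v[j]; best = j; }
    }
    if (best < 0) {
      rad[k] = NA_REAL; val[k] = NA_REAL; flag[k] = true;
    } else {
      rad[k] = r0 + best * step;
      val[k] = bv;
      flag[k] = (best == 0 || best == nsamp - 1 || anyna);
    }
  }
  return List::create(_["radius"] = rad, _["value"] = val, _["flag"] = flag);
}

// Periodic linear interpolation of radii given at (sorted) angles `a`
// onto target angles `phi`; both in [0, 2pi).
static void interp_periodic(const std::vector<double>& a,
                            const std::vector<double>& r,
                            const std::vector<double>& phi,
                            std::vector<double>& out) {
  int n = a.size();
  int m = phi.size();
  const double TWO_PI = 2.0 * M_PI;
  for (int j = 0; j < m; ++j) {
    double p = phi[j];
    // find first angle >= p
    int hi = (int)(std::lower_bound(a.begin(), a.end(), p) - a.begin());
    int lo = hi - 1;
    double alo, ahi, rlo, rhi;
    if (hi == 0) { lo = n - 1; alo = a[lo] - TWO_PI; ahi = a[0]; }
    else if (hi == n) { hi = 0; alo = a[lo]; ahi = a[0] + TWO_PI; }
    else { alo = a[lo]; ahi = a[hi]; }
    rlo = r[lo]; rhi = r[hi];
    double t = (ahi > alo) ? (p - alo) / (ahi - alo) : 0.0;
    out[j] = rlo + t * (rhi - rlo);
  }
}

// Exact geometric recentering of contours sampled at uniform angles.
// radii: n_angles x n_contours.  Iteratively estimates the center offset
// from the first Fourier component, shifts the center, and re-samples the
// boundary points at uniform angles about the new center.  Returns the
// recentered radii and accumulated (dx, dy) shifts.
// [[Rcpp::export]]
List cpp_recenter(const NumericMatrix& radii, int max_iter, double tol) {
  int n = radii.nrow(), m = radii.ncol();
  const double TWO_PI = 2.0 * M_PI;
  NumericMatrix out(n, m);
  NumericMatrix shift(2, m);
  std::vector<double> phi(n), cphi(n), sphi(n);
  for (int j = 0; j < n; ++j) {
    phi[j] = TWO_PI * j / n;
    cphi[j] = std::cos(phi[j]);
    sphi[j] = std::sin(phi[j]);
  }
  std::vector<double> r(n), px(n), py(n), ang(n), rho(n), rnew(n);
  std::vector<int> ord(n);
  for (int c = 0; c < m; ++c) {
    for (int j = 0; j < n; ++j) r[j] = radii(j, c);
    double ox = 0.0, oy = 0.0;
    for (int it = 0; it < max_iter; ++it) {
      double dx = 0.0, dy = 0.0, rbar = 0.0;
      for (int j = 0; j < n; ++j) {
        dx += r[j] * cphi[j];
        dy += r[j] * sphi[j];
        rbar += r[j];
      }
      dx *= 2.0 / n; dy *= 2.0 / n; rbar /= n;
      if (std::sqrt(dx * dx + dy * dy) < tol * rbar) break;
      // boundary points in old frame, re-expressed about shifted center
      for (int j = 0; j < n; ++j) {
        px[j] = r[j] * cphi[j] - dx;
        py[j] = r[j] * sphi[j] - dy;
        rho[j] = std::sqrt(px[j] * px[j] + py[j] * py[j]);
        ang[j] = std::atan2(py[j], px[j]);
        if (ang[j] < 0) ang[j] += TWO_PI;
        ord[j] = j;
      }
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return ang[a] < ang[b]; });
      std::vector<double> as(n), rs(n);
      for (int j = 0; j < n; ++j) { as[j] = ang[ord[j]]; rs[j] = rho[ord[j]]; }
      interp_periodic(as, rs, phi, rnew);
      r = rnew;
      ox += dx; oy += dy;
    }
    for (int j = 0; j < n; ++j) out(j, c) = r[j];
    shift(0, c) = ox; shift(1, c) = oy;
  }
  return List::create(_["radii"] = out, _["shift"] = shift);
}

// Render the tanh interface profile: I = bg + A*(0.5 - 0.5*tanh((d - r(phi))/zeta))
// over an nr x nc frame with center (cx, cy) and contour radii at uniform
// angles.  Used by the synthetic generator; noise/quantization applied in R.
// [[Rcpp::export]]
NumericMatrix cpp_render_tanh(int nr, int nc, double cx, double cy,
                              const NumericVector& contour, double zeta,
                              double amplitude, double background) {
  int nang = contour.size();
  const double TWO_PI = 2.0 * M_PI;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int rI = 0; rI < nr; ++rI) {
      double dx = c - cx, dy = rI - cy;
      double d = std::sqrt(dx * dx + dy * dy);
      double phi = std::atan2(dy, dx);
      if (phi < 0) phi += TWO_PI;
      // periodic linear interpolation of the contour radius at phi
      double u = phi / TWO_PI * nang;
      int i0 = (int)std::floor(u) % nang;
      int i1 = (i0 + 1) % nang;
      double t = u - std::floor(u);
      double rb = contour[i0] + t * (contour[i1] - contour[i0]);
      out(rI, c) =
          background + amplitude * (0.5 - 0.5 * std::tanh((d - rb) / zeta));
    }
  }
  return out;
}

// 4-connected flood fill from (x0, y0) over pixels >= thresh.
// Returns a logical mask.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_fill(const NumericMatrix& img, int x0, int y0,
                             double thresh) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix mask(nr, nc);
  if (x0 < 0 || y0 < 0 || x0 >= nc || y0 >= nr) return mask;
  if (img(y0, x0) < thresh) return mask;
  std::vector<std::pair<int, int>> stack;
  stack.emplace_back(x0, y0);
  mask(y0, x0) = true;
  const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
  while (!stack.empty()) {
    auto [x, y] = stack.back();
    stack.pop_back();
    for (int k = 0; k < 4; ++k) {
      int xx = x + dx[k], yy = y + dy[k];
      if (xx < 0 || yy < 0 || xx >= nc || yy >= nr) continue;
      if (mask(yy, xx)) continue;
      if (img(yy, xx) >= thresh) {
        mask(yy, xx) = true;
        stack.emplace_back(xx, yy);
      }
    }
  }
  return mask;
}
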