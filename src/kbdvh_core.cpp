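#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double KB_INF = std::numeric_limits<double>::infinity();

// "infinite" squared distance sentinel: large but finite so the parabola
// envelope arithmetic stays well defined; anything above KB_BIG/2 in the
// result means "no source voxel"
static const double KB_BIG = 1e20;

// ---------------------------------------------------------------------------
// 1-D squared Euclidean distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2012), samples at positions i*h.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -KB_INF;
  z[1] = KB_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    if (s <= z[k]) { // k == 0: q's parabola dominates everywhere
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = KB_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double x = q * h;
    while (z[k + 1] < x) ++k;
    double xv = v[k] * h;
    d[q] = (x - xv) * (x - xv) + f[v[k]];
  }
}

// Euclidean distance (cm) from each voxel centre to the nearest TRUE voxel
// centre, with anisotropic spacing. Returns Inf everywhere if mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : KB_BIG;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // transform along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * nx * ny] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] > KB_BIG / 2) ? KB_INF : std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur of a 3-D array; sigma given in voxels per axis.
// Kernels are truncated at 4 sigma and renormalised at the array edges.
// ---------------------------------------------------------------------------
static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  for (int t = -r; t <= r; ++t)
    kern[t + r] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)nx
                                                  : (R_xlen_t)nx * ny;
  std::vector<double> line(n), res(n);
  int n1 = (axis == 0) ? ny : nx;
  int n2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a1 = 0; a1 < n1; ++a1) {
      R_xlen_t base;
      if (axis == 0)
        base = (R_xlen_t)b * nx * ny + (R_xlen_t)a1 * nx;
      else if (axis == 1)
        base = (R_xlen_t)b * nx * ny + a1;
      else
        base = (R_xlen_t)b * nx + a1;
      for (int q = 0; q < n; ++q) line[q] = a[base + q * stride];
      for (int q = 0; q < n; ++q) {
        double s = 0.0, w = 0.0;
        int lo = std::max(-r, -q), hi = std::min(r, n - 1 - q);
        for (int t = lo; t <= hi; ++t) {
          s += kern[t + r] * line[q + t];
          w += kern[t + r];
        }
        res[q] = s / w;
      }
      for (int q = 0; q < n; ++q) a[base + q * stride] = res[q];
    }
}

// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector arr, IntegerVector dim,
                         NumericVector sigmaVox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(arr.begin(), arr.end());
  blur_axis(a, nx, ny, nz, 0, sigmaVox[0]);
  blur_axis(a, nx, ny, nz, 1, sigmaVox[1]);
  blur_axis(a, nx, ny, nz, 2, sigmaVox[2]);
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Uniform-intensity conformal field dose.
//
// Parallel beam in the axial plane with gantry angle theta (deg): the beam
// travels along d = (sin theta, cos theta, 0). The aperture is the
// beam's-eye-view projection of the fit target, represented per axial slice
// as a lateral interval [umin(z), umax(z)] in the rotated lateral coordinate
// u = x cos(theta) - y sin(theta) (a per-slice conformal jaw/leaf-pair
// fitting). The interval is expanded by marginCm and edge-softened with a
// Gaussian penumbra: transmission T = Phi((margin - s)/sigma) where s is the
// signed distance to the raw projection (negative inside). Depth from the
// body surface is an exact 2-D voxel traversal (Amanatides & Woo) along the
// ray towards the source, and dose = T * exp(-mu * depth), zero outside the
// body. The returned grid is unnormalised; the caller rescales.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_field_dose(LogicalVector body, LogicalVector target,
                             IntegerVector dim, NumericVector spacing,
                             double angleDeg, double marginCm,
                             double sigmaCm, double muPerCm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n); // zero-initialised

  const double th = angleDeg * M_PI / 180.0;
  const double cth = std::cos(th), sth = std::sin(th);
  // direction towards the source (opposite to beam travel)
  const double mx = -sth, my = -cth;
  const double hf = 0.5 * (std::fabs(cth) * sx + std::fabs(sth) * sy);

  // per-slice lateral extent of the projected target
  std::vector<double> umin(nz, KB_INF), umax(nz, -KB_INF);
  std::vector<bool> occ(nz, false);
  for (int k = 0; k < nz; ++k) {
    R_xlen_t base = (R_xlen_t)k * nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!target[base + (R_xlen_t)j * nx + i]) continue;
        double x = (i + 0.5) * sx, y = (j + 0.5) * sy;
        double u = x * cth - y * sth;
        if (u - hf < umin[k]) umin[k] = u - hf;
        if (u + hf > umax[k]) umax[k] = u + hf;
        occ[k] = true;
      }
  }
  bool any_occ = false;
  for (int k = 0; k < nz; ++k) any_occ = any_occ || occ[k];
  if (!any_occ) stop("fit target projects to an empty aperture");

  const int stepi = (mx > 0) ? 1 : (mx < 0 ? -1 : 0);
  const int stepj = (my > 0) ? 1 : (my < 0 ? -1 : 0);

  for (int k = 0; k < nz; ++k) {
    R_xlen_t base = (R_xlen_t)k * nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = base + (R_xlen_t)j * nx + i;
        if (!body[idx]) continue;
        double x = (i + 0.5) * sx, y = (j + 0.5) * sy;
        double u = x * cth - y * sth;

        // signed distance s to the projected target (slice-centre model)
        double s;
        bool inside = occ[k] && u >= umin[k] && u <= umax[k];
        if (!inside) {
          double best = KB_INF;
          for (int o = 0; o < nz; ++o) {
            double dz = o * sz;
            if (dz >= best) break;
            bool found = false;
            for (int pm = 0; pm < 2; ++pm) {
              int kk = (pm == 0) ? k - o : k + o;
              if (pm == 1 && o == 0) continue;
              if (kk < 0 || kk >= nz || !occ[kk]) continue;
              found = true;
              double duo = 0.0;
              if (u < umin[kk]) duo = umin[kk] - u;
              else if (u > umax[kk]) duo = u - umax[kk];
              double dd = std::sqrt(dz * dz + duo * duo);
              if (dd < best) best = dd;
            }
            (void)found;
          }
          s = best;
        } else {
          double best = KB_INF;
          for (int o = 0; ; ++o) {
            double dz = o * sz;
            if (dz >= best) break;
            for (int pm = 0; pm < 2; ++pm) {
              int kk = (pm == 0) ? k - o : k + o;
              if (pm == 1 && o == 0) continue;
              double dd;
              if (kk < 0 || kk >= nz || !occ[kk]) {
                dd = dz; // empty slice: complement directly above/below
              } else {
                double off = 0.0;
                if (u >= umin[kk] && u <= umax[kk])
                  off = std::min(u - umin[kk], umax[kk] - u);
                dd = std::sqrt(dz * dz + off * off);
              }
              if (dd < best) best = dd;
            }
          }
          s = -best;
        }
        double T = R::pnorm((marginCm - s) / sigmaCm, 0.0, 1.0, 1, 0);
        if (T < 1e-12) continue;

        // depth: in-body path length from grid entry to the voxel centre
        double depth = 0.0;
        if (stepi == 0 && stepj == 0) {
          depth = 0.0;
        } else {
          int ci = i, cj = j;
          double t = 0.0;
          double tMaxX = KB_INF, tMaxY = KB_INF, tDX = KB_INF, tDY = KB_INF;
          if (stepi != 0) {
            double edge = (stepi > 0) ? (ci + 1) * sx : ci * sx;
            tMaxX = (edge - x) / mx;
            tDX = sx / std::fabs(mx);
          }
          if (stepj != 0) {
            double edge = (stepj > 0) ? (cj + 1) * sy : cj * sy;
            tMaxY = (edge - y) / my;
            tDY = sy / std::fabs(my);
          }
          while (ci >= 0 && ci < nx && cj >= 0 && cj < ny) {
            double tNext = std::min(tMaxX, tMaxY);
            if (body[base + (R_xlen_t)cj * nx + ci]) depth += tNext - t;
            t = tNext;
            if (tMaxX <= tMaxY) {
              ci += stepi;
              tMaxX += tDX;
            } else {
              cj += stepj;
              tMaxY += tDY;
            }
          }
        }
        out[idx] = T * std::exp(-muPerCm * depth);
      }
  }
  return out;
}
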