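#include <Rcpp.h>
using namespace Rcpp;

struct Geom {
  int d[3];
  double sp[3], org[3];
};

static Geom read_geom(IntegerVector dims, NumericVector spacing, NumericVector origin) {
  Geom g;
  for (int a = 0; a < 3; ++a) {
    g.d[a] = dims[a];
    g.sp[a] = spacing[a];
    g.org[a] = origin[a];
  }
  return g;
}

// Trilinear interpolation at one continuous index position (ix, iy, iz).
// Returns false when the position lies outside [0, d-1] on any axis.
static inline bool tri_interp(const double *v, const Geom &g, double ix, double iy,
                              double iz, double &val, double *grad) {
  if (ix < 0 || iy < 0 || iz < 0 || ix > g.d[0] - 1 || iy > g.d[1] - 1 ||
      iz > g.d[2] - 1)
    return false;
  int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy), z0 = (int)std::floor(iz);
  if (x0 == g.d[0] - 1) x0--;
  if (y0 == g.d[1] - 1) y0--;
  if (z0 == g.d[2] - 1) z0--;
  // degenerate single-voxel axes
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = ix - x0, fy = iy - y0, fz = iz - z0;
  long nx = g.d[0], nxy = (long)g.d[0] * g.d[1];
  long base = x0 + (long)y0 * nx + (long)z0 * nxy;
  int sx = (g.d[0] > 1) ? 1 : 0;
  long sy = (g.d[1] > 1) ? nx : 0;
  long sz = (g.d[2] > 1) ? nxy : 0;
  double c000 = v[base], c100 = v[base + sx];
  double c010 = v[base + sy], c110 = v[base + sx + sy];
  double c001 = v[base + sz], c101 = v[base + sx + sz];
  double c011 = v[base + sy + sz], c111 = v[base + sx + sy + sz];
  double c00 = c000 + fx * (c100 - c000);
  double c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001);
  double c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  val = c0 + fz * (c1 - c0);
  if (grad) {
    // d/dindex, converted to d/dmm by the caller
    double gx0 = (c100 - c000) + fy * ((c110 - c010) - (c100 - c000));
    double gx1 = (c101 - c001) + fy * ((c111 - c011) - (c101 - c001));
    grad[0] = gx0 + fz * (gx1 - gx0);
    double gy0 = (c10 - c00), gy1 = (c11 - c01);
    grad[1] = gy0 + fz * (gy1 - gy0);
    grad[2] = c1 - c0;
  }
  return true;
}

// Trilinear sampling of a volume at physical points (mm).
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dims, NumericVector spacing,
                   NumericVector origin, NumericMatrix pts, double fill,
                   bool want_grad) {
  Geom g = read_geom(dims, spacing, origin);
  int np = pts.nrow();
  NumericVector values(np);
  LogicalVector inside(np);
  NumericMatrix grad(want_grad ? np : 1, 3);
  const double *v = vol.begin();
  double gtmp[3];
  for (int k = 0; k < np; ++k) {
    double ix = (pts(k, 0) - g.org[0]) / g.sp[0];
    double iy = (pts(k, 1) - g.org[1]) / g.sp[1];
    double iz = (pts(k, 2) - g.org[2]) / g.sp[2];
    double val;
    bool ok = tri_interp(v, g, ix, iy, iz, val, want_grad ? gtmp : (double *)0);
    inside[k] = ok;
    values[k] = ok ? val : fill;
    if (want_grad) {
      if (ok) {
        grad(k, 0) = gtmp[0] / g.sp[0];
        grad(k, 1) = gtmp[1] / g.sp[1];
        grad(k, 2) = gtmp[2] / g.sp[2];
      } else {
        grad(k, 0) = grad(k, 1) = grad(k, 2) = 0.0;
      }
    }
  }
  return List::create(_["values"] = values, _["inside"] = inside,
                      _["gradient"] = grad);
}

// Resample a moving volume onto a reference grid under the composite map
// T(p) = A p + b + D(p), where D is an optional B-spline displacement field.
// The B-spline part mirrors cpp_bspline_eval (points outside the lattice
// support contribute zero displacement).
static inline double bsp_w(double t) {
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  double u = 2.0 - a;
  return u * u * u / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector mvol, IntegerVector mdims,
                           NumericVector mspacing, NumericVector morigin,
                           IntegerVector rdims, NumericVector rspacing,
                           NumericVector rorigin, NumericMatrix A, NumericVector b,
                           bool use_bspline, NumericVector coef,
                           NumericVector grid_origin, NumericVector grid_spacing,
                           IntegerVector grid_size, double fill) {
  Geom gm = read_geom(mdims, mspacing, morigin);
  Geom gr = read_geom(rdims, rspacing, rorigin);
  long nout = (long)gr.d[0] * gr.d[1] * gr.d[2];
  NumericVector out(nout);
  out.attr("dim") = IntegerVector::create(gr.d[0], gr.d[1], gr.d[2]);
  const double *mv = mvol.begin();
  const double *cf = use_bspline ? coef.begin() : (double *)0;
  int n1 = 0, n2 = 0, n3 = 0;
  long planesz = 0, volsz = 0;
  double gorg[3], gsp[3];
  if (use_bspline) {
    n1 = grid_size[0]; n2 = grid_size[1]; n3 = grid_size[2];
    planesz = (long)n1 * n2;
    volsz = planesz * n3;
    for (int a = 0; a < 3; ++a) {
      gorg[a] = grid_origin[a];
      gsp[a] = grid_spacing[a];
    }
  }
  long idx = 0;
  for (int kz = 0; kz < gr.d[2]; ++kz) {
    double pz = gr.org[2] + kz * gr.sp[2];
    for (int ky = 0; ky < gr.d[1]; ++ky) {
      double py = gr.org[1] + ky * gr.sp[1];
      for (int kx = 0; kx < gr.d[0]; ++kx, ++idx) {
        double px = gr.org[0] + kx * gr.sp[0];
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        if (use_bspline) {
          double u[3] = {(px - gorg[0]) / gsp[0], (py - gorg[1]) / gsp[1],
                         (pz - gorg[2]) / gsp[2]};
          int base[3];
          bool ins = true;
          int nn[3] = {n1, n2, n3};
          for (int a = 0; a < 3; ++a) {
            base[a] = (int)std::floor(u[a]);
            if (base[a] - 1 < 0 || base[a] + 2 > nn[a] - 1) {
              if (base[a] + 2 == nn[a] && u[a] == (double)base[a]) base[a] -= 1;
              else ins = false;
            }
          }
          if (ins) {
            double wx[4], wy[4], wz[4];
            for (int i = 0; i < 4; ++i) {
              wx[i] = bsp_w(u[0] - (base[0] - 1 + i));
              wy[i] = bsp_w(u[1] - (base[1] - 1 + i));
              wz[i] = bsp_w(u[2] - (base[2] - 1 + i));
            }
            double acc[3] = {0, 0, 0};
            for (int az = 0; az < 4; ++az) {
              long offz = (long)(base[2] - 1 + az) * planesz;
              for (int ay = 0; ay < 4; ++ay) {
                double wyz = wy[ay] * wz[az];
                long off = (long)(base[1] - 1 + ay) * n1 + offz;
                for (int ax = 0; ax < 4; ++ax) {
                  double w = wx[ax] * wyz;
                  long ci = (base[0] - 1 + ax) + off;
                  acc[0] += w * cf[ci];
                  acc[1] += w * cf[ci + volsz];
                  acc[2] += w * cf[ci + 2 * volsz];
                }
              }
            }
            qx += acc[0];
            qy += acc[1];
            qz += acc[2];
          }
        }
        double ix = (qx - gm.org[0]) / gm.sp[0];
        double iy = (qy - gm.org[1]) / gm.sp[1];
        double iz = (qz - gm.org[2]) / gm.sp[2];
        double val;
        if (tri_interp(mv, gm, ix, iy, iz, val, (double *)0))
          out[idx] = val;
        else
          out[idx] = fill;
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing; sigma per axis in voxels, kernel truncated at
// 3 sigma, boundary handled by edge replication so constants are preserved.
static void smooth_axis(std::vector<double> &src, std::vector<double> &dst,
                        const int d[3], int axis, double sigma) {
  if (sigma <= 0) {
    dst = src;
    return;
  }
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= s;
  long nx = d[0], ny = d[1], nz = d[2];
  long stride = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
  long len = d[axis];
  // iterate over all lines along `axis`
  for (long z = 0; z < (axis == 2 ? 1 : nz); ++z) {
    for (long y = 0; y < (axis == 1 ? 1 : ny); ++y) {
      for (long x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        long start = x + y * nx + z * nx * ny;
        for (long i = 0; i < len; ++i) {
          double acc = 0;
          for (int j = -r; j <= r; ++j) {
            long ii = i + j;
            if (ii < 0) ii = 0;
            if (ii >= len) ii = len - 1;
            acc += k[j + r] * src[start + ii * stride];
          }
          dst[start + i * stride] = acc;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dims,
                               NumericVector sigma) {
  int d[3] = {dims[0], dims[1], dims[2]};
  long n = (long)d[0] * d[1] * d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  smooth_axis(a, b, d, 0, sigma[0]);
  smooth_axis(b, a, d, 1, sigma[1]);
  smooth_axis(a, b, d, 2, sigma[2]);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = IntegerVector::create(d[0], d[1], d[2]);
  return out;
}

// 6-connected 3D component labelling (two-pass union-find).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<int> parent(1, 0);
  int next = 0;
  auto find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  long nxy = (long)nx * ny;
  for (long z = 0; z < nz; ++z)
    for (long y = 0; y < ny; ++y)
      for (long x = 0; x < nx; ++x) {
        long i = x + y * nx + z * nxy;
        if (!mask[i]) continue;
        int lx = (x > 0 && mask[i - 1]) ? lab[i - 1] : 0;
        int ly = (y > 0 && mask[i - nx]) ? lab[i - nx] : 0;
        int lz = (z > 0 && mask[i - nxy]) ? lab[i - nxy] : 0;
        int m = 0;
        if (lx) m = lx;
        if (ly) m = m ? std::min(m, ly) : ly;
        if (lz) m = m ? std::min(m, lz) : lz;
        if (!m) {
          ++next;
          parent.push_back(next);
          lab[i] = next;
        } else {
          lab[i] = m;
          if (lx && lx != m) unite(lx, m);
          if (ly && ly != m) unite(ly, m);
          if (lz && lz != m) unite(lz, m);
        }
      }
  // relabel to consecutive ids
  std::vector<int> remap(next + 1, 0);
  int cnt = 0;
  for (int i = 1; i <= next; ++i) {
    int r = find(i);
    if (!remap[r]) remap[r] = ++cnt;
  }
  IntegerVector out(n);
  for (long i = 0; i < n; ++i) out[i] = lab[i] ? remap[find(lab[i])] : 0;
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
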