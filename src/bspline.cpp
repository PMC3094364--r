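#include <Rcpp.h>
using namespace Rcpp;

// Cubic B-spline kernel and derivative on [-2, 2].
static inline double b3(double t) {
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  double u = 2.0 - a;
  return u * u * u / 6.0;
}

static inline double db3(double t) {
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  double s = (t < 0.0) ? -1.0 : 1.0;
  if (a < 1.0) return s * (-2.0 * a + 1.5 * a * a);
  double u = 2.0 - a;
  return s * (-0.5 * u * u);
}

// [[Rcpp::export]]
NumericVector cpp_b3_kernel(NumericVector t) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = b3(t[i]);
  return out;
}

struct Grid {
  double org[3], sp[3];
  int n[3];
};

static Grid read_grid(NumericVector grid_origin, NumericVector grid_spacing,
                      IntegerVector grid_size) {
  Grid g;
  for (int a = 0; a < 3; ++a) {
    g.org[a] = grid_origin[a];
    g.sp[a] = grid_spacing[a];
    g.n[a] = grid_size[a];
  }
  return g;
}

// Displacement of a tensor-product cubic B-spline lattice at physical points.
// coef has dim (n1, n2, n3, 3), in mm.  Points outside the support of the
// lattice raise an error unless zero_outside is TRUE.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_eval(NumericVector coef, NumericVector grid_origin,
                               NumericVector grid_spacing, IntegerVector grid_size,
                               NumericMatrix pts, bool zero_outside) {
  Grid g = read_grid(grid_origin, grid_spacing, grid_size);
  int np = pts.nrow();
  NumericMatrix out(np, 3);
  const double *cf = coef.begin();
  int n1 = g.n[0], n2 = g.n[1], n3 = g.n[2];
  long planesz = (long)n1 * n2;
  long volsz = planesz * n3;

  for (int k = 0; k < np; ++k) {
    double u[3];
    int base[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      u[a] = (pts(k, a) - g.org[a]) / g.sp[a];
      base[a] = (int)std::floor(u[a]);
      if (base[a] - 1 < 0 || base[a] + 2 > g.n[a] - 1) {
        // allow the exact upper boundary where floor(u) == u
        if (base[a] + 2 == g.n[a] && u[a] == (double)base[a]) {
          base[a] -= 1;
        } else {
          inside = false;
        }
      }
    }
    if (!inside) {
      if (zero_outside) continue;
      stop("point %d (%.3f, %.3f, %.3f) is outside the B-spline grid support",
           k + 1, pts(k, 0), pts(k, 1), pts(k, 2));
    }
    double wx[4], wy[4], wz[4];
    for (int i = 0; i < 4; ++i) {
      wx[i] = b3(u[0] - (base[0] - 1 + i));
      wy[i] = b3(u[1] - (base[1] - 1 + i));
      wz[i] = b3(u[2] - (base[2] - 1 + i));
    }
    double acc[3] = {0.0, 0.0, 0.0};
    for (int kz = 0; kz < 4; ++kz) {
      int iz = base[2] - 1 + kz;
      for (int ky = 0; ky < 4; ++ky) {
        int iy = base[1] - 1 + ky;
        double wyz = wy[ky] * wz[kz];
        long off = (long)iy * n1 + (long)iz * planesz;
        for (int kx = 0; kx < 4; ++kx) {
          int ix = base[0] - 1 + kx;
          double w = wx[kx] * wyz;
          long idx = ix + off;
          acc[0] += w * cf[idx];
          acc[1] += w * cf[idx + volsz];
          acc[2] += w * cf[idx + 2 * volsz];
        }
      }
    }
    out(k, 0) = acc[0];
    out(k, 1) = acc[1];
    out(k, 2) = acc[2];
  }
  return out;
}

// Accumulate d(cost)/d(coefficients): for each sample point the gradient with
// respect to the displacement vector (point_grad, n x 3) is scattered onto the
// 4x4x4 neighbourhood of control points with tensor-product basis weights.
// Returns an array with dim (n1, n2, n3, 3).
// [[Rcpp::export]]
NumericVector cpp_bspline_scatter(NumericVector grid_origin, NumericVector grid_spacing,
                                  IntegerVector grid_size, NumericMatrix pts,
                                  NumericMatrix point_grad) {
  Grid g = read_grid(grid_origin, grid_spacing, grid_size);
  int np = pts.nrow();
  int n1 = g.n[0], n2 = g.n[1], n3 = g.n[2];
  long planesz = (long)n1 * n2;
  long volsz = planesz * n3;
  NumericVector out(volsz * 3);
  out.attr("dim") = IntegerVector::create(n1, n2, n3, 3);
  double *gr = out.begin();

  for (int k = 0; k < np; ++k) {
    double u[3];
    int base[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      u[a] = (pts(k, a) - g.org[a]) / g.sp[a];
      base[a] = (int)std::floor(u[a]);
      if (base[a] - 1 < 0 || base[a] + 2 > g.n[a] - 1) {
        if (base[a] + 2 == g.n[a] && u[a] == (double)base[a]) base[a] -= 1;
        else inside = false;
      }
    }
    if (!inside) continue;
    double wx[4], wy[4], wz[4];
    for (int i = 0; i < 4; ++i) {
      wx[i] = b3(u[0] - (base[0] - 1 + i));
      wy[i] = b3(u[1] - (base[1] - 1 + i));
      wz[i] = b3(u[2] - (base[2] - 1 + i));
    }
    double g0 = point_grad(k, 0), g1 = point_grad(k, 1), g2 = point_grad(k, 2);
    for (int kz = 0; kz < 4; ++kz) {
      int iz = base[2] - 1 + kz;
      for (int ky = 0; ky < 4; ++ky) {
        int iy = base[1] - 1 + ky;
        double wyz = wy[ky] * wz[kz];
        long off = (long)iy * n1 + (long)iz * planesz;
        for (int kx = 0; kx < 4; ++kx) {
          double w = wx[kx] * wyz;
          long idx = (base[0] - 1 + kx) + off;
          gr[idx] += w * g0;
          gr[idx + volsz] += w * g1;
          gr[idx + 2 * volsz] += w * g2;
        }
      }
    }
  }
  return out;
}

// Interior support test used by transform_point(); returns logical vector.
// [[Rcpp::export]]
LogicalVector cpp_bspline_inside(NumericVector grid_origin, NumericVector grid_spacing,
                                 IntegerVector grid_size, NumericMatrix pts) {
  Grid g = read_grid(grid_origin, grid_spacing, grid_size);
  int np = pts.nrow();
  LogicalVector out(np);
  for (int k = 0; k < np; ++k) {
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      double u = (pts(k, a) - g.org[a]) / g.sp[a];
      int b = (int)std::floor(u);
      if (b - 1 < 0 || b + 2 > g.n[a] - 1) {
        if (!(b + 2 == g.n[a] && u == (double)b)) inside = false;
      }
    }
    out[k] = inside;
  }
  return out;
}
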