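#include <Rcpp.h>
using namespace Rcpp;

// Mattes-form mutual information between a set of fixed-image samples and a
// moving image evaluated at their mapped positions.  The joint distribution
// uses a zero-order (histogram) Parzen window along the fixed axis and a
// cubic B-spline window along the moving axis, so the metric is continuously
// differentiable in the mapped positions.  The value returned is -MI (the
// quantity minimised); the gradient is with respect to the mapped physical
// positions and is chained to transform parameters by the caller.

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
List cpp_mattes_mi(NumericVector fvals, NumericMatrix pts, NumericVector mvol,
                   IntegerVector mdims, NumericVector mspacing,
                   NumericVector morigin, int nbins, double fmin, double fmax,
                   double mmin, double mmax, bool want_grad) {
  int np = pts.nrow();
  const double *mv = mvol.begin();
  int d0 = mdims[0], d1 = mdims[1], d2 = mdims[2];
  long nx = d0, nxy = (long)d0 * d1;

  std::vector<double> yval(np), gx(np), gy(np), gz(np);
  std::vector<int> used(np, 0);
  int nused = 0;

  for (int k = 0; k < np; ++k) {
    double ix = (pts(k, 0) - morigin[0]) / mspacing[0];
    double iy = (pts(k, 1) - morigin[1]) / mspacing[1];
    double iz = (pts(k, 2) - morigin[2]) / mspacing[2];
    if (ix < 0 || iy < 0 || iz < 0 || ix > d0 - 1 || iy > d1 - 1 || iz > d2 - 1)
      continue;
    int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy), z0 = (int)std::floor(iz);
    if (x0 == d0 - 1) x0--;
    if (y0 == d1 - 1) y0--;
    if (z0 == d2 - 1) z0--;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = ix - x0, fy = iy - y0, fz = iz - z0;
    int sx = (d0 > 1) ? 1 : 0;
    long sy = (d1 > 1) ? nx : 0, sz = (d2 > 1) ? nxy : 0;
    long base = x0 + (long)y0 * nx + (long)z0 * nxy;
    double c000 = mv[base], c100 = mv[base + sx];
    double c010 = mv[base + sy], c110 = mv[base + sx + sy];
    double c001 = mv[base + sz], c101 = mv[base + sx + sz];
    double c011 = mv[base + sy + sz], c111 = mv[base + sx + sy + sz];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    yval[k] = c0 + fz * (c1 - c0);
    if (want_grad) {
      double gx0 = (c100 - c000) + fy * ((c110 - c010) - (c100 - c000));
      double gx1 = (c101 - c001) + fy * ((c111 - c011) - (c101 - c001));
      gx[k] = (gx0 + fz * (gx1 - gx0)) / mspacing[0];
      gy[k] = ((c10 - c00) + fz * ((c11 - c01) - (c10 - c00))) / mspacing[1];
      gz[k] = (c1 - c0) / mspacing[2];
    }
    used[k] = 1;
    ++nused;
  }

  NumericMatrix grad(want_grad ? np : 1, 3);
  LogicalVector usedv(np);
  for (int k = 0; k < np; ++k) usedv[k] = used[k] != 0;

  if (nused == 0)
    return List::create(_["value"] = NA_REAL, _["gradient"] = grad,
                        _["n_used"] = 0, _["used"] = usedv);

  // Degenerate intensity ranges: a spatially constant partner carries no
  // information, MI = 0 by convention.
  if (!(mmax > mmin) || !(fmax > fmin)) {
    return List::create(_["value"] = 0.0, _["gradient"] = grad,
                        _["n_used"] = nused, _["used"] = usedv);
  }

  double bwf = (fmax - fmin) / nbins;
  // 2-bin padding each side keeps the 4-bin cubic window inside the table
  double bwm = (mmax - mmin) / (nbins - 5);
  std::vector<double> W((long)nbins * nbins, 0.0);
  std::vector<int> fbin(np, 0);
  std::vector<double> mpos(np, 0.0);
  double wnorm = 1.0 / nused;

  for (int k = 0; k < np; ++k) {
    if (!used[k]) continue;
    int fb = (int)std::floor((fvals[k] - fmin) / bwf);
    if (fb < 0) fb = 0;
    if (fb > nbins - 1) fb = nbins - 1;
    double m = (yval[k] - mmin) / bwm + 2.0;
    if (m < 2.0) m = 2.0;
    if (m > nbins - 3.0) m = nbins - 3.0;
    fbin[k] = fb;
    mpos[k] = m;
    int j0 = (int)std::floor(m) - 1;
    for (int j = j0; j < j0 + 4; ++j)
      W[(long)fb * nbins + j] += wnorm * b3(j - m);
  }

  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int f = 0; f < nbins; ++f)
    for (int j = 0; j < nbins; ++j) {
      double w = W[(long)f * nbins + j];
      pf[f] += w;
      pm[j] += w;
    }
  double mi = 0.0;
  for (int f = 0; f < nbins; ++f)
    for (int j = 0; j < nbins; ++j) {
      double w = W[(long)f * nbins + j];
      if (w > 0.0 && pf[f] > 0.0 && pm[j] > 0.0)
        mi += w * std::log(w / (pf[f] * pm[j]));
    }

  if (want_grad) {
    double c = wnorm / bwm;
    for (int k = 0; k < np; ++k) {
      if (!used[k]) continue;
      double m = mpos[k];
      int fb = fbin[k];
      int j0 = (int)std::floor(m) - 1;
      double s = 0.0;
      for (int j = j0; j < j0 + 4; ++j) {
        double w = W[(long)fb * nbins + j];
        double d = db3(j - m);
        if (d != 0.0 && w > 0.0 && pm[j] > 0.0) s += d * std::log(w / pm[j]);
      }
      double gmag = c * s;  // d(-MI)/dy_k
      grad(k, 0) = gmag * gx[k];
      grad(k, 1) = gmag * gy[k];
      grad(k, 2) = gmag * gz[k];
    }
  }

  return List::create(_["value"] = -mi, _["gradient"] = grad,
                      _["n_used"] = nused, _["used"] = usedv);
}
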