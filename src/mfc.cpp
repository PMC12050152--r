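#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double PI2 = M_PI * M_PI;

// Improved-Sheather-Jones discrepancy t - xi * gamma^[7](t) on the squared
// DCT coefficients a2 (frequencies 1..m). Terms are truncated once the
// Gaussian factor drops below exp(-46).
static double isj_discrepancy_cpp(double t, double N,
                                  const std::vector< std::vector<double> >& Ia2,
                                  const std::vector<double>& I) {
  const int m = I.size();
  int l = 7;
  double f = 0.0;
  for (int i = 0; i < m; ++i) {
    double e = I[i] * PI2 * t;
    if (e > 46.0) break;
    f += Ia2[l - 2][i] * std::exp(-e);
  }
  f *= 2.0 * std::pow(M_PI, 2.0 * l);
  if (!(f > 0.0) || !std::isfinite(f)) return NA_REAL;
  for (int s = l - 1; s >= 2; --s) {
    double k0 = 1.0;
    for (int k = 3; k <= 2 * s - 1; k += 2) k0 *= k;
    k0 /= std::sqrt(2.0 * M_PI);
    double cst = (1.0 + std::pow(0.5, s + 0.5)) / 3.0;
    double tt = std::pow(2.0 * cst * k0 / (N * f), 2.0 / (3.0 + 2.0 * s));
    f = 0.0;
    for (int i = 0; i < m; ++i) {
      double e = I[i] * PI2 * tt;
      if (e > 46.0) break;
      f += Ia2[s - 2][i] * std::exp(-e);
    }
    f *= 2.0 * std::pow(M_PI, 2.0 * s);
    if (!(f > 0.0) || !std::isfinite(f)) return NA_REAL;
  }
  double pen = std::pow(2.0 * N * std::sqrt(M_PI) * f, -0.4);
  return t - pen;
}

// Root of the ISJ discrepancy (squared rescaled diffusion time), located by
// geometric bracketing from the pilot value followed by bisection.
// Returns NA when no root can be bracketed (caller falls back to Silverman).
// [[Rcpp::export]]
double cpp_isj_root(NumericVector a2, double N, double t_pilot) {
  const int m = a2.size();
  std::vector<double> I(m);
  for (int i = 0; i < m; ++i) {
    double ii = (double)(i + 1);
    I[i] = ii * ii;
  }
  std::vector< std::vector<double> > Ia2(6, std::vector<double>(m));
  for (int s = 2; s <= 7; ++s)
    for (int i = 0; i < m; ++i)
      Ia2[s - 2][i] = std::pow(I[i], s) * a2[i];

  double t_lo = t_pilot / 4096.0;
  double v_lo = isj_discrepancy_cpp(t_lo, N, Ia2, I);
  int k = 0;
  while (k < 24 && !(std::isfinite(v_lo) && v_lo < 0.0)) {
    t_lo /= 16.0;
    v_lo = isj_discrepancy_cpp(t_lo, N, Ia2, I);
    ++k;
  }
  if (!(std::isfinite(v_lo) && v_lo < 0.0)) return NA_REAL;
  double t_hi = t_lo * 2.0, v_hi;
  k = 0;
  for (;;) {
    v_hi = isj_discrepancy_cpp(t_hi, N, Ia2, I);
    if (!std::isfinite(v_hi)) return NA_REAL;
    if (v_hi > 0.0) break;
    t_lo = t_hi;
    t_hi *= 2.0;
    if (++k >= 60) return NA_REAL;
  }
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (t_lo + t_hi);
    double v = isj_discrepancy_cpp(mid, N, Ia2, I);
    if (!std::isfinite(v)) return NA_REAL;
    if (v < 0.0) t_lo = mid; else t_hi = mid;
    if ((t_hi - t_lo) < 1e-6 * t_hi) break;
  }
  return 0.5 * (t_lo + t_hi);
}

// Pairwise KLS matrix from per-region fine density representations.
// fine_y: nfine x R matrix of density values; region r's fine grid is
// fine_x0[r] + (0..nfine-1) * fine_dx[r]. lo/hi are the region sample
// ranges; each pair grid spans the pooled range padded by `pad` of it.
// [[Rcpp::export]]
NumericMatrix cpp_kls_from_fine(NumericMatrix fine_y, NumericVector fine_x0,
                                NumericVector fine_dx, NumericVector lo,
                                NumericVector hi, int n_grid, double floor_pmf,
                                double pad) {
  const int R = fine_y.ncol();
  const int nfine = fine_y.nrow();
  NumericMatrix out(R, R);
  std::vector<double> p(n_grid), q(n_grid);
  for (int r = 0; r < R; ++r) out(r, r) = 1.0;
  for (int i = 0; i < R - 1; ++i) {
    for (int j = i + 1; j < R; ++j) {
      double glo = std::min(lo[i], lo[j]);
      double ghi = std::max(hi[i], hi[j]);
      double gpad = pad * (ghi - glo);
      glo -= gpad;
      ghi += gpad;
      double dg = (ghi - glo) / (n_grid - 1);
      double sp = 0.0, sq = 0.0;
      for (int g = 0; g < n_grid; ++g) {
        double x = glo + g * dg;
        // linear interpolation from region i's fine grid (0 outside)
        double ui = (x - fine_x0[i]) / fine_dx[i];
        double di = 0.0;
        if (ui >= 0.0 && ui <= nfine - 1) {
          int i0 = (int)ui;
          if (i0 >= nfine - 1) i0 = nfine - 2;
          double fr = ui - i0;
          di = fine_y(i0, i) * (1.0 - fr) + fine_y(i0 + 1, i) * fr;
        }
        double uj = (x - fine_x0[j]) / fine_dx[j];
        double dj = 0.0;
        if (uj >= 0.0 && uj <= nfine - 1) {
          int j0 = (int)uj;
          if (j0 >= nfine - 1) j0 = nfine - 2;
          double fr = uj - j0;
          dj = fine_y(j0, j) * (1.0 - fr) + fine_y(j0 + 1, j) * fr;
        }
        p[g] = std::max(di * dg, floor_pmf);
        q[g] = std::max(dj * dg, floor_pmf);
        sp += p[g];
        sq += q[g];
      }
      double d = 0.0;
      for (int g = 0; g < n_grid; ++g) {
        double pg = p[g] / sp, qg = q[g] / sq;
        d += (pg - qg) * (std::log(pg) - std::log(qg));
      }
      out(i, j) = out(j, i) = std::exp(-d);
    }
  }
  return out;
}
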