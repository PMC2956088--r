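#include <Rcpp.h>
using namespace Rcpp;

// Mean force -dW/dx of the ground-truth landscape, evaluated per substep.
// form: 0 flat, 1 harmonic well (pars: curvature, center, half_width),
// 2 tanh-walled square well (pars: depth, edge_lo, edge_hi, edge_width),
// 3 tabulated (linear interpolation of tabF on the uniform grid tabD).
static inline double landscape_force(double x, int form, const double *pars,
                                     const double *tabD, const double *tabF,
                                     int ntab) {
  switch (form) {
  case 0:
    return 0.0;
  case 1: {
    double dx = x - pars[1];
    if (std::abs(dx) > pars[2]) return 0.0; // outside a truncated well
    return -pars[0] * dx;
  }
  case 2: {
    double depth = pars[0], a = pars[1], b = pars[2], s = pars[3];
    double ta = std::tanh((x - a) / s), tb = std::tanh((b - x) / s);
    double dW = -depth / 4.0 * ((1.0 - ta * ta) / s * (1.0 + tb) -
                                (1.0 + ta) * (1.0 - tb * tb) / s);
    return -dW;
  }
  case 3: {
    if (x <= tabD[0]) return tabF[0];
    if (x >= tabD[ntab - 1]) return tabF[ntab - 1];
    double h = (tabD[ntab - 1] - tabD[0]) / (ntab - 1);
    int i = (int)((x - tabD[0]) / h);
    if (i > ntab - 2) i = ntab - 2;
    double w = (x - tabD[i]) / h;
    return (1.0 - w) * tabF[i] + w * tabF[i + 1];
  }
  }
  return 0.0;
}

// Overdamped (Brownian) dynamics of the separation coordinate under the
// landscape plus a harmonic restraint, Euler-Maruyama with n_substeps
// integration steps per recorded sample. Positions are recorded every dt
// after a burn-in of n_burn samples. Uses R's RNG, so set.seed() applies.
// [[Rcpp::export]]
NumericVector cpp_langevin_positions(int n_samples, double dt, int n_substeps,
                                     double x0, int n_burn,
                                     double restraint_center, double restraint_k,
                                     double diffusion, double beta, int form,
                                     NumericVector pars, double dom_lo,
                                     double dom_hi, NumericVector tabD,
                                     NumericVector tabF) {
  NumericVector out(n_samples);
  const double h = dt / n_substeps;
  const double drift = beta * diffusion * h;
  const double sigma = std::sqrt(2.0 * diffusion * h);
  const double *p = pars.size() ? REAL(pars) : nullptr;
  const double *td = tabD.size() ? REAL(tabD) : nullptr;
  const double *tf = tabF.size() ? REAL(tabF) : nullptr;
  const int ntab = tabD.size();

  double x = x0;
  const long total = (long)(n_samples + n_burn) * n_substeps;
  long rec = 0;
  for (long step = 1; step <= total; ++step) {
    double xe = std::min(std::max(x, dom_lo), dom_hi);
    double f = landscape_force(xe, form, p, td, tf, ntab) -
               restraint_k * (x - restraint_center);
    x += drift * f + sigma * norm_rand();
    if (step % n_substeps == 0) {
      long isamp = step / n_substeps; // 1-based recorded sample index
      if (isamp > n_burn) out[rec++] = x;
    }
  }
  return out;
}
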