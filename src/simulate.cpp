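// Overdamped Langevin (Euler-Maruyama, Ito convention) propagation of
// independent permeants on periodic profiles:
//   dz = [ -beta * Dperp(z) * F'(z) + Dperp'(z) ] dt + sqrt(2 Dperp(z)) dW
//   dx = sqrt(2 Dpar(z)) dW ,  dy likewise (lateral motion is unwrapped).
// Profiles are cosine series over the box height H:
//   F(z)      = sum_k a_k cos(2 pi k z / H)
//   ln D(z)   = ln D0 + sum_k b_k cos(2 pi k z / H)
// Uses R's RNG so set.seed() gives bitwise-reproducible trajectories.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void eval_series(const std::vector<double>& c, double w,
                               double z, double& val, double& deriv) {
  val = 0.0; deriv = 0.0;
  for (size_t k = 1; k <= c.size(); ++k) {
    double kk = w * k;
    val += c[k - 1] * std::cos(kk * z);
    deriv -= c[k - 1] * kk * std::sin(kk * z);
  }
}

// [[Rcpp::export(name = ".sim_overdamped")]]
List sim_overdamped(int n_perm, double total_ps, double dt, double save_dt,
                    NumericVector z0, NumericVector x0, NumericVector y0,
                    NumericVector f_coef, NumericVector ldperp_coef,
                    NumericVector ldpar_coef, double d_perp0, double d_par0,
                    double H, double beta, bool ito_drift) {
  const double w = 2.0 * M_PI / H;
  const long nsteps = (long)std::lround(total_ps / dt);
  const int save_every = (int)std::lround(save_dt / dt);
  if (save_every < 1) stop("save interval smaller than integration step");
  const long n_save = nsteps / save_every + 1;

  std::vector<double> fc(f_coef.begin(), f_coef.end());
  std::vector<double> bp(ldperp_coef.begin(), ldperp_coef.end());
  std::vector<double> bl(ldpar_coef.begin(), ldpar_coef.end());
  const double ln_dp0 = std::log(d_perp0), ln_dl0 = std::log(d_par0);

  NumericMatrix Z(n_save, n_perm), X(n_save, n_perm), Y(n_save, n_perm);
  RNGScope scope;

  for (int p = 0; p < n_perm; ++p) {
    double z = z0[p], x = x0[p], y = y0[p];
    Z(0, p) = z - H * std::floor(z / H + 0.5);
    X(0, p) = x; Y(0, p) = y;
    long isave = 1;
    for (long s = 1; s <= nsteps; ++s) {
      double F, Fp, lp, lpp, ll, llp;
      eval_series(fc, w, z, F, Fp);
      eval_series(bp, w, z, lp, lpp);
      eval_series(bl, w, z, ll, llp);
      double Dperp = std::exp(ln_dp0 + lp);
      double Dpar  = std::exp(ln_dl0 + ll);
      if (!std::isfinite(Fp) || !std::isfinite(Dperp))
        stop("non-finite force or diffusion at z = %f", z);
      double drift = -beta * Dperp * Fp;
      if (ito_drift) drift += Dperp * lpp;  // D'(z) = D(z) * (ln D)'(z)
      z += drift * dt + std::sqrt(2.0 * Dperp * dt) * norm_rand();
      z -= H * std::floor(z / H + 0.5);     // wrap to [-H/2, H/2)
      double sl = std::sqrt(2.0 * Dpar * dt);
      x += sl * norm_rand();
      y += sl * norm_rand();
      if (s % save_every == 0) {
        Z(isave, p) = z; X(isave, p) = x; Y(isave, p) = y;
        ++isave;
      }
    }
  }
  return List::create(_["z"] = Z, _["x"] = X, _["y"] = Y,
                      _["n_save"] = (double)n_save);
}

// First-exit side simulation for walkers initialized inside a flat membrane
// slab: returns +1/-1 exit side per walker.  Constant D, no force.
// [[Rcpp::export(name = ".sim_first_exit_side")]]
IntegerVector sim_first_exit_side(NumericVector zstart, double h_half,
                                  double D, double dt) {
  const int n = zstart.size();
  IntegerVector side(n);
  const double s = std::sqrt(2.0 * D * dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double z = zstart[i];
    while (std::fabs(z) < h_half) z += s * norm_rand();
    side[i] = z > 0 ? 1 : -1;
  }
  return side;
}
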