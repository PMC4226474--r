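// Overdamped Brownian dynamics of a bead-spring chain above an implicit
// plane. Reduced units: kT = 1 (energies in kT), D = 1 (dt is pre-scaled by
// the bead diffusion coefficient on the R side), lengths in nm.
//
// Interactions: harmonic bonds; purely repulsive WCA between beads at least
// two bonds apart; one-sided harmonic wall at z = 0; short-range attractive
// well on the terminal bead for 0 < z < r_bind. Bead 0 is held fixed when
// tethered. The RNG is a self-contained mt19937_64 + Box-Muller stream so
// that a given seed reproduces a trajectory bit-for-bit.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Gauss {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() {  // uniform in (0, 1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double operator()() {
    if (have_spare) { have_spare = false; return spare; }
    double r = std::sqrt(-2.0 * std::log(unif()));
    double th = 6.283185307179586476925287 * unif();
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

}  // namespace

// [[Rcpp::export]]
List bd_core(NumericMatrix coords0, int n_steps, int burn_steps, int thin,
             double dt, double b, double k_bond, double sigma_ev,
             double eps_ev, double k_wall, bool wall, double eps_bind,
             double r_bind, bool tethered, double blow_limit, double f_max,
             int seed) {
  const int n = coords0.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
  }

  Gauss rnorm(static_cast<uint64_t>(seed));
  const double sig2 = sigma_ev * sigma_ev;
  const double rc2 = std::cbrt(2.0) * sig2;  // WCA cutoff^2 = 2^(1/3) sigma^2
  const double rc = std::sqrt(rc2);
  const double noise = std::sqrt(2.0 * dt);
  const double fmax2 = f_max * f_max;
  const int i0 = tethered ? 1 : 0;
  const int n_rec = n_steps / thin;
  NumericVector rec_t(n_rec), rec_z(n_rec), rec_ree(n_rec);

  bool blown = false;
  int rec_i = 0;
  const long total = static_cast<long>(burn_steps) + n_steps;

  for (long step = 0; step < total; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // harmonic bonds
    for (int i = 0; i + 1 < n; ++i) {
      double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) r = 1e-12;
      double f = -k_bond * (r - b) / r;  // on bead i+1 along (dx,dy,dz)
      fx[i + 1] += f * dx; fy[i + 1] += f * dy; fz[i + 1] += f * dz;
      fx[i] -= f * dx; fy[i] -= f * dy; fz[i] -= f * dz;
    }

    // WCA excluded volume, pairs |i-j| >= 2
    if (eps_ev > 0.0) {
      for (int i = 0; i + 2 < n + 0; ++i) {
        for (int j = i + 2; j < n; ++j) {
          double dx = x[j] - x[i];
          if (dx > rc || dx < -rc) continue;
          double dy = y[j] - y[i];
          if (dy > rc || dy < -rc) continue;
          double dz = z[j] - z[i];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= rc2) continue;
          if (r2 < 1e-8) r2 = 1e-8;
          double s2 = sig2 / r2;
          double s6 = s2 * s2 * s2;
          double f = 24.0 * eps_ev * (2.0 * s6 * s6 - s6) / r2;  // repulsive
          fx[j] += f * dx; fy[j] += f * dy; fz[j] += f * dz;
          fx[i] -= f * dx; fy[i] -= f * dy; fz[i] -= f * dz;
        }
      }
    }

    // one-sided harmonic wall at z = 0
    if (wall) {
      for (int i = i0; i < n; ++i)
        if (z[i] < 0.0) fz[i] -= k_wall * z[i];
    }

    // attractive well on the terminal bead: U = -eps (1 - (z/rb)^2)^2
    if (eps_bind > 0.0) {
      double zt = z[n - 1];
      if (zt > 0.0 && zt < r_bind) {
        double s = zt / r_bind;
        fz[n - 1] -= 4.0 * eps_bind * s * (1.0 - s * s) / r_bind;
      }
    }

    // Euler-Maruyama update with a drift cap for rare steep overlaps
    for (int i = i0; i < n; ++i) {
      double fxi = fx[i], fyi = fy[i], fzi = fz[i];
      double f2 = fxi * fxi + fyi * fyi + fzi * fzi;
      if (f2 > fmax2) {
        double s = f_max / std::sqrt(f2);
        fxi *= s; fyi *= s; fzi *= s;
      }
      x[i] += fxi * dt + noise * rnorm();
      y[i] += fyi * dt + noise * rnorm();
      z[i] += fzi * dt + noise * rnorm();
    }

    if ((step & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (std::fabs(x[i]) > blow_limit || std::fabs(y[i]) > blow_limit ||
            std::fabs(z[i]) > blow_limit) { blown = true; break; }
      }
      if (blown) break;
    }

    long prod = step - burn_steps;
    if (prod >= 0 && ((prod + 1) % thin == 0) && rec_i < n_rec) {
      double ex = x[n - 1] - x[0], ey = y[n - 1] - y[0], ez = z[n - 1] - z[0];
      rec_t[rec_i] = (prod + 1) * dt;
      rec_z[rec_i] = z[n - 1];
      rec_ree[rec_i] = std::sqrt(ex * ex + ey * ey + ez * ez);
      ++rec_i;
    }
  }

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i) {
    final_coords(i, 0) = x[i]; final_coords(i, 1) = y[i];
    final_coords(i, 2) = z[i];
  }
  if (blown && rec_i < n_rec) {
    rec_t = head(rec_t, rec_i); rec_z = head(rec_z, rec_i);
    rec_ree = head(rec_ree, rec_i);
  }
  return List::create(_["times"] = rec_t, _["height"] = rec_z,
                      _["ree"] = rec_ree, _["final"] = final_coords,
                      _["blown"] = blown);
}
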