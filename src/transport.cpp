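// Charged-particle transport kernel: continuous ionization energy loss
// (pre-tabulated mass stopping power), Bohr energy-loss straggling,
// Highland multiple Coulomb scattering with per-species f_mcs scaling,
// and exponential free-path sampling against a pre-tabulated mass
// attenuation coefficient.  Each track is advanced until it stops,
// escapes the grid, or reaches a nuclear interaction point; event
// generation itself happens on the R side.
//
// Uses R's RNG (norm_rand/exp_rand), so runs are reproducible under
// set.seed() and single-threaded execution.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double M_U = 931.49410242;   // MeV per nucleon
static const double BOHR_K = 0.1569;      // MeV^2 cm^2 / g
static const double HIGHLAND_E = 13.6;    // MeV

// linear interpolation on the shared log-uniform energy grid
static inline double interp_loggrid(const double *tab, double E,
                                    double loge0, double dloge, int n) {
  double u = (std::log(E) - loge0) / dloge;
  if (u <= 0) return tab[0];
  if (u >= n - 1) return tab[n - 1];
  int i = (int)u;
  double f = u - i;
  return tab[i] * (1 - f) + tab[i + 1] * f;
}

static inline double zeff2(double z, double beta) {
  if (z <= 1.0) return z * z;
  double ze = z * (1.0 - std::exp(-125.0 * beta / std::pow(z, 2.0 / 3.0)));
  return ze * ze;
}

// [[Rcpp::export]]
List transport_kernel(NumericMatrix state, IntegerVector spec_id,
                      IntegerVector sp_z, IntegerVector sp_a,
                      NumericVector f_mcs, LogicalVector nuclear,
                      NumericVector dose, NumericVector dose_sq,
                      NumericVector dens, IntegerVector dims,
                      NumericVector vox, NumericVector origin,
                      double loge0, double dloge,
                      NumericMatrix stop_tab, NumericMatrix murho_tab,
                      IntegerVector murho_row,
                      double z_over_a, double x0_gcm2,
                      double e_cutoff, double max_frac,
                      bool straggling, bool do_mcs) {
  const int ntrk = state.nrow();
  const int negrid = stop_tab.ncol();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double vx = vox[0], vy = vox[1], vz = vox[2];
  const double emin_grid = std::exp(loge0);

  IntegerVector fate(ntrk);
  NumericMatrix out(ntrk, 7);
  double edep_total = 0.0, escaped_total = 0.0;

  std::vector<const double *> stop_rows(stop_tab.nrow());
  std::vector<double> stop_buf(stop_tab.nrow() * negrid);
  for (int s = 0; s < stop_tab.nrow(); ++s) {
    for (int j = 0; j < negrid; ++j) stop_buf[s * negrid + j] = stop_tab(s, j);
    stop_rows[s] = &stop_buf[s * negrid];
  }
  std::vector<double> mu_buf;
  std::vector<const double *> mu_rows(murho_tab.nrow());
  if (murho_tab.nrow() > 0) {
    mu_buf.resize(murho_tab.nrow() * negrid);
    for (int s = 0; s < murho_tab.nrow(); ++s) {
      for (int j = 0; j < negrid; ++j) mu_buf[s * negrid + j] = murho_tab(s, j);
      mu_rows[s] = &mu_buf[s * negrid];
    }
  }

  for (int t = 0; t < ntrk; ++t) {
    double x = state(t, 0), y = state(t, 1), z = state(t, 2);
    double ux = state(t, 3), uy = state(t, 4), uz = state(t, 5);
    double E = state(t, 6);
    const int sid = spec_id[t];
    const double A = sp_a[sid], Zq = sp_z[sid], fm = f_mcs[sid];
    const double *stab = stop_rows[sid];
    const int mrow = murho_row[sid];
    const bool has_nuc = nuclear[t] && mrow >= 0;
    double budget = has_nuc ? exp_rand() : 0.0;
    int f = 0;
    long iter = 0;

    while (true) {
      if (++iter > 20000000L) stop("transport iteration guard tripped");
      int ix = (int)std::floor((x - ox) / vx);
      int iy = (int)std::floor((y - oy) / vy);
      int iz = (int)std::floor((z - oz) / vz);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        f = 1;                      // escaped; energy not scored
        escaped_total += E * A;
        break;
      }
      const R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      const double rho = dens[idx];

      // geometric distance to the voxel boundary along the direction
      double tmax = 1e30;
      if (ux > 0)      { double d = (ox + (ix + 1) * vx - x) / ux; if (d < tmax) tmax = d; }
      else if (ux < 0) { double d = (ox + ix * vx - x) / ux;       if (d < tmax) tmax = d; }
      if (uy > 0)      { double d = (oy + (iy + 1) * vy - y) / uy; if (d < tmax) tmax = d; }
      else if (uy < 0) { double d = (oy + iy * vy - y) / uy;       if (d < tmax) tmax = d; }
      if (uz > 0)      { double d = (oz + (iz + 1) * vz - z) / uz; if (d < tmax) tmax = d; }
      else if (uz < 0) { double d = (oz + iz * vz - z) / uz;       if (d < tmax) tmax = d; }
      if (tmax < 0) tmax = 0;
      double step = tmax + 1e-6;    // push just across the boundary

      if (rho < 1e-9) {             // vacuum-like voxel: free flight
        x += ux * step; y += uy * step; z += uz * step;
        continue;
      }

      const double S = interp_loggrid(stab, std::max(E, emin_grid), loge0,
                                      dloge, negrid);
      const double dEdx = S * rho;  // MeV/cm (total, not per nucleon)
      const double step_E = max_frac * E * A / dEdx;
      if (step_E < step) step = step_E;

      bool interact = false;
      if (has_nuc) {
        const double mu = interp_loggrid(mu_rows[mrow],
                                         std::max(E, emin_grid), loge0,
                                         dloge, negrid) * rho;   // 1/cm
        if (mu * step >= budget) {
          step = budget / mu;
          interact = true;
        } else {
          budget -= mu * step;
        }
      }

      // midpoint-corrected energy loss over the step
      double dE = dEdx * step;
      double Emid = E - 0.5 * dE / A;
      if (Emid < emin_grid) Emid = emin_grid;
      dE = interp_loggrid(stab, Emid, loge0, dloge, negrid) * rho * step;
      if (straggling) {
        const double g = 1.0 + Emid / M_U;
        const double beta = std::sqrt(1.0 - 1.0 / (g * g));
        dE += norm_rand() * std::sqrt(BOHR_K * zeff2(Zq, beta) * z_over_a *
                                      rho * step);
      }
      if (dE < 0) dE = 0;
      if (dE > E * A) dE = E * A;

      dose[idx] += dE;
      dose_sq[idx] += dE * dE;
      edep_total += dE;
      E -= dE / A;

      x += ux * step; y += uy * step; z += uz * step;

      if (E <= e_cutoff) {          // residual range below resolution
        dose[idx] += E * A;
        dose_sq[idx] += E * A * E * A;
        edep_total += E * A;
        E = 0;
        f = 0;
        break;
      }
      if (interact) { f = 2; break; }

      if (do_mcs && Zq > 0) {
        const double t_rad = step * rho / x0_gcm2;
        if (t_rad > 0) {
          const double pc_u = std::sqrt(E * E + 2.0 * E * M_U);
          const double beta = pc_u / (E + M_U);
          double brk = 1.0 + 0.038 * std::log(t_rad);
          if (brk < 0.1) brk = 0.1;
          const double th0 = HIGHLAND_E / (A * pc_u * beta) * Zq *
            std::sqrt(t_rad) * brk * fm;
          const double tx = norm_rand() * th0;
          const double ty = norm_rand() * th0;
          // orthonormal basis perpendicular to the direction
          double b1x, b1y, b1z;
          if (std::fabs(uz) < 0.99) { b1x = -uy; b1y = ux; b1z = 0.0; }
          else {                    // near the z axis: Gram-Schmidt on x
            const double d = ux;    // (1,0,0) . u
            b1x = 1.0 - d * ux; b1y = -d * uy; b1z = -d * uz;
          }
          double nrm = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
          b1x /= nrm; b1y /= nrm; b1z /= nrm;
          const double b2x = uy * b1z - uz * b1y;
          const double b2y = uz * b1x - ux * b1z;
          const double b2z = ux * b1y - uy * b1x;
          ux += tx * b1x + ty * b2x;
          uy += tx * b1y + ty * b2y;
          uz += tx * b1z + ty * b2z;
          nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
        }
      }
    }

    fate[t] = f;
    out(t, 0) = x; out(t, 1) = y; out(t, 2) = z;
    out(t, 3) = ux; out(t, 4) = uy; out(t, 5) = uz;
    out(t, 6) = E;
  }

  return List::create(_["fate"] = fate, _["state"] = out,
                      _["edep"] = edep_total, _["escaped"] = escaped_total);
}
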