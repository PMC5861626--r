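#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// D2Q9 lattice: rest, axis-aligned, diagonal velocities.
// Opposite pairs: (1,3), (2,4), (5,7), (6,8).
static const int ex[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int ey[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const double wq[9] = {4.0 / 9.0,
                             1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                             1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0};
static const int opp[9] = {0, 3, 4, 1, 2, 7, 8, 5, 6};

static inline void equilibrium(double rho, double ux, double uy, double *feq) {
  const double usq = 1.5 * (ux * ux + uy * uy);
  for (int k = 0; k < 9; ++k) {
    const double eu = 3.0 * (ex[k] * ux + ey[k] * uy);
    feq[k] = wq[k] * rho * (1.0 + eu + 0.5 * eu * eu - usq);
  }
}

// Steady-state D2Q9 lattice Boltzmann solver, TRT (or BGK) collision,
// halfway bounce-back walls, non-equilibrium-extrapolation velocity inlets
// and pressure outlet. Time-marched until the relative L2 change of the
// velocity field over `check_every` steps drops below `tol`.
//
// Distributions are stored direction-major (f[k][cell]) so pull streaming
// reads each direction as a contiguous shifted stream.
//
// cells: nx x ny codes (0 solid, >0 fluid; 2/3 velocity inlets, 4 outlet)
// bc_idx: 1-based cell indices of boundary-condition cells
// bc_type: 1 velocity inlet, 2 pressure outlet (parallel to bc_idx)
// bc_ux, bc_uy: prescribed lattice velocity at inlet cells
// bc_nbr: 1-based index of the interior cell anchoring each BC cell
//         (density extrapolation at inlets, velocity at the outlet); 0 = none
// ramp_steps: inlet velocity ramped linearly over this many initial steps
// [[Rcpp::export(name = ".lbm_solve")]]
List lbm_solve(IntegerMatrix cells,
               IntegerVector bc_idx, IntegerVector bc_type,
               NumericVector bc_ux, NumericVector bc_uy,
               IntegerVector bc_nbr,
               double omega_plus, double omega_minus,
               int max_iter, int check_every, double tol,
               int ramp_steps) {
  const int nx = cells.nrow(), ny = cells.ncol();
  const int ncell = nx * ny;
  std::vector<char> isf(ncell);
  std::vector<int> fluid, bulk;
  fluid.reserve(ncell);
  for (int c = 0; c < ncell; ++c) {
    isf[c] = cells[c] > 0;
    if (isf[c]) fluid.push_back(c);
  }
  std::vector<char> btype(ncell, 0);
  std::vector<int> nbrv;
  std::vector<int> bidx;
  std::vector<double> ubx, uby;
  for (int m = 0; m < bc_idx.size(); ++m) {
    const int c = bc_idx[m] - 1;
    btype[c] = (char)bc_type[m];
    bidx.push_back(c);
    nbrv.push_back(bc_nbr[m] - 1);
    ubx.push_back(bc_ux[m]);
    uby.push_back(bc_uy[m]);
  }
  bulk.reserve(fluid.size());
  for (size_t n = 0; n < fluid.size(); ++n) {
    if (btype[fluid[n]] == 0) bulk.push_back(fluid[n]);
  }

  // direction-major storage
  std::vector<double> f(9 * (size_t)ncell, 0.0), fnew(9 * (size_t)ncell, 0.0);
  std::vector<double> ux(ncell, 0.0), uy(ncell, 0.0), rho(ncell, 1.0);
  std::vector<double> uxp(ncell, 0.0), uyp(ncell, 0.0);
  // pull-streaming sources: src[k][cell] = flat index into f (upwind
  // neighbour's slot k, or this cell's slot opp(k) for bounce-back)
  std::vector<int> src(9 * (size_t)ncell);
  for (size_t n = 0; n < fluid.size(); ++n) {
    const int c = fluid[n];
    const int i = c % nx, j = c / nx;
    for (int k = 0; k < 9; ++k) {
      const int si = i - ex[k], sj = j - ey[k];
      if (si < 0 || si >= nx || sj < 0 || sj >= ny || !isf[si + sj * nx]) {
        src[(size_t)k * ncell + c] = opp[k] * ncell + c;
      } else {
        src[(size_t)k * ncell + c] = k * ncell + (si + sj * nx);
      }
    }
  }
  double feq[9], fk[9], feqn[9];
  for (size_t n = 0; n < fluid.size(); ++n) {
    const int c = fluid[n];
    equilibrium(1.0, 0.0, 0.0, feq);
    for (int k = 0; k < 9; ++k) f[(size_t)k * ncell + c] = feq[k];
  }

  const double hop = 0.5 * omega_plus, hom = 0.5 * omega_minus;
  std::vector<double> res_hist;
  std::vector<int> res_iter;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    const double ramp = (ramp_steps > 0 && it < ramp_steps)
      ? (double)it / ramp_steps : 1.0;

    // boundary-condition cells: Guo-type non-equilibrium extrapolation
    for (size_t m = 0; m < bidx.size(); ++m) {
      const int c = bidx[m];
      const int cn = nbrv[m] >= 0 ? nbrv[m] : c;
      double rn = 0.0, rnx = 0.0, rny = 0.0;
      for (int k = 0; k < 9; ++k) {
        fk[k] = f[(size_t)k * ncell + cn];
        rn += fk[k];
        rnx += fk[k] * ex[k];
        rny += fk[k] * ey[k];
      }
      const double vxn = rnx / rn, vyn = rny / rn;
      equilibrium(rn, vxn, vyn, feqn);
      double r, vx, vy;
      if (btype[c] == 1) {        // velocity inlet: prescribed u, rho from
        r = rn;                   // the anchor cell
        vx = ramp * ubx[m];
        vy = ramp * uby[m];
      } else {                    // pressure outlet: rho = 1, zero-gradient u
        r = 1.0;
        vx = vxn;
        vy = vyn;
      }
      equilibrium(r, vx, vy, feq);
      for (int k = 0; k < 9; ++k) {
        fnew[(size_t)k * ncell + c] = feq[k] + (fk[k] - feqn[k]);
      }
      rho[c] = r;
      ux[c] = vx;
      uy[c] = vy;
    }

    // bulk cells: pull streaming + TRT collision
    for (size_t n = 0; n < bulk.size(); ++n) {
      const int c = bulk[n];
      for (int k = 0; k < 9; ++k) fk[k] = f[src[(size_t)k * ncell + c]];
      const double r = fk[0] + fk[1] + fk[2] + fk[3] + fk[4] +
        fk[5] + fk[6] + fk[7] + fk[8];
      const double rux = fk[1] - fk[3] + fk[5] - fk[6] - fk[7] + fk[8];
      const double ruy = fk[2] - fk[4] + fk[5] + fk[6] - fk[7] - fk[8];
      const double vx = rux / r, vy = ruy / r;
      equilibrium(r, vx, vy, feq);
      fnew[c] = fk[0] - omega_plus * (fk[0] - feq[0]);
      static const int kpair[4] = {1, 2, 5, 6};
      for (int p = 0; p < 4; ++p) {
        const int k = kpair[p];
        const int ko = opp[k];
        const double dp = hop * ((fk[k] + fk[ko]) - (feq[k] + feq[ko]));
        const double dm = hom * ((fk[k] - fk[ko]) - (feq[k] - feq[ko]));
        fnew[(size_t)k * ncell + c] = fk[k] - dp - dm;
        fnew[(size_t)ko * ncell + c] = fk[ko] - dp + dm;
      }
      rho[c] = r;
      ux[c] = vx;
      uy[c] = vy;
    }
    f.swap(fnew);

    if (it % check_every == 0) {
      double dnum = 0.0, dden = 0.0;
      for (size_t n = 0; n < fluid.size(); ++n) {
        const int c = fluid[n];
        const double dx = ux[c] - uxp[c], dy = uy[c] - uyp[c];
        dnum += dx * dx + dy * dy;
        dden += ux[c] * ux[c] + uy[c] * uy[c];
        uxp[c] = ux[c];
        uyp[c] = uy[c];
      }
      const double res = std::sqrt(dnum / (dden > 0.0 ? dden : 1.0));
      res_hist.push_back(res);
      res_iter.push_back(it);
      if (res < tol) {
        converged = true;
        break;
      }
      Rcpp::checkUserInterrupt();
    }
  }
  if (it > max_iter) it = max_iter;

  NumericMatrix UX(nx, ny), UY(nx, ny), RHO(nx, ny);
  for (int c = 0; c < ncell; ++c) {
    UX[c] = ux[c];
    UY[c] = uy[c];
    RHO[c] = rho[c];
  }
  return List::create(_["ux"] = UX, _["uy"] = UY, _["rho"] = RHO,
                      _["iterations"] = it, _["converged"] = converged,
                      _["res_iter"] = res_iter, _["residual"] = res_hist);
}
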