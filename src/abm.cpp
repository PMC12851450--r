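#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

// Per-voxel structure-attraction distributions.
//
// For every voxel of the grid, sum the unit vectors pointing toward every
// mask-true voxel within Euclidean distance d (own voxel excluded), fold each
// unit vector into the 6 axis slots (+x,-x,+y,-y,+z,-z) using componentwise
// magnitudes, and L1-normalize.  Voxels sensing no structure get the uniform
// distribution 1/6.  Masks are static during a simulation, so this is
// computed once per (mask, d) and reused by every cell at every step.
//
// `domain` restricts computation to voxels where it is true (others get the
// uniform fallback immediately); pass the brain mask since cells never leave
// it.
// [[Rcpp::export]]
NumericMatrix attraction_field_cpp(LogicalVector mask, IntegerVector dims,
                                   double d, LogicalVector domain) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mask.size() != nvox) stop("mask size does not match dims");
  const bool have_domain = domain.size() == nvox;

  // enumerate sensing offsets once
  const int di = (int)std::floor(d);
  const double d2 = d * d;
  std::vector<std::array<int, 3>> offs;
  std::vector<std::array<double, 6>> u6;
  for (int dz = -di; dz <= di; ++dz)
    for (int dy = -di; dy <= di; ++dy)
      for (int dx = -di; dx <= di; ++dx) {
        const int r2 = dx * dx + dy * dy + dz * dz;
        if (r2 == 0 || (double)r2 > d2) continue;
        const double inv = 1.0 / std::sqrt((double)r2);
        offs.push_back({dx, dy, dz});
        u6.push_back({dx > 0 ?  dx * inv : 0.0,
                      dx < 0 ? -dx * inv : 0.0,
                      dy > 0 ?  dy * inv : 0.0,
                      dy < 0 ? -dy * inv : 0.0,
                      dz > 0 ?  dz * inv : 0.0,
                      dz < 0 ? -dz * inv : 0.0});
      }
  const int noff = (int)offs.size();

  NumericMatrix P(nvox, 6);
  const int nxny = nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t v = x + (R_xlen_t)nx * y + (R_xlen_t)nxny * z;
        if (have_domain && !domain[v]) {
          for (int k = 0; k < 6; ++k) P(v, k) = 1.0 / 6.0;
          continue;
        }
        double acc[6] = {0, 0, 0, 0, 0, 0};
        for (int o = 0; o < noff; ++o) {
          const int xx = x + offs[o][0];
          if (xx < 0 || xx >= nx) continue;
          const int yy = y + offs[o][1];
          if (yy < 0 || yy >= ny) continue;
          const int zz = z + offs[o][2];
          if (zz < 0 || zz >= nz) continue;
          if (!mask[xx + (R_xlen_t)nx * yy + (R_xlen_t)nxny * zz]) continue;
          const std::array<double, 6> &u = u6[o];
          for (int k = 0; k < 6; ++k) acc[k] += u[k];
        }
        double s = 0;
        for (int k = 0; k < 6; ++k) s += acc[k];
        if (s > 0) {
          for (int k = 0; k < 6; ++k) P(v, k) = acc[k] / s;
        } else {
          for (int k = 0; k < 6; ++k) P(v, k) = 1.0 / 6.0;
        }
      }
  return P;
}

// Run the lattice ABM for `steps` time steps.
//
// Dynamics per step: the N_t cells alive at step start are processed in a
// uniformly random permutation; each first proliferates with probability p_p
// if its voxel holds < K cells (offspring placed in the same voxel, inert for
// the rest of the step), then attempts to migrate with probability p_m to a
// von Neumann neighbor drawn from the mixed direction distribution
//   (1/6)(1 - w_wm - w_bv) + w_wm P_wm + w_bv P_bv;
// moves into full voxels, off the grid, or off the brain mask are aborted.
// Offspring enter the actionable pool at the next step.
//
// Treatment (q_mig in [0,1], active for steps with index >= treat_start):
// each acting cell draws its blocked mechanism independently every step —
// with probability q_mig its migration attempt is suppressed, otherwise its
// proliferation attempt is suppressed.  Pass q_mig = -1 for no treatment.
//
// Uses R's RNG stream (seed via set.seed() before calling).
// [[Rcpp::export]]
List run_abm_cpp(IntegerVector counts0, LogicalVector brain, IntegerVector dims,
                 NumericMatrix Pwm, NumericMatrix Pbv,
                 double p_m, double p_p, double w_wm, double w_bv,
                 int K, int steps, double q_mig, int treat_start) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxny = nx * ny;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (counts0.size() != nvox || brain.size() != nvox)
    stop("lattice size does not match dims");
  const bool use_wm = w_wm > 0.0, use_bv = w_bv > 0.0;
  if (use_wm && Pwm.nrow() != nvox) stop("Pwm does not match lattice");
  if (use_bv && Pbv.nrow() != nvox) stop("Pbv does not match lattice");
  const double base = (1.0 - w_wm - w_bv) / 6.0;

  std::vector<int> counts(counts0.begin(), counts0.end());
  std::vector<int> cells;  // voxel index per cell
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (counts[v] < 0) stop("negative cell count");
    if (counts[v] > K) stop("initial count exceeds carrying capacity");
    for (int c = 0; c < counts[v]; ++c) cells.push_back((int)v);
  }

  IntegerVector n_traj(steps + 1);
  n_traj[0] = (int)cells.size();
  long long births = 0, moves = 0, moves_treat = 0;
  std::vector<int> perm;

  RNGScope scope;
  for (int t = 0; t < steps; ++t) {
    const int n_alive = (int)cells.size();  // newborns appended later are inert
    perm.resize(n_alive);
    for (int i = 0; i < n_alive; ++i) perm[i] = i;
    for (int i = n_alive - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    const bool treated = q_mig >= 0.0 && t >= treat_start;

    for (int ii = 0; ii < n_alive; ++ii) {
      const int i = perm[ii];
      const int v = cells[i];
      bool block_mig = false, block_pro = false;
      if (treated) {
        if (unif_rand() < q_mig) block_mig = true; else block_pro = true;
      }
      // proliferation (capacity check includes newborns already placed)
      if (!block_pro && counts[v] < K && unif_rand() < p_p) {
        ++counts[v];
        cells.push_back(v);
        ++births;
      }
      // migration
      if (!block_mig && unif_rand() < p_m) {
        double u = unif_rand(), acc = 0.0;
        int k = 0;
        for (; k < 6; ++k) {
          double pk = base;
          if (use_wm) pk += w_wm * Pwm(v, k);
          if (use_bv) pk += w_bv * Pbv(v, k);
          acc += pk;
          if (u < acc) break;
        }
        if (k == 6) k = 5;  // guard against rounding in the cumulative sum
        int x = v % nx, y = (v / nx) % ny, z = v / nxny;
        switch (k) {
          case 0: ++x; break;
          case 1: --x; break;
          case 2: ++y; break;
          case 3: --y; break;
          case 4: ++z; break;
          case 5: --z; break;
        }
        if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz) {
          const int nv = x + nx * y + nxny * z;
          if (brain[nv] && counts[nv] < K) {
            --counts[v];
            ++counts[nv];
            cells[i] = nv;
            ++moves;
            if (treated) ++moves_treat;
          }
        }
      }
    }
    n_traj[t + 1] = (int)cells.size();
  }

  IntegerVector out(counts.begin(), counts.end());
  return List::create(_["counts"] = out,
                      _["n_cells"] = (double)cells.size(),
                      _["n_traj"] = n_traj,
                      _["births"] = (double)births,
                      _["moves"] = (double)moves,
                      _["moves_treatment"] = (double)moves_treat);
}
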