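// Constant-pH Metropolis Monte Carlo core for the one-bead-per-residue
// model: translation / pivot / crankshaft moves on flexible beads and
// charge-swap moves on titratable sites. Energies in kT. All randomness
// flows through R's RNG so runs are reproducible with set.seed().
//
// Chains have at most two bonded partners per bead, so bonded exclusions
// are two flat integer slots. The screened Coulomb factor exp(-r/kappa)/r
// is tabulated on a fine grid (identical table for incremental and full
// recomputation, so energy bookkeeping stays self-consistent).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int n;
  std::vector<double> x, y, z;
  std::vector<double> q;             // bead charges (sum of site charges)
  std::vector<char> flex;
  std::vector<int> excl1, excl2;     // bonded partners (-1 = none)
  std::vector<int> bond_a, bond_b;
  double lB, screen, sigma2, eps, bond_eq, bond_k, cutoff2, rcont2;

  // tabulated exp(-r*screen)/r on [r_tab0, r_tab1]
  std::vector<double> tab;
  double r_tab0, inv_dr;

  void build_table(double cutoff) {
    r_tab0 = 1.0;
    double r1 = (cutoff > 0) ? cutoff + 1.0 : 2000.0;
    double dr = 0.05;
    inv_dr = 1.0 / dr;
    int m = (int)((r1 - r_tab0) * inv_dr) + 2;
    tab.resize(m);
    for (int i = 0; i < m; ++i) {
      double r = r_tab0 + i * dr;
      tab[i] = std::exp(-r * screen) / r;
    }
  }

  inline double screen_fac(double r) const {
    if (screen == 0.0) return 1.0 / r;
    if (r < r_tab0) return std::exp(-r * screen) / r;
    double t = (r - r_tab0) * inv_dr;
    int i = (int)t;
    if (i + 1 >= (int)tab.size()) return 0.0;
    double f = t - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }

  inline bool excluded(int i, int j) const {
    return j == excl1[i] || j == excl2[i];
  }

  // non-bonded pair energy with bead i virtually at (xi,yi,zi) carrying qi
  inline double nb(int i, int j, double xi, double yi, double zi,
                   double qi) const {
    if (excluded(i, j)) return 0.0;
    double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    double sr2 = sigma2 / r2, sr6 = sr2 * sr2 * sr2;
    double u = 4.0 * eps * (sr6 * sr6 - sr6);
    if (qi != 0.0 && q[j] != 0.0 && lB > 0.0) {
      if (cutoff2 <= 0 || r2 <= cutoff2)
        u += lB * qi * q[j] * screen_fac(std::sqrt(r2));
    }
    return u;
  }

  double bond_energy(int k) const {
    int a = bond_a[k], b = bond_b[k];
    double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - bond_eq;
    return 0.5 * bond_k * d * d;
  }

  double total_energy() const {
    double u = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        u += nb(i, j, x[i], y[i], z[i], q[i]);
    for (size_t k = 0; k < bond_a.size(); ++k) u += bond_energy(k);
    return u;
  }

  inline bool inside(double xi, double yi, double zi) const {
    return xi * xi + yi * yi + zi * zi <= rcont2;
  }

  void setup(NumericMatrix coords, List params, IntegerMatrix bonds) {
    n = coords.nrow();
    x.resize(n); y.resize(n); z.resize(n);
    q.assign(n, 0.0);
    flex.assign(n, 1);
    for (int i = 0; i < n; ++i) {
      x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    }
    excl1.assign(n, -1); excl2.assign(n, -1);
    for (int k = 0; k < bonds.nrow(); ++k) {
      int a = bonds(k, 0) - 1, b = bonds(k, 1) - 1;
      bond_a.push_back(a); bond_b.push_back(b);
      if (excl1[a] < 0) excl1[a] = b; else excl2[a] = b;
      if (excl1[b] < 0) excl1[b] = a; else excl2[b] = a;
    }
    lB = as<double>(params["lB"]);
    screen = as<double>(params["screen"]);
    double sigma = as<double>(params["sigma"]);
    sigma2 = sigma * sigma;
    eps = as<double>(params["eps"]);
    bond_eq = as<double>(params["bond_eq"]);
    bond_k = as<double>(params["bond_k"]);
    double cutoff = as<double>(params["cutoff"]);
    cutoff2 = (cutoff > 0 && R_finite(cutoff)) ? cutoff * cutoff : 0.0;
    rcont2 = 1e18;
    if (params.containsElementNamed("container_radius")) {
      double rc = as<double>(params["container_radius"]);
      rcont2 = rc * rc;
    }
    if (lB > 0) build_table(cutoff2 > 0 ? std::sqrt(cutoff2) : 0.0);
  }
};

void rot_matrix(double ux, double uy, double uz, double ang, double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang), t = 1.0 - c;
  R[0][0] = c + ux * ux * t;      R[0][1] = ux * uy * t - uz * s; R[0][2] = ux * uz * t + uy * s;
  R[1][0] = uy * ux * t + uz * s; R[1][1] = c + uy * uy * t;      R[1][2] = uy * uz * t - ux * s;
  R[2][0] = uz * ux * t - uy * s; R[2][1] = uz * uy * t + ux * s; R[2][2] = c + uz * uz * t;
}

void random_axis(double &ux, double &uy, double &uz) {
  double nrm = 0.0;
  do {
    ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
    nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  } while (nrm < 1e-12);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

} // namespace

// [[Rcpp::export]]
List mc_core_run(NumericMatrix coords, LogicalVector flexible,
                 IntegerMatrix bonds, IntegerMatrix segments,
                 IntegerVector site_bead, LogicalVector site_acid,
                 NumericVector site_pka0, LogicalVector site_prot_init,
                 List params, List config) {
  Model m;
  m.setup(coords, params, bonds);
  for (int i = 0; i < m.n; ++i) m.flex[i] = flexible[i] ? 1 : 0;

  const int n_sites = site_bead.size();
  std::vector<int> sb(n_sites);
  std::vector<char> acid(n_sites), prot(n_sites);
  for (int s = 0; s < n_sites; ++s) {
    sb[s] = site_bead[s] - 1;
    acid[s] = site_acid[s] ? 1 : 0;
    prot[s] = site_prot_init[s] ? 1 : 0;
    // acid: protonated 0 / deprotonated -1; base: protonated +1 / deprot 0
    double qs = acid[s] ? (prot[s] ? 0.0 : -1.0) : (prot[s] ? 1.0 : 0.0);
    m.q[sb[s]] += qs;
  }

  const double pH = as<double>(config["pH"]);
  const int n_sweeps = as<int>(config["n_sweeps"]);
  const int n_equil = as<int>(config["n_equil"]);
  NumericVector wts = config["weights"];   // translation, pivot, crank, swap
  const double max_disp = as<double>(config["max_disp"]);
  const int n_blocks = as<int>(config["n_blocks"]);
  const double ln10 = std::log(10.0);

  std::vector<int> flex_idx;
  for (int i = 0; i < m.n; ++i) if (m.flex[i]) flex_idx.push_back(i);
  const int n_seg = segments.nrow();

  double w_cum[4];
  double tot_w = 0.0;
  for (int t = 0; t < 4; ++t) { tot_w += wts[t]; w_cum[t] = tot_w; }
  if (tot_w <= 0) stop("all move weights are zero");

  double e_run = m.total_energy();
  double e_sum = 0.0;
  long attempts[4] = {0, 0, 0, 0}, accepts[4] = {0, 0, 0, 0};

  const int n_sample = n_sweeps - n_equil;
  NumericMatrix block_sum(n_sites, n_blocks);
  std::vector<int> block_n(n_blocks, 0);

  std::vector<double> nx, ny, nz;   // scratch for rotated coords

  const double *X = m.x.data(), *Y = m.y.data(), *Z = m.z.data();
  const double *Q = m.q.data();

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int att = 0; att < m.n; ++att) {
      double u = unif_rand() * tot_w;
      int mt = 0;
      while (u > w_cum[mt]) ++mt;
      attempts[mt]++;
      if (mt == 0) {
        // --- single-bead translation -------------------------------------
        if (flex_idx.empty()) continue;
        int b = flex_idx[(int)(unif_rand() * flex_idx.size())];
        double xi = X[b] + (unif_rand() - 0.5) * 2.0 * max_disp;
        double yi = Y[b] + (unif_rand() - 0.5) * 2.0 * max_disp;
        double zi = Z[b] + (unif_rand() - 0.5) * 2.0 * max_disp;
        if (!m.inside(xi, yi, zi)) continue;
        double du = 0.0;
        for (int j = 0; j < m.n; ++j) {
          if (j == b) continue;
          du += m.nb(b, j, xi, yi, zi, Q[b]) -
                m.nb(b, j, X[b], Y[b], Z[b], Q[b]);
        }
        for (int p : {m.excl1[b], m.excl2[b]}) {
          if (p < 0) continue;
          double dxo = X[b] - X[p], dyo = Y[b] - Y[p], dzo = Z[b] - Z[p];
          double dxn = xi - X[p], dyn = yi - Y[p], dzn = zi - Z[p];
          double ro = std::sqrt(dxo * dxo + dyo * dyo + dzo * dzo) - m.bond_eq;
          double rn = std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn) - m.bond_eq;
          du += 0.5 * m.bond_k * (rn * rn - ro * ro);
        }
        if (du <= 0 || unif_rand() < std::exp(-du)) {
          m.x[b] = xi; m.y[b] = yi; m.z[b] = zi;
          e_run += du; accepts[0]++;
        }
      } else if (mt == 1 || mt == 2) {
        // --- pivot / crankshaft ------------------------------------------
        if (n_seg == 0) continue;
        int s = (int)(unif_rand() * n_seg);
        int s0 = segments(s, 0) - 1, s1 = segments(s, 1) - 1;
        int side = segments(s, 2);
        int len = s1 - s0 + 1;
        int m0, m1, pivA, pivB; // moving range and fixed reference bead(s)
        double ax, ay, az, ux, uy, uz;
        if (mt == 1) {
          // pivot about a bead; rotate the free side
          if (len < 2) continue;
          if (side == 2) {
            if (len < 3) continue;
            int p = s0 + 1 + (int)(unif_rand() * (len - 2));
            if (unif_rand() < 0.5) { m0 = p + 1; m1 = s1; }
            else { m0 = s0; m1 = p - 1; }
            pivA = pivB = p;
          } else if (side == 1) {      // free end at s1
            int p = s0 + (int)(unif_rand() * (len - 1));
            m0 = p + 1; m1 = s1; pivA = pivB = p;
          } else {                     // free end at s0
            int p = s0 + 1 + (int)(unif_rand() * (len - 1));
            m0 = s0; m1 = p - 1; pivA = pivB = p;
          }
          if (m0 > m1) continue;
          ax = X[pivA]; ay = Y[pivA]; az = Z[pivA];
          random_axis(ux, uy, uz);
        } else {
          // crankshaft about the axis through two beads of the segment
          if (len < 3) continue;
          int i0 = s0 + (int)(unif_rand() * (len - 2));
          int max_span = std::min(7, s1 - i0);
          int j0 = i0 + 2 + (int)(unif_rand() * (max_span - 1));
          if (j0 > s1) continue;
          m0 = i0 + 1; m1 = j0 - 1; pivA = i0; pivB = j0;
          ax = X[pivA]; ay = Y[pivA]; az = Z[pivA];
          ux = X[pivB] - ax; uy = Y[pivB] - ay; uz = Z[pivB] - az;
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          if (nrm < 1e-9) continue;
          ux /= nrm; uy /= nrm; uz /= nrm;
        }
        double ang = (unif_rand() - 0.5) * 2.0 * M_PI;
        double R[3][3];
        rot_matrix(ux, uy, uz, ang, R);
        int nm = m1 - m0 + 1;
        nx.assign(nm, 0); ny.assign(nm, 0); nz.assign(nm, 0);
        bool ok = true;
        for (int k = 0; k < nm; ++k) {
          int b = m0 + k;
          double dx = X[b] - ax, dy = Y[b] - ay, dz = Z[b] - az;
          double rx = R[0][0] * dx + R[0][1] * dy + R[0][2] * dz + ax;
          double ry = R[1][0] * dx + R[1][1] * dy + R[1][2] * dz + ay;
          double rz = R[2][0] * dx + R[2][1] * dy + R[2][2] * dz + az;
          if (!m.inside(rx, ry, rz)) { ok = false; break; }
          nx[k] = rx; ny[k] = ry; nz[k] = rz;
        }
        if (!ok) continue;
        // distances within the moving set and to the pivot bead(s) are
        // preserved; only pairs (moving, outside) change
        double du = 0.0;
        for (int j = 0; j < m.n; ++j) {
          if (j >= m0 && j <= m1) continue;
          if (j == pivA || j == pivB) continue;
          for (int k = 0; k < nm; ++k) {
            int b = m0 + k;
            du += m.nb(b, j, nx[k], ny[k], nz[k], Q[b]) -
                  m.nb(b, j, X[b], Y[b], Z[b], Q[b]);
          }
        }
        if (du <= 0 || unif_rand() < std::exp(-du)) {
          for (int k = 0; k < nm; ++k) {
            int b = m0 + k;
            m.x[b] = nx[k]; m.y[b] = ny[k]; m.z[b] = nz[k];
          }
          e_run += du; accepts[mt]++;
        }
      } else {
        // --- charge swap --------------------------------------------------
        if (n_sites == 0) continue;
        int s = (int)(unif_rand() * n_sites);
        int b = sb[s];
        bool protonate = !prot[s];
        // charge change of the bead if the move is accepted
        double dq = protonate ? 1.0 : -1.0;
        double chem = ln10 * (pH - site_pka0[s]);
        if (!protonate) chem = -chem;
        double du_elec = 0.0;
        if (m.lB > 0) {
          double xb = X[b], yb = Y[b], zb = Z[b];
          for (int j = 0; j < m.n; ++j) {
            if (j == b || Q[j] == 0.0 || m.excluded(b, j)) continue;
            double dx = xb - X[j], dy = yb - Y[j], dz = zb - Z[j];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (m.cutoff2 > 0 && r2 > m.cutoff2) continue;
            du_elec += m.lB * dq * Q[j] * m.screen_fac(std::sqrt(r2));
          }
        }
        double du = chem + du_elec;
        if (du <= 0 || unif_rand() < std::exp(-du)) {
          prot[s] = protonate ? 1 : 0;
          m.q[b] += dq;
          e_run += du_elec;   // chemical term is not configurational energy
          accepts[3]++;
        }
      }
    }
    if (sweep >= n_equil) {
      int ib = (int)((long)(sweep - n_equil) * n_blocks / n_sample);
      if (ib >= n_blocks) ib = n_blocks - 1;
      for (int s = 0; s < n_sites; ++s) block_sum(s, ib) += prot[s];
      block_n[ib]++;
      e_sum += e_run;
    }
  }

  NumericMatrix out_coords(m.n, 3);
  for (int i = 0; i < m.n; ++i) {
    out_coords(i, 0) = m.x[i]; out_coords(i, 1) = m.y[i]; out_coords(i, 2) = m.z[i];
  }
  NumericVector site_mean(n_sites);
  NumericMatrix block_mean(n_sites, n_blocks);
  for (int s = 0; s < n_sites; ++s) {
    double tot = 0.0; long cnt = 0;
    for (int ib = 0; ib < n_blocks; ++ib) {
      block_mean(s, ib) = block_n[ib] > 0 ? block_sum(s, ib) / block_n[ib] : NA_REAL;
      tot += block_sum(s, ib); cnt += block_n[ib];
    }
    site_mean[s] = cnt > 0 ? tot / cnt : NA_REAL;
  }
  IntegerVector att_out(4), acc_out(4);
  for (int t = 0; t < 4; ++t) { att_out[t] = attempts[t]; acc_out[t] = accepts[t]; }

  LogicalVector prot_final(n_sites);
  for (int s = 0; s < n_sites; ++s) prot_final[s] = prot[s] == 1;

  return List::create(
    _["site_mean_protonation"] = site_mean,
    _["block_means"] = block_mean,
    _["attempts"] = att_out,
    _["accepts"] = acc_out,
    _["mean_energy"] = n_sample > 0 ? e_sum / n_sample : NA_REAL,
    _["energy_running"] = e_run,
    _["energy_recomputed"] = m.total_energy(),
    _["coords"] = out_coords,
    _["prot_final"] = prot_final);
}

// [[Rcpp::export]]
double mc_total_energy_cpp(NumericMatrix coords, NumericVector charges,
                           IntegerMatrix bonds, List params) {
  Model m;
  m.setup(coords, params, bonds);
  for (int i = 0; i < m.n; ++i) m.q[i] = charges[i];
  return m.total_energy();
}
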