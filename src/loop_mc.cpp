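#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Bending energy (kT) of a discretized worm-like chain with joint stiffness g
// (kT per joint). The optional rigidly bent vertex is excluded: its angle is
// held fixed by construction and contributes no thermal energy.
static double chain_bend_energy(const NumericMatrix &v, int bend_vertex,
                                double g) {
  const int nv = v.nrow();
  double e = 0.0;
  for (int i = 1; i < nv - 1; ++i) {
    if (i == bend_vertex) continue;
    double ax = v(i, 0) - v(i - 1, 0), ay = v(i, 1) - v(i - 1, 1),
           az = v(i, 2) - v(i - 1, 2);
    double bx = v(i + 1, 0) - v(i, 0), by = v(i + 1, 1) - v(i, 1),
           bz = v(i + 1, 2) - v(i, 2);
    double na = std::sqrt(ax * ax + ay * ay + az * az);
    double nb = std::sqrt(bx * bx + by * by + bz * bz);
    double c = (ax * bx + ay * by + az * bz) / (na * nb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    e += g * (1.0 - c);
  }
  return e;
}

// [[Rcpp::export(name = ".bend_energy_cpp")]]
double bend_energy_cpp(NumericMatrix vertices, int bend_vertex, double g) {
  return chain_bend_energy(vertices, bend_vertex, g);
}

static inline double joint_cos(const NumericMatrix &v, int i) {
  double ax = v(i, 0) - v(i - 1, 0), ay = v(i, 1) - v(i - 1, 1),
         az = v(i, 2) - v(i - 1, 2);
  double bx = v(i + 1, 0) - v(i, 0), by = v(i + 1, 1) - v(i, 1),
         bz = v(i + 1, 2) - v(i, 2);
  double na = std::sqrt(ax * ax + ay * ay + az * az);
  double nb = std::sqrt(bx * bx + by * by + bz * bz);
  double c = (ax * bx + ay * by + az * bz) / (na * nb);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline double end_to_end(const NumericMatrix &v) {
  const int nv = v.nrow();
  double dx = v(nv - 1, 0) - v(0, 0), dy = v(nv - 1, 1) - v(0, 1),
         dz = v(nv - 1, 2) - v(0, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Umbrella-sampled pivot Monte Carlo on a discretized WLC.
//
// vertices: (n+1) x 3 start configuration (nm). bend_vertex: 0-based vertex
// index excluded from pivot selection (rigid internal bend), or -1.
// g: joint stiffness in kT. k_bias: harmonic bias stiffness in pN nm per
// squared bias-coordinate unit; r is expressed in bias units as r_nm /
// bias_unit_nm (bias_unit_nm = 0.338 for bp coordinates, 1 for nm).
// Histogram of r (nm) on a uniform grid [0, nbins*binwidth), split into
// nblocks contiguous production blocks.
// [[Rcpp::export(name = ".mc_umbrella_cpp")]]
List mc_umbrella_cpp(NumericMatrix vertices, int bend_vertex, double g,
                     double k_bias, double r0_bias, double bias_unit_nm,
                     double kT_pn_nm, int n_equil, int n_prod,
                     double max_angle_deg, double binwidth, int nbins,
                     int nblocks, double seed) {
  NumericMatrix v = clone(vertices);
  const int nv = v.nrow();
  const int n_int = nv - 2;  // interior vertices 1..nv-2
  if (n_int < 1) stop("chain too short for pivot moves");

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double max_angle = max_angle_deg * M_PI / 180.0;

  // candidate pivot vertices (exclude the rigid bend vertex)
  std::vector<int> pivots;
  for (int i = 1; i <= nv - 2; ++i)
    if (i != bend_vertex) pivots.push_back(i);
  if (pivots.empty()) stop("no pivot vertices available");

  double e_bend = chain_bend_energy(v, bend_vertex, g);
  double r = end_to_end(v);
  auto bias_energy = [&](double rr) {
    if (k_bias <= 0.0) return 0.0;
    double d = rr / bias_unit_nm - r0_bias;
    return 0.5 * k_bias * d * d / kT_pn_nm;  // kT units
  };
  double e_bias = bias_energy(r);

  IntegerMatrix counts(nbins, nblocks);
  long long accepted = 0;
  double max_drift = 0.0;
  double sum_r = 0.0, sum_r2 = 0.0;
  const long long n_total = (long long)n_equil + n_prod;
  const int block_len = n_prod / nblocks;

  std::vector<double> work(3);
  for (long long step = 0; step < n_total; ++step) {
    const int pv = pivots[(size_t)(unif(rng) * pivots.size()) % pivots.size()];
    // random rotation axis (uniform on sphere) and angle in [-max, max]
    double ux = gauss(rng), uy = gauss(rng), uz = gauss(rng);
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    const double phi = (2.0 * unif(rng) - 1.0) * max_angle;
    const double c = std::cos(phi), s = std::sin(phi), omc = 1.0 - c;
    // Rodrigues rotation matrix
    const double R00 = c + ux * ux * omc, R01 = ux * uy * omc - uz * s,
                 R02 = ux * uz * omc + uy * s;
    const double R10 = uy * ux * omc + uz * s, R11 = c + uy * uy * omc,
                 R12 = uy * uz * omc - ux * s;
    const double R20 = uz * ux * omc - uy * s, R21 = uz * uy * omc + ux * s,
                 R22 = c + uz * uz * omc;

    // rotate the shorter side (both contain a chain end, so r changes)
    const bool tail = (nv - 1 - pv) <= pv;
    const int lo = tail ? pv + 1 : 0;
    const int hi = tail ? nv - 1 : pv - 1;
    const double px = v(pv, 0), py = v(pv, 1), pz = v(pv, 2);

    const double old_cos = joint_cos(v, pv);
    const int nrot = hi - lo + 1;
    std::vector<double> saved((size_t)nrot * 3);
    for (int i = lo; i <= hi; ++i) {
      const int k = i - lo;
      saved[3 * k] = v(i, 0);
      saved[3 * k + 1] = v(i, 1);
      saved[3 * k + 2] = v(i, 2);
      const double dx = v(i, 0) - px, dy = v(i, 1) - py, dz = v(i, 2) - pz;
      v(i, 0) = px + R00 * dx + R01 * dy + R02 * dz;
      v(i, 1) = py + R10 * dx + R11 * dy + R12 * dz;
      v(i, 2) = pz + R20 * dx + R21 * dy + R22 * dz;
    }
    const double new_cos = joint_cos(v, pv);
    const double r_new = end_to_end(v);
    double dE = (pv == bend_vertex) ? 0.0 : g * (old_cos - new_cos);
    dE += bias_energy(r_new) - e_bias;

    bool accept = dE <= 0.0 || unif(rng) < std::exp(-dE);
    if (accept) {
      e_bend += (pv == bend_vertex) ? 0.0 : g * (old_cos - new_cos);
      e_bias = bias_energy(r_new);
      r = r_new;
      if (step >= n_equil) ++accepted;
    } else {
      for (int i = lo; i <= hi; ++i) {
        const int k = i - lo;
        v(i, 0) = saved[3 * k];
        v(i, 1) = saved[3 * k + 1];
        v(i, 2) = saved[3 * k + 2];
      }
    }

    if ((step + 1) % 10000 == 0) {
      const double e_full = chain_bend_energy(v, bend_vertex, g);
      const double drift = std::fabs(e_full - e_bend);
      if (drift > max_drift) max_drift = drift;
      e_bend = e_full;
    }

    if (step >= n_equil) {
      const long long ps = step - n_equil;
      int b = (int)(ps / block_len);
      if (b >= nblocks) b = nblocks - 1;
      int bin = (int)(r / binwidth);
      if (bin >= 0 && bin < nbins) counts(bin, b) += 1;
      sum_r += r;
      sum_r2 += r * r;
    }
  }

  const double mr = sum_r / n_prod;
  return List::create(
      _["counts"] = counts, _["acceptance"] = (double)accepted / n_prod,
      _["max_energy_drift"] = max_drift, _["mean_r"] = mr,
      _["sd_r"] = std::sqrt(std::max(0.0, sum_r2 / n_prod - mr * mr)),
      _["final_vertices"] = v, _["final_energy"] = e_bend);
}
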