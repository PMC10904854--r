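#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Square-well energy of a bead chain: -eps per sticky-sticky pair within
// the well (|i-j| > 1). Returns R_PosInf on hard-core overlap of any
// non-bonded pair.
static double chain_energy(const std::vector<double> &x, int n,
                           double hard2, double well2, double eps,
                           const std::vector<int> &sticky) {
  int contacts = 0;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < hard2) return R_PosInf;
      if (sticky[i] && sticky[j] && d2 < well2) ++contacts;
    }
  }
  return -eps * contacts;
}

// Pivot Monte Carlo sampler for a self-avoiding bead chain with a
// square-well potential among sticky beads. Uses R's RNG so set.seed()
// makes runs fully reproducible. Returns an (n_frames x 3n) matrix of
// coordinates recorded every `stride` accepted-or-rejected moves after
// `burn_in` moves.
// [[Rcpp::export]]
NumericMatrix sample_chain_cpp(int n_res, double bond, double hard_core,
                               double well, double eps,
                               IntegerVector sticky_flags, double kT,
                               int n_frames, int burn_in, int stride) {
  RNGScope scope;
  int n = n_res;
  std::vector<double> x(3 * n), trial(3 * n);
  std::vector<int> sticky(n);
  for (int i = 0; i < n; ++i) sticky[i] = sticky_flags[i];
  // initial conformation: straight line along x
  for (int i = 0; i < n; ++i) {
    x[3 * i] = bond * i;
    x[3 * i + 1] = 0.0;
    x[3 * i + 2] = 0.0;
  }
  double hard2 = hard_core * hard_core;
  double well2 = well * well;

  NumericMatrix out(n_frames, 3 * n);
  int total_moves = burn_in + n_frames * stride;
  int recorded = 0;
  // burn-in anneals the well depth from 0 to its target so deep quenches
  // reach the collapsed equilibrium instead of a metastable trap
  double eps_cur = (burn_in > 0) ? 0.0 : eps;
  double e_cur = chain_energy(x, n, hard2, well2, eps_cur, sticky);

  for (int m = 0; m < total_moves; ++m) {
    double eps_new = (m < burn_in) ? eps * ((double)(m + 1) / burn_in) : eps;
    if (eps_new != eps_cur) {
      // rescale the current configuration's energy to the new well depth
      e_cur = chain_energy(x, n, hard2, well2, eps_new, sticky);
      eps_cur = eps_new;
    }
    // random axis (uniform on sphere) and angle, shared by both move types
    double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
    double norm = std::sqrt(ax * ax + ay * ay + az * az);
    ax /= norm; ay /= norm; az /= norm;
    double theta = unif_rand() * 2.0 * M_PI;
    double c = std::cos(theta), s = std::sin(theta), t = 1.0 - c;
    double R[3][3] = {
      {t * ax * ax + c, t * ax * ay - s * az, t * ax * az + s * ay},
      {t * ax * ay + s * az, t * ay * ay + c, t * ay * az - s * ax},
      {t * ax * az - s * ay, t * ay * az + s * ax, t * az * az + c}};

    trial = x;
    if (unif_rand() < 0.5) {
      // pivot move: rotate tail p+1..n-1 about bead p
      int p = (int)std::floor(unif_rand() * (n - 1));
      if (p > n - 2) p = n - 2;
      double px = x[3 * p], py = x[3 * p + 1], pz = x[3 * p + 2];
      for (int i = p + 1; i < n; ++i) {
        double vx = x[3 * i] - px, vy = x[3 * i + 1] - py,
               vz = x[3 * i + 2] - pz;
        trial[3 * i] = px + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
        trial[3 * i + 1] = py + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
        trial[3 * i + 2] = pz + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
      }
    } else {
      // local kink move: rotate one interior bead about the axis through
      // its neighbours (keeps both bond lengths); improves mixing in
      // collapsed globules where pivots are rarely accepted
      int i = 1 + (int)std::floor(unif_rand() * (n - 2));
      if (i > n - 2) i = n - 2;
      double kx = x[3 * (i + 1)] - x[3 * (i - 1)];
      double ky = x[3 * (i + 1) + 1] - x[3 * (i - 1) + 1];
      double kz = x[3 * (i + 1) + 2] - x[3 * (i - 1) + 2];
      double knorm = std::sqrt(kx * kx + ky * ky + kz * kz);
      if (knorm > 1e-10) {
        kx /= knorm; ky /= knorm; kz /= knorm;
        double kc = std::cos(theta), ks = std::sin(theta), kt = 1.0 - kc;
        double K[3][3] = {
          {kt * kx * kx + kc, kt * kx * ky - ks * kz, kt * kx * kz + ks * ky},
          {kt * kx * ky + ks * kz, kt * ky * ky + kc, kt * ky * kz - ks * kx},
          {kt * kx * kz - ks * ky, kt * ky * kz + ks * kx, kt * kz * kz + kc}};
        double ox = x[3 * (i - 1)], oy = x[3 * (i - 1) + 1],
               oz = x[3 * (i - 1) + 2];
        double vx = x[3 * i] - ox, vy = x[3 * i + 1] - oy,
               vz = x[3 * i + 2] - oz;
        trial[3 * i] = ox + K[0][0] * vx + K[0][1] * vy + K[0][2] * vz;
        trial[3 * i + 1] = oy + K[1][0] * vx + K[1][1] * vy + K[1][2] * vz;
        trial[3 * i + 2] = oz + K[2][0] * vx + K[2][1] * vy + K[2][2] * vz;
      }
    }
    double e_new = chain_energy(trial, n, hard2, well2, eps_cur, sticky);
    bool accept = false;
    if (R_finite(e_new)) {
      if (e_new <= e_cur) {
        accept = true;
      } else {
        accept = unif_rand() < std::exp(-(e_new - e_cur) / kT);
      }
    }
    if (accept) {
      x = trial;
      e_cur = e_new;
    }
    int after = m + 1 - burn_in;
    if (after > 0 && after % stride == 0 && recorded < n_frames) {
      for (int i = 0; i < 3 * n; ++i) out(recorded, i) = x[i];
      ++recorded;
    }
  }
  return out;
}
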