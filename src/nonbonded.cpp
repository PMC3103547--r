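// Nonbonded energy kernel: Lennard-Jones + Coulomb over a masked pair list,
// plus Still-type Generalized-Born solvation with Hawkins-Cramer-Truhlar
// (HCT) pairwise-descreening effective Born radii. All energies kcal/mol,
// distances Angstrom, charges e.

#include <Rcpp.h>
using namespace Rcpp;

static const double KE = 332.0636; // kcal*A/(mol*e^2)

// Descreening neighbours beyond this distance contribute < 1e-4 1/A to any
// inverse Born radius and are skipped.
static const double HCT_CUTOFF2 = 12.0 * 12.0;

static void hct_radii(int n, const double* x, const double* y,
                      const double* z, const double* rho, double scale,
                      std::vector<double>& B) {
  for (int i = 0; i < n; ++i) {
    double inv = 1.0 / rho[i];
    const double xi = x[i], yi = y[i], zi = z[i], rhoi = rho[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > HCT_CUTOFF2) continue;
      const double r = std::sqrt(r2);
      const double S = scale * rho[j];
      if (r + S <= rhoi) continue;  // neighbour fully inside atom i
      const double L = (r - S > rhoi) ? (r - S) : rhoi;
      const double U = r + S;
      const double iL = 1.0 / L, iU = 1.0 / U;
      const double term = (iL - iU)
        + 0.25 * r * (iU * iU - iL * iL)
        + (0.5 / r) * std::log(L / U)
        + (0.25 * S * S / r) * (iL * iL - iU * iU);
      inv -= 0.5 * term;
    }
    // saturation: heavily descreened (deeply buried / transiently clashing)
    // atoms are capped at B_MAX instead of letting 1/B cross zero, keeping
    // the energy finite and the descent continuous
    const double INV_B_MAX = 1.0 / 1000.0;
    if (inv < INV_B_MAX) inv = INV_B_MAX;
    B[i] = 1.0 / inv;
  }
}

// HCT effective Born radii with a global descreening scale factor.
// 1/B_i = 1/rho_i - sum_j I(r_ij, rho_i, s*rho_j)
// [[Rcpp::export]]
NumericVector born_radii_cpp(NumericMatrix xyz, NumericVector rho,
                             double scale) {
  int n = xyz.nrow();
  std::vector<double> B(n);
  hct_radii(n, &xyz(0, 0), &xyz(0, 1), &xyz(0, 2), rho.begin(), scale, B);
  return NumericVector(B.begin(), B.end());
}

static void nb_terms(int n, const double* x, const double* y, const double* z,
                     const double* q, const double* sig, const double* eps,
                     const double* born, const int* pi, const int* pj,
                     const double* pw, int np, double eps_int,
                     double eps_solv, double& e_lj, double& e_coul,
                     double& e_gb) {
  e_lj = 0.0; e_coul = 0.0; e_gb = 0.0;
  for (int k = 0; k < np; ++k) {
    const int i = pi[k], j = pj[k];
    const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 <= 0.0)
      stop("coincident atoms %d and %d", i + 1, j + 1);
    const double sij = 0.5 * (sig[i] + sig[j]);
    const double eij = std::sqrt(eps[i] * eps[j]);
    const double s2 = sij * sij / r2;
    const double sr6 = s2 * s2 * s2;
    e_lj += pw[k] * 4.0 * eij * (sr6 * sr6 - sr6);
    e_coul += pw[k] * KE * q[i] * q[j] / (eps_int * std::sqrt(r2));
  }
  // Still GB: -0.5 * tau * sum_ij ke qi qj / fGB, all pairs + self
  const double tau = (1.0 / eps_int - 1.0 / eps_solv);
  for (int i = 0; i < n; ++i) {
    if (q[i] == 0.0) continue;
    e_gb += -0.5 * tau * KE * q[i] * q[i] / born[i];
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = i + 1; j < n; ++j) {
      if (q[j] == 0.0) continue;
      const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double bb = born[i] * born[j];
      const double fgb = std::sqrt(r2 + bb * std::exp(-r2 / (4.0 * bb)));
      e_gb += -tau * KE * q[i] * q[j] / fgb;
    }
  }
}

// LJ + Coulomb over the supplied pair list (0-based indices, per-pair weight
// w: excluded pairs are not in the list, 0.5 for 1-4 pairs, 1 otherwise)
// and GB over all pairs including self terms.
// [[Rcpp::export]]
List nb_energy_cpp(NumericMatrix xyz, NumericVector q, NumericVector sig,
                   NumericVector eps, NumericVector born,
                   IntegerVector pi, IntegerVector pj, NumericVector pw,
                   double eps_int, double eps_solv) {
  double e_lj, e_coul, e_gb;
  nb_terms(xyz.nrow(), &xyz(0, 0), &xyz(0, 1), &xyz(0, 2), q.begin(),
           sig.begin(), eps.begin(), born.begin(), pi.begin(), pj.begin(),
           pw.begin(), pi.size(), eps_int, eps_solv, e_lj, e_coul, e_gb);
  return List::create(_["lj"] = e_lj, _["coulomb"] = e_coul, _["gb"] = e_gb);
}

// Born radii + all terms in one call, returning the total (fast path for
// torsion relaxation).
// [[Rcpp::export]]
double nb_total_cpp(NumericMatrix xyz, NumericVector q, NumericVector sig,
                    NumericVector eps, NumericVector rho, double scale,
                    IntegerVector pi, IntegerVector pj, NumericVector pw,
                    double eps_int, double eps_solv) {
  int n = xyz.nrow();
  std::vector<double> B(n);
  hct_radii(n, &xyz(0, 0), &xyz(0, 1), &xyz(0, 2), rho.begin(), scale, B);
  double e_lj, e_coul, e_gb;
  nb_terms(n, &xyz(0, 0), &xyz(0, 1), &xyz(0, 2), q.begin(), sig.begin(),
           eps.begin(), B.data(), pi.begin(), pj.begin(), pw.begin(),
           pi.size(), eps_int, eps_solv, e_lj, e_coul, e_gb);
  return e_lj + e_coul + e_gb;
}

// Screened pairwise interaction between unit-charge sites (Coulomb + GB
// cross term), used for titration couplings and background terms.
// [[Rcpp::export]]
NumericMatrix screened_coupling_cpp(NumericMatrix xyz, NumericVector q,
                                    NumericVector born, double eps_int,
                                    double eps_solv) {
  int n = xyz.nrow();
  double tau = (1.0 / eps_int - 1.0 / eps_solv);
  NumericMatrix W(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r <= 0.0) stop("coincident sites %d and %d", i + 1, j + 1);
      double bb = born[i] * born[j];
      double fgb = std::sqrt(r2 + bb * std::exp(-r2 / (4.0 * bb)));
      double w = KE * q[i] * q[j] * (1.0 / (eps_int * r) - tau / fgb);
      W(i, j) = w;
      W(j, i) = w;
    }
  }
  return W;
}

// Single-site Metropolis Monte Carlo over ionization microstates at one pH.
// h[i]: energy (kcal/mol) of the ionized form of site i relative to neutral;
// W: pairwise ionized-ionized couplings. Returns the average ionization
// indicator per site over post-burn-in sweeps. Uses R's RNG (set.seed).
// [[Rcpp::export]]
NumericVector mc_titration_cpp(NumericVector h, NumericMatrix W, int sweeps,
                               double burn_frac, double kT) {
  int n = h.size();
  std::vector<int> x(n, 0);
  std::vector<double> acc(n, 0.0);
  int burn = (int)(sweeps * burn_frac);
  int kept = 0;
  RNGScope scope;
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      double dE = h[i];
      for (int j = 0; j < n; ++j)
        if (j != i && x[j]) dE += W(i, j);
      if (x[i]) dE = -dE;  // flipping down
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) x[i] = 1 - x[i];
    }
    if (s >= burn) {
      ++kept;
      for (int i = 0; i < n; ++i) acc[i] += x[i];
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = acc[i] / kept;
  return out;
}
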