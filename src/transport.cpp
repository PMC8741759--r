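// Condensed-history electron transport for a voxelized homogeneous bulk.
//
// Physics model (deliberately simple, documented in the package vignette):
//  - CSDA energy loss from the Berger-Seltzer collision stopping power
//    (no density-effect correction; < ~3% below 2.3 MeV).
//  - Step length limited to a maximum fractional energy loss and a maximum
//    geometric step; energy deposited at the step midpoint.
//  - Multiple scattering: Highland/Rossi Gaussian small-angle model per step.
//  - Tracking cutoff: residual energy deposited locally.
//  - Bremsstrahlung neglected (radiative yield < 2% for Y-90 betas in water).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

constexpr double MEC2 = 0.51099895; // MeV

// xoshiro-free deterministic RNG: 64-bit Mersenne twister is standardized.
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  // uniform in [0,1) built from raw bits: identical on every platform
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_open() { // (0,1)
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  double gauss() {
    double u1 = unif_open(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct MaterialPars {
  double density;   // g/cm^3
  double z_over_a;  // mol electrons per g (relative)
  double i_mc2;     // mean excitation energy in units of mec2
  double x0_cm;     // radiation length in cm
};

// Collision stopping power, MeV/cm
inline double stopping_power(double E, const MaterialPars& m) {
  double tau = E / MEC2;
  double gamma = tau + 1.0;
  double beta2 = 1.0 - 1.0 / (gamma * gamma);
  double term = std::log(tau * tau * (tau + 2.0) / (2.0 * m.i_mc2 * m.i_mc2))
              + 1.0 - beta2
              + (tau * tau / 8.0 - (2.0 * tau + 1.0) * M_LN2)
                / ((tau + 1.0) * (tau + 1.0));
  return 0.1535336 * m.density * m.z_over_a / beta2 * term;
}

// Rotate unit vector d by polar angle theta with uniform azimuth phi
inline void rotate_dir(double* d, double theta, double phi) {
  double st = std::sin(theta), ct = std::cos(theta);
  double sp = std::sin(phi), cp = std::cos(phi);
  double u = d[0], v = d[1], w = d[2];
  double s2 = 1.0 - w * w;
  if (s2 < 1e-12) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = (w >= 0 ? ct : -ct);
  } else {
    double s = std::sqrt(s2);
    d[0] = u * ct + st * (u * w * cp - v * sp) / s;
    d[1] = v * ct + st * (v * w * cp + u * sp) / s;
    d[2] = w * ct - s * st * cp;
  }
  double n = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

inline double sample_energy(const NumericVector& cdf_u,
                            const NumericVector& cdf_e, double u) {
  // linear interpolation in the inverse CDF table
  int lo = 0, hi = cdf_u.size() - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (cdf_u[mid] <= u) lo = mid; else hi = mid;
  }
  double du = cdf_u[hi] - cdf_u[lo];
  double f = du > 0 ? (u - cdf_u[lo]) / du : 0.0;
  return cdf_e[lo] + f * (cdf_e[hi] - cdf_e[lo]);
}

struct Deposit {
  virtual void operator()(const double* pos, double de) = 0;
  virtual ~Deposit() = default;
};

// Transport one electron of energy E0 from pos0 along dir0.
void track(double E0, const double* pos0, const double* dir0,
           const MaterialPars& mat, double cutoff, double max_defrac,
           double max_step_mm, Rng& rng, Deposit& dep) {
  double E = E0;
  double pos[3] = {pos0[0], pos0[1], pos0[2]};
  double dir[3] = {dir0[0], dir0[1], dir0[2]};
  while (E > cutoff) {
    double S = stopping_power(E, mat); // MeV/cm
    double de = max_defrac * E;
    double step_mm = de / S * 10.0;
    if (step_mm > max_step_mm) {
      step_mm = max_step_mm;
      de = S * step_mm / 10.0;
    }
    if (de > E - cutoff) {
      de = E - cutoff;
      step_mm = de / S * 10.0;
    }
    double mid[3] = {pos[0] + dir[0] * step_mm * 0.5,
                     pos[1] + dir[1] * step_mm * 0.5,
                     pos[2] + dir[2] * step_mm * 0.5};
    dep(mid, de);
    pos[0] += dir[0] * step_mm;
    pos[1] += dir[1] * step_mm;
    pos[2] += dir[2] * step_mm;
    E -= de;
    if (E <= cutoff) break;
    // Highland multiple-scattering angle for this step, x = step / X0
    double x = step_mm / 10.0 / mat.x0_cm;
    if (x > 0) {
      double p = std::sqrt(E * (E + 2.0 * MEC2)); // MeV/c
      double beta = p / (E + MEC2);
      double corr = 1.0 + 0.038 * std::log(x);
      if (corr < 0.25) corr = 0.25;
      double th0 = 13.6 / (beta * p) * std::sqrt(x) * corr; // p in MeV/c
      // Rayleigh-distributed spatial angle from 2D Gaussian components
      double theta = th0 * std::sqrt(-2.0 * std::log(rng.unif_open()));
      if (theta > 1.5) theta = 1.5; // small-angle model sanity clamp
      rotate_dir(dir, theta, 2.0 * M_PI * rng.unif());
    }
  }
  dep(pos, E); // residual below cutoff deposited locally
}

} // namespace

// Voxel grid scorer: centers x,y in {x0 .. x0+nx-1} mm, z in {z0 .. z0+nz-1}
struct GridDeposit : public Deposit {
  std::vector<double>& batch;
  double& escaped;
  int nx, ny, nz;
  double x0, y0, z0;
  GridDeposit(std::vector<double>& b, double& esc,
              int nx_, int ny_, int nz_, double x0_, double y0_, double z0_)
    : batch(b), escaped(esc), nx(nx_), ny(ny_), nz(nz_),
      x0(x0_), y0(y0_), z0(z0_) {}
  void operator()(const double* pos, double de) override {
    int i = (int)std::floor(pos[0] - x0 + 0.5);
    int j = (int)std::floor(pos[1] - y0 + 0.5);
    int k = (int)std::floor(pos[2] - z0 + 0.5);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
      escaped += de;
    } else {
      batch[(size_t)k * nx * ny + (size_t)j * nx + i] += de;
    }
  }
};

// [[Rcpp::export]]
List cpp_mc_grid(double n_hist, int seed, int n_batch,
                 double R_mm, double t_mm,
                 double density, double z_over_a, double i_eV, double x0_g_cm2,
                 NumericVector cdf_u, NumericVector cdf_e,
                 double cutoff_MeV, double max_defrac, double max_step_mm,
                 int nx, int ny, int nz,
                 double x0c, double y0c, double z0c) {
  MaterialPars mat{density, z_over_a, i_eV * 1e-6 / MEC2, x0_g_cm2 / density};
  Rng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> sum(nvox, 0.0), sumsq(nvox, 0.0), batch(nvox, 0.0);
  double e_emitted = 0.0, e_escaped = 0.0;
  long long total = (long long)n_hist;
  long long per_batch = total / n_batch;
  GridDeposit dep(batch, e_escaped, nx, ny, nz, x0c, y0c, z0c);
  long long done = 0;
  for (int b = 0; b < n_batch; ++b) {
    long long nb = (b == n_batch - 1) ? (total - done) : per_batch;
    done += nb;
    std::fill(batch.begin(), batch.end(), 0.0);
    for (long long h = 0; h < nb; ++h) {
      // emission point uniform in the source cylinder (disc when t = 0)
      double r = R_mm * std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      double pos[3] = {r * std::cos(phi), r * std::sin(phi),
                       t_mm > 0 ? (rng.unif() - 0.5) * t_mm : 0.0};
      // isotropic direction
      double w = 2.0 * rng.unif() - 1.0;
      double s = std::sqrt(std::max(0.0, 1.0 - w * w));
      double psi = 2.0 * M_PI * rng.unif();
      double dir[3] = {s * std::cos(psi), s * std::sin(psi), w};
      double E = sample_energy(cdf_u, cdf_e, rng.unif());
      e_emitted += E;
      track(E, pos, dir, mat, cutoff_MeV, max_defrac, max_step_mm, rng, dep);
    }
    for (size_t v = 0; v < nvox; ++v) {
      sum[v] += batch[v];
      sumsq[v] += batch[v] * batch[v];
    }
    Rcpp::checkUserInterrupt();
  }
  NumericVector dose(nvox), sigma(nvox);
  double e_dep = 0.0;
  for (size_t v = 0; v < nvox; ++v) {
    dose[v] = sum[v];
    e_dep += sum[v];
    double varb = (sumsq[v] - sum[v] * sum[v] / n_batch)
                  / std::max(1, n_batch - 1);
    sigma[v] = std::sqrt(std::max(0.0, varb * n_batch)); // sigma of the total
  }
  dose.attr("dim") = IntegerVector::create(nx, ny, nz);
  sigma.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["edep_MeV"] = dose, _["sigma_MeV"] = sigma,
                      _["e_emitted_MeV"] = e_emitted,
                      _["e_escaped_MeV"] = e_escaped,
                      _["e_deposited_MeV"] = e_dep);
}

// Spherical-shell scorer for the point kernel
struct ShellDeposit : public Deposit {
  std::vector<double>& shells;
  double& escaped;
  double dr;
  int n;
  ShellDeposit(std::vector<double>& s, double& esc, double dr_, int n_)
    : shells(s), escaped(esc), dr(dr_), n(n_) {}
  void operator()(const double* pos, double de) override {
    double r = std::sqrt(pos[0]*pos[0] + pos[1]*pos[1] + pos[2]*pos[2]);
    int i = (int)(r / dr);
    if (i >= n) escaped += de; else shells[i] += de;
  }
};

// [[Rcpp::export]]
List cpp_mc_point_kernel(double n_hist, int seed,
                         double density, double z_over_a, double i_eV,
                         double x0_g_cm2,
                         NumericVector cdf_u, NumericVector cdf_e,
                         double cutoff_MeV, double max_defrac,
                         double max_step_mm, double dr_mm, int n_shell) {
  MaterialPars mat{density, z_over_a, i_eV * 1e-6 / MEC2, x0_g_cm2 / density};
  Rng rng((uint64_t)seed * 6364136223846793005ULL + 88172645463325252ULL);
  std::vector<double> shells(n_shell, 0.0);
  double e_emitted = 0.0, e_escaped = 0.0;
  ShellDeposit dep(shells, e_escaped, dr_mm, n_shell);
  long long total = (long long)n_hist;
  for (long long h = 0; h < total; ++h) {
    double pos[3] = {0.0, 0.0, 0.0};
    double w = 2.0 * rng.unif() - 1.0;
    double s = std::sqrt(std::max(0.0, 1.0 - w * w));
    double psi = 2.0 * M_PI * rng.unif();
    double dir[3] = {s * std::cos(psi), s * std::sin(psi), w};
    double E = sample_energy(cdf_u, cdf_e, rng.unif());
    e_emitted += E;
    track(E, pos, dir, mat, cutoff_MeV, max_defrac, max_step_mm, rng, dep);
    if (h % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["shell_MeV"] = NumericVector(shells.begin(), shells.end()),
                      _["e_emitted_MeV"] = e_emitted,
                      _["e_escaped_MeV"] = e_escaped);
}

// Superpose a radial point kernel over a uniform source cylinder.
// kernel_r: shell-center radii (mm, uniform spacing), kernel_k: dose per
// decay (Gy) at those distances. Returns dose per decay (Gy) at each
// (r_target, z_target) pair, averaged over emission positions.
// [[Rcpp::export]]
NumericMatrix cpp_kernel_superpose(NumericVector kernel_r, NumericVector kernel_k,
                                   double R_mm, double t_mm,
                                   NumericVector r_targets, NumericVector z_targets,
                                   int n_r, int n_phi, int n_z) {
  int nk = kernel_r.size();
  double dr = kernel_r[1] - kernel_r[0];
  double r0k = kernel_r[0];
  double rmax = kernel_r[nk - 1];
  auto kval = [&](double d) -> double {
    double f = (d - r0k) / dr;
    if (f <= 0) return kernel_k[0];
    int i = (int)f;
    if (i >= nk - 1) return 0.0;
    double w = f - i;
    return kernel_k[i] * (1.0 - w) + kernel_k[i + 1] * w;
  };
  (void)rmax;
  int nz_eff = t_mm > 0 ? n_z : 1;
  // midpoint nodes: uniform in r'^2 (area), phi, z'
  std::vector<double> rs(n_r), zs(nz_eff);
  for (int i = 0; i < n_r; ++i)
    rs[i] = R_mm * std::sqrt((i + 0.5) / n_r);
  for (int i = 0; i < nz_eff; ++i)
    zs[i] = t_mm > 0 ? (-t_mm / 2.0 + t_mm * (i + 0.5) / nz_eff) : 0.0;
  int nt_r = r_targets.size(), nt_z = z_targets.size();
  NumericMatrix out(nt_r, nt_z);
  double wgt = 1.0 / ((double)n_r * n_phi * nz_eff);
  for (int a = 0; a < nt_r; ++a) {
    double rt = r_targets[a];
    for (int b = 0; b < nt_z; ++b) {
      double zt = z_targets[b];
      double acc = 0.0;
      for (int i = 0; i < n_r; ++i) {
        double rp = rs[i];
        double c0 = rt * rt + rp * rp;
        for (int j = 0; j < n_phi; ++j) {
          double phi = 2.0 * M_PI * (j + 0.5) / n_phi;
          double horiz2 = c0 - 2.0 * rt * rp * std::cos(phi);
          for (int m = 0; m < nz_eff; ++m) {
            double dz = zt - zs[m];
            acc += kval(std::sqrt(horiz2 + dz * dz));
          }
        }
      }
      out(a, b) = acc * wgt;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
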