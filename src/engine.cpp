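// Core numerical kernels: pair potentials, Ewald electrostatics, BAOAB
// Langevin integration, virial pressure, structure factors.
//
// Conventions: reduced units (sigma_ion = 1, kBT = 1, m = 1). Positions are
// kept unwrapped; all pair terms use the minimum-image convention so wrapping
// never affects energies or forces. All RNG draws go through R's generator so
// set.seed() makes whole runs reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

namespace {

struct Model {
  double L, V, lB;
  int nspecies;
  NumericVector z;            // charge number per species
  NumericMatrix sigma, lam, rcut, ushift; // per species pair
  IntegerMatrix bonds;        // nb x 2, 0-based
  double kbond, r0;
  bool exclude_bonded_wca;
  bool has_charges;
  double alpha;               // Ewald splitting parameter
  double ewald_rcut;          // real-space cutoff
  int nmax;                   // reciprocal-space |n| bound per axis
  std::unordered_set<long long> bonded_set;

  bool is_bonded(int i, int j) const {
    long long a = i < j ? i : j, b = i < j ? j : i;
    return bonded_set.count(a * 1000003LL + b) > 0;
  }
};

Model build_model(const List& m) {
  Model md;
  md.L = as<double>(m["L"]);
  md.V = md.L * md.L * md.L;
  md.lB = as<double>(m["lB"]);
  md.z = as<NumericVector>(m["z"]);
  md.nspecies = md.z.size();
  md.sigma = as<NumericMatrix>(m["sigma"]);
  md.lam = as<NumericMatrix>(m["lam"]);
  md.rcut = as<NumericMatrix>(m["rcut"]);
  md.ushift = as<NumericMatrix>(m["ushift"]);
  md.bonds = as<IntegerMatrix>(m["bonds"]);
  md.kbond = as<double>(m["kbond"]);
  md.r0 = as<double>(m["r0"]);
  md.exclude_bonded_wca = as<bool>(m["exclude_bonded_wca"]);
  md.alpha = as<double>(m["ewald_alpha"]);
  md.ewald_rcut = as<double>(m["ewald_rcut"]);
  md.nmax = as<int>(m["ewald_nmax"]);
  for (int b = 0; b < md.bonds.nrow(); ++b) {
    int i = md.bonds(b, 0), j = md.bonds(b, 1);
    long long a = i < j ? i : j, c = i < j ? j : i;
    md.bonded_set.insert(a * 1000003LL + c);
  }
  return md;
}

inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// lambda-WCA, truncated and shifted: repulsive core raised by (1-lambda)eps,
// attractive tail scaled by lambda, whole curve shifted to vanish at rcut.
inline double wca_u(double r, double sg, double lm, double rc, double ush) {
  if (r >= rc) return 0.0;
  double s2 = sg * sg / (r * r), s6 = s2 * s2 * s2, s12 = s6 * s6;
  double rmin = 1.122462048309373 * sg; // 2^(1/6) sigma
  double u = (r < rmin) ? 4.0 * (s12 - s6) + (1.0 - lm)
                        : lm * 4.0 * (s12 - s6);
  return u - ush;
}

// magnitude of -dU/dr divided by r (so F_vec = w * dr_vec)
inline double wca_w(double r, double sg, double lm, double rc) {
  if (r >= rc) return 0.0;
  double s2 = sg * sg / (r * r), s6 = s2 * s2 * s2, s12 = s6 * s6;
  double rmin = 1.122462048309373 * sg;
  double pref = (r < rmin) ? 1.0 : lm;
  return pref * 24.0 * (2.0 * s12 - s6) / (r * r);
}

struct EwaldWork {
  std::vector<double> kx, ky, kz, k2, Ak; // reciprocal vectors (full sphere)
};

void setup_kvecs(const Model& md, EwaldWork& ew) {
  ew.kx.clear(); ew.ky.clear(); ew.kz.clear(); ew.k2.clear(); ew.Ak.clear();
  double twopiL = 2.0 * M_PI / md.L;
  double kcut2 = std::pow(twopiL * md.nmax, 2) + 1e-12;
  for (int nx = -md.nmax; nx <= md.nmax; ++nx)
    for (int ny = -md.nmax; ny <= md.nmax; ++ny)
      for (int nz = -md.nmax; nz <= md.nmax; ++nz) {
        if (nx == 0 && ny == 0 && nz == 0) continue;
        double gx = twopiL * nx, gy = twopiL * ny, gz = twopiL * nz;
        double g2 = gx * gx + gy * gy + gz * gz;
        if (g2 > kcut2) continue;
        ew.kx.push_back(gx); ew.ky.push_back(gy); ew.kz.push_back(gz);
        ew.k2.push_back(g2);
        ew.Ak.push_back(std::exp(-g2 / (4.0 * md.alpha * md.alpha)) / g2);
      }
}

// Full energy breakdown; optionally accumulates forces and the virial trace.
struct EnergyResult {
  double bonded = 0, shortrange = 0, coul = 0;
  double w_sr = 0, w_bond = 0, w_coul = 0; // virial traces sum(r.F)
};

EnergyResult evaluate(const NumericMatrix& pos, const IntegerVector& spec,
                      const Model& md, const EwaldWork& ew,
                      NumericMatrix* forces, bool want_virial) {
  EnergyResult res;
  const int N = pos.nrow();
  std::vector<double> q(N);
  bool any_q = false;
  for (int i = 0; i < N; ++i) {
    q[i] = md.z[spec[i]];
    if (q[i] != 0.0) any_q = true;
  }

  // short-range pairs + real-space Ewald (all pairs, minimum image)
  double sqrtpi = std::sqrt(M_PI);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = min_image(pos(i, 0) - pos(j, 0), md.L);
      double dy = min_image(pos(i, 1) - pos(j, 1), md.L);
      double dz = min_image(pos(i, 2) - pos(j, 2), md.L);
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      int si = spec[i], sj = spec[j];
      bool skip_wca = md.exclude_bonded_wca && md.is_bonded(i, j);
      if (!skip_wca && r < md.rcut(si, sj)) {
        res.shortrange += wca_u(r, md.sigma(si, sj), md.lam(si, sj),
                                md.rcut(si, sj), md.ushift(si, sj));
        double w = wca_w(r, md.sigma(si, sj), md.lam(si, sj), md.rcut(si, sj));
        if (want_virial) res.w_sr += w * r2;
        if (forces) {
          (*forces)(i, 0) += w * dx; (*forces)(i, 1) += w * dy; (*forces)(i, 2) += w * dz;
          (*forces)(j, 0) -= w * dx; (*forces)(j, 1) -= w * dy; (*forces)(j, 2) -= w * dz;
        }
      }
      if (any_q && q[i] != 0.0 && q[j] != 0.0 && r < md.ewald_rcut) {
        double qq = q[i] * q[j] * md.lB;
        double er = std::erfc(md.alpha * r);
        res.coul += qq * er / r;
        double w = qq * (er / r + 2.0 * md.alpha / sqrtpi *
                         std::exp(-md.alpha * md.alpha * r2)) / r2;
        if (want_virial) res.w_coul += w * r2;
        if (forces) {
          (*forces)(i, 0) += w * dx; (*forces)(i, 1) += w * dy; (*forces)(i, 2) += w * dz;
          (*forces)(j, 0) -= w * dx; (*forces)(j, 1) -= w * dy; (*forces)(j, 2) -= w * dz;
        }
      }
    }
  }

  // bonds
  for (int b = 0; b < md.bonds.nrow(); ++b) {
    int i = md.bonds(b, 0), j = md.bonds(b, 1);
    double dx = min_image(pos(i, 0) - pos(j, 0), md.L);
    double dy = min_image(pos(i, 1) - pos(j, 1), md.L);
    double dz = min_image(pos(i, 2) - pos(j, 2), md.L);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - md.r0;
    res.bonded += 0.5 * md.kbond * d * d;
    double w = -md.kbond * d / r; // F = -k (r - r0) rhat
    if (want_virial) res.w_bond += w * r * r;
    if (forces) {
      (*forces)(i, 0) += w * dx; (*forces)(i, 1) += w * dy; (*forces)(i, 2) += w * dz;
      (*forces)(j, 0) -= w * dx; (*forces)(j, 1) -= w * dy; (*forces)(j, 2) -= w * dz;
    }
  }

  // reciprocal-space Ewald + self term (tinfoil boundary, no dipole term)
  if (any_q) {
    const int nk = (int)ew.kx.size();
    double pref = 2.0 * M_PI * md.lB / md.V;
    double erec = 0.0, wrec = 0.0;
    for (int kk = 0; kk < nk; ++kk) {
      double re = 0.0, im = 0.0;
      for (int i = 0; i < N; ++i) {
        if (q[i] == 0.0) continue;
        double th = ew.kx[kk] * pos(i, 0) + ew.ky[kk] * pos(i, 1) +
                    ew.kz[kk] * pos(i, 2);
        re += q[i] * std::cos(th);
        im += q[i] * std::sin(th);
      }
      double Ek = pref * ew.Ak[kk] * (re * re + im * im);
      erec += Ek;
      if (want_virial)
        wrec += Ek * (1.0 - ew.k2[kk] / (2.0 * md.alpha * md.alpha));
      if (forces) {
        double fpref = 2.0 * pref * ew.Ak[kk];
        for (int i = 0; i < N; ++i) {
          if (q[i] == 0.0) continue;
          double th = ew.kx[kk] * pos(i, 0) + ew.ky[kk] * pos(i, 1) +
                      ew.kz[kk] * pos(i, 2);
          // F_i = -dE/dr_i = 2 pref Ak q_i k (sin(th) Re S - cos(th) Im S)
          double g = fpref * q[i] * (std::sin(th) * re - std::cos(th) * im);
          (*forces)(i, 0) += g * ew.kx[kk];
          (*forces)(i, 1) += g * ew.ky[kk];
          (*forces)(i, 2) += g * ew.kz[kk];
        }
      }
    }
    double self = 0.0;
    for (int i = 0; i < N; ++i) self += q[i] * q[i];
    res.coul += erec - md.lB * md.alpha / sqrtpi * self;
    // reciprocal virial trace: sum_k E_k (1 - k^2/(2 alpha^2)) == wrec;
    // real-space and self terms were handled above (self has no virial)
    res.w_coul += wrec;
  }
  return res;
}

} // namespace

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, IntegerVector spec, List model) {
  Model md = build_model(model);
  EwaldWork ew;
  setup_kvecs(md, ew);
  EnergyResult r = evaluate(pos, spec, md, ew, nullptr, false);
  return List::create(_["bonded"] = r.bonded, _["short_range"] = r.shortrange,
                      _["electrostatic"] = r.coul,
                      _["total"] = r.bonded + r.shortrange + r.coul);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector spec, List model) {
  Model md = build_model(model);
  EwaldWork ew;
  setup_kvecs(md, ew);
  NumericMatrix f(pos.nrow(), 3);
  evaluate(pos, spec, md, ew, &f, false);
  return f;
}

// [[Rcpp::export]]
List cpp_pressure(NumericMatrix pos, IntegerVector spec, List model) {
  Model md = build_model(model);
  EwaldWork ew;
  setup_kvecs(md, ew);
  EnergyResult r = evaluate(pos, spec, md, ew, nullptr, true);
  double N = pos.nrow();
  double ideal = N / md.V; // kBT = 1
  double p = ideal + (r.w_sr + r.w_bond + r.w_coul) / (3.0 * md.V);
  return List::create(_["total"] = p, _["ideal"] = ideal,
                      _["virial_short_range"] = r.w_sr / (3.0 * md.V),
                      _["virial_bonded"] = r.w_bond / (3.0 * md.V),
                      _["virial_electrostatic"] = r.w_coul / (3.0 * md.V));
}

// BAOAB splitting of the Langevin equation; gamma = 0 with no noise reduces
// to velocity Verlet. Positions evolve unwrapped.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos_, NumericMatrix vel_,
                      IntegerVector spec, List model, double dt, double gamma,
                      int nsteps, int sample_every, bool with_noise,
                      bool sample_pressure) {
  Model md = build_model(model);
  EwaldWork ew;
  setup_kvecs(md, ew);
  NumericMatrix pos = clone(pos_), vel = clone(vel_);
  const int N = pos.nrow();
  double c1 = std::exp(-gamma * dt);
  double c2 = with_noise ? std::sqrt(1.0 - c1 * c1) : 0.0; // kBT = m = 1

  NumericMatrix f(N, 3);
  evaluate(pos, spec, md, ew, &f, false);

  int nsamp = sample_every > 0 ? nsteps / sample_every : 0;
  List frames(nsamp);
  NumericMatrix energies(nsamp, 4); // bonded, short_range, electrostatic, kinetic
  NumericVector pressures(nsamp), times(nsamp);
  int isamp = 0;

  for (int step = 1; step <= nsteps; ++step) {
    // B: half kick
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) vel(i, d) += 0.5 * dt * f(i, d);
    // A: half drift
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) pos(i, d) += 0.5 * dt * vel(i, d);
    // O: friction + noise
    if (gamma > 0.0) {
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          vel(i, d) = c1 * vel(i, d) + c2 * norm_rand();
    }
    // A: half drift
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) pos(i, d) += 0.5 * dt * vel(i, d);
    // recompute forces, then B: half kick
    std::fill(f.begin(), f.end(), 0.0);
    EnergyResult er = evaluate(pos, spec, md, ew, &f,
                               sample_pressure && sample_every > 0 &&
                                   step % sample_every == 0);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) {
        if (!std::isfinite(f(i, d)))
          stop("force overflow on particle %d (likely hard overlap)", i + 1);
        vel(i, d) += 0.5 * dt * f(i, d);
      }

    if (sample_every > 0 && step % sample_every == 0) {
      double ekin = 0.0;
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d) ekin += 0.5 * vel(i, d) * vel(i, d);
      energies(isamp, 0) = er.bonded;
      energies(isamp, 1) = er.shortrange;
      energies(isamp, 2) = er.coul;
      energies(isamp, 3) = ekin;
      if (sample_pressure)
        pressures[isamp] = N / md.V +
                           (er.w_sr + er.w_bond + er.w_coul) / (3.0 * md.V);
      times[isamp] = step * dt;
      frames[isamp] = clone(pos);
      ++isamp;
    }
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["frames"] = frames,
                      _["energies"] = energies, _["pressures"] = pressures,
                      _["times"] = times);
}

// Spherically resolved static structure factor over the discrete box modes.
// Returns |k| and S(k) for every lattice vector in the positive half-space
// with |n| <= nmax; binning into shells is done on the R side.
// [[Rcpp::export]]
List cpp_structure_factor(List frames, IntegerVector sel0, double L,
                          int nmax) {
  std::vector<double> kx, ky, kz;
  double twopiL = 2.0 * M_PI / L;
  for (int nx = 0; nx <= nmax; ++nx)
    for (int ny = (nx == 0 ? 0 : -nmax); ny <= nmax; ++ny)
      for (int nz = (nx == 0 && ny == 0 ? 1 : -nmax); nz <= nmax; ++nz) {
        kx.push_back(twopiL * nx);
        ky.push_back(twopiL * ny);
        kz.push_back(twopiL * nz);
      }
  const int nk = (int)kx.size();
  NumericVector kmag(nk), S(nk);
  const int nf = frames.size();
  const int ns = sel0.size();
  for (int kk = 0; kk < nk; ++kk)
    kmag[kk] = std::sqrt(kx[kk] * kx[kk] + ky[kk] * ky[kk] + kz[kk] * kz[kk]);
  for (int fidx = 0; fidx < nf; ++fidx) {
    NumericMatrix pos = frames[fidx];
    for (int kk = 0; kk < nk; ++kk) {
      double re = 0.0, im = 0.0;
      for (int a = 0; a < ns; ++a) {
        int i = sel0[a];
        double th = kx[kk] * pos(i, 0) + ky[kk] * pos(i, 1) +
                    kz[kk] * pos(i, 2);
        re += std::cos(th);
        im += std::sin(th);
      }
      S[kk] += (re * re + im * im) / ns;
    }
  }
  for (int kk = 0; kk < nk; ++kk) S[kk] /= nf;
  return List::create(_["k"] = kmag, _["S"] = S);
}
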