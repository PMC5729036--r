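// Path-integral Monte Carlo core for the quantum-instanton machinery.
//
// One-dimensional paths, staging (free-particle bridge) resampling of
// bead segments, Metropolis acceptance on the potential part of the
// action.  Two topologies:
//   * pinned ring: beads 0 and P/2 frozen on the two dividing surfaces
//     (delta-delta / flux-flux constrained ensembles),
//   * closed ring: all beads free plus whole-chain translation moves
//     (reactant partition-function estimators for bound systems).
// Factorizations: Lie-Trotter (w_i = 1) and Suzuki-Chin (w = 4/3 on odd
// beads, 2/3 on even beads, gradient term eps^3 V'^2 / (9 m) on odd
// beads; pinned beads must be even, i.e. P divisible by 4).
//
// The RNG is a fully specified xorshift-based generator so that a given
// seed reproduces bit-identical streams on every platform.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {  // splitmix64
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {  // Box-Muller, one draw per call (cache the pair)
    if (have) { have = false; return cached; }
    double u1 = 0.0, u2;
    while (u1 <= 1e-300) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    have = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  bool have = false;
  double cached = 0.0;
};

struct Pot {
  int code;
  double p1, p2;
  double lambda;  // potential scaling for thermodynamic integration
  double V(double x) const {
    double v;
    switch (code) {
      case 0: v = 0.0; break;
      case 1: {  // Eckart: p1 = V0, p2 = a
        double c = std::cosh(x / p2);
        v = p1 / (c * c);
        break;
      }
      case 2: {  // harmonic: p1 = m w^2, p2 = center
        double d = x - p2;
        v = 0.5 * p1 * d * d;
        break;
      }
      case 3: {  // quartic double well: p1 = barrier, p2 = x0
        double u = x * x - p2 * p2;
        v = p1 * u * u / (p2 * p2 * p2 * p2);
        break;
      }
      default: stop("unknown potential code");
    }
    return lambda * v;
  }
  double dV(double x) const {
    double g;
    switch (code) {
      case 0: g = 0.0; break;
      case 1: {
        double c = std::cosh(x / p2), t = std::tanh(x / p2);
        g = -2.0 * p1 / p2 * t / (c * c);
        break;
      }
      case 2: g = p1 * (x - p2); break;
      case 3: g = 4.0 * p1 * x * (x * x - p2 * p2) /
                  (p2 * p2 * p2 * p2); break;
      default: stop("unknown potential code");
    }
    return lambda * g;
  }
};

// effective potential action of bead i (weight * eps * V + SC gradient)
inline double bead_U(const Pot& pot, double x, int i, double eps,
                     double m, bool sc) {
  if (!sc) return eps * pot.V(x);
  double w = (i % 2 == 1) ? 4.0 / 3.0 : 2.0 / 3.0;
  double u = w * eps * pot.V(x);
  if (i % 2 == 1) {
    double g = pot.dV(x);
    u += eps * eps * eps * g * g / (9.0 * m);
  }
  return u;
}

// staging resample of beads (l+1 .. l+j) between fixed x[l] and x[l+j+1]
// (indices taken modulo P for the closed topology)
inline bool stage_move(std::vector<double>& x, int P, int l, int j,
                       double m, double eps, const Pot& pot, bool sc,
                       Rng& rng, std::vector<double>& prop) {
  double dUold = 0.0, dUnew = 0.0;
  int iend = l + j + 1;
  double xl = x[l % P];
  double xr = x[iend % P];
  prop.resize(j);
  double xprev = xl;
  for (int k = 1; k <= j; ++k) {
    int nleft = j - k + 1;  // segments remaining to the right end
    double mean = (nleft * xprev + xr) / (nleft + 1.0);
    double var = eps * nleft / (m * (nleft + 1.0));
    double xi = mean + std::sqrt(var) * rng.norm();
    prop[k - 1] = xi;
    xprev = xi;
  }
  for (int k = 1; k <= j; ++k) {
    int idx = (l + k) % P;
    dUold += bead_U(pot, x[idx], idx, eps, m, sc);
    dUnew += bead_U(pot, prop[k - 1], idx, eps, m, sc);
  }
  if (dUnew <= dUold || rng.unif() < std::exp(dUold - dUnew)) {
    for (int k = 1; k <= j; ++k) x[(l + k) % P] = prop[k - 1];
    return true;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
List pimc_core(int pot_code, NumericVector pot_params, double lambda,
               int P, double beta, double m, bool pinned, double xa,
               double xb, int nsweep, int nburn, int seg, double seed,
               bool suzuki_chin, bool tune) {
  if (P < 4) stop("P must be >= 4");
  if (pinned && P % 2 != 0) stop("pinned topology needs even P");
  if (suzuki_chin && P % 2 != 0) stop("suzuki-chin needs even P");
  if (suzuki_chin && pinned && P % 4 != 0)
    stop("suzuki-chin with pinned beads needs P divisible by 4");
  Pot pot{pot_code, pot_params[0],
          pot_params.size() > 1 ? pot_params[1] : 0.0, lambda};
  double eps = beta / P;
  Rng rng(static_cast<uint64_t>(seed));

  std::vector<double> x(P);
  int half = P / 2;
  if (pinned) {
    for (int i = 0; i < P; ++i) {
      double f = (i <= half) ? static_cast<double>(i) / half
                             : static_cast<double>(P - i) / half;
      x[i] = xa + f * (xb - xa) + 0.05 * rng.norm();
    }
    x[0] = xa;
    x[half] = xb;
  } else {
    for (int i = 0; i < P; ++i) x[i] = xa + 0.05 * rng.norm();
  }

  std::vector<double> prop;
  long acc = 0, tries = 0;
  int j = std::min(seg, pinned ? half - 1 : P - 1);
  if (j < 1) j = 1;

  auto sweep_once = [&](bool count) {
    if (pinned) {
      // cover each half with consecutive segments of <= j interior beads
      for (int h = 0; h < 2; ++h) {
        int start = h * half;  // pinned bead of this half
        int free_beads = half - 1;
        int pos = 0;
        while (pos < free_beads) {
          int jj = std::min(j, free_beads - pos);
          // segment interior beads start+pos+1 .. start+pos+jj; right
          // anchor is start+pos+jj+1 unless that exceeds the half pin
          int l = start + pos;
          if (l + jj + 1 > start + half) jj = start + half - l - 1;
          if (jj < 1) break;
          bool ok = stage_move(x, P, l, jj, m, eps, pot, suzuki_chin,
                               rng, prop);
          if (count) { acc += ok; ++tries; }
          pos += jj;
        }
      }
    } else {
      int nseg = (P + j - 1) / j;
      for (int s = 0; s < nseg; ++s) {
        int l = static_cast<int>(rng.unif() * P);
        bool ok = stage_move(x, P, l, j, m, eps, pot, suzuki_chin, rng,
                             prop);
        if (count) { acc += ok; ++tries; }
      }
      // whole-chain translation
      double dx = 0.5 * std::sqrt(eps / m) * rng.norm();
      double dU = 0.0;
      for (int i = 0; i < P; ++i)
        dU += bead_U(pot, x[i] + dx, i, eps, m, suzuki_chin) -
              bead_U(pot, x[i], i, eps, m, suzuki_chin);
      if (dU <= 0 || rng.unif() < std::exp(-dU))
        for (int i = 0; i < P; ++i) x[i] += dx;
    }
  };

  // burn-in with optional segment-length tuning
  int chunk = std::max(nburn / 10, 1);
  for (int b = 0; b < nburn; ++b) {
    sweep_once(true);
    if (tune && (b + 1) % chunk == 0 && tries > 0) {
      double ar = static_cast<double>(acc) / tries;
      if (ar < 0.3 && j > 1) j = std::max(1, j / 2);
      else if (ar > 0.7) j = std::min(pinned ? half - 1 : P - 1, j * 2);
      acc = 0; tries = 0;
    }
  }
  acc = 0; tries = 0;

  // production: per-sweep estimator accumulation
  NumericMatrix out(nsweep, 11);
  colnames(out) = CharacterVector::create(
      "spr1", "spr2", "sv1", "sv2", "vprod", "sumV", "sumUw", "vir",
      "gpin", "x2", "sumG");
  for (int swp = 0; swp < nsweep; ++swp) {
    sweep_once(true);
    double spr1 = 0, spr2 = 0, sv1 = 0, sv2 = 0, sumV = 0, sumUw = 0,
           vir = 0, x2 = 0, sumG = 0;
    double cent = 0;
    if (!pinned) {
      for (int i = 0; i < P; ++i) cent += x[i];
      cent /= P;
    }
    for (int i = 0; i < P; ++i) {
      int in = (i + 1) % P;
      double d = x[in] - x[i];
      double sp = m * d * d;  // m (dx)^2 ; spring energy = sp / (2 eps^2)
      if (pinned && i >= half) spr2 += sp; else if (pinned) spr1 += sp;
      else spr1 += sp;
      double v = pot.V(x[i]);
      sumV += v;
      sumUw += bead_U(pot, x[i], i, eps, m, suzuki_chin);
      if (suzuki_chin && i % 2 == 1) {
        double g = pot.dV(x[i]);
        sumG += eps * eps * eps * g * g / (9.0 * m);
      }
      if (pinned) {
        // trapezoid half sums: ends (pins) weight 1/2 within each half
        double w1 = (i == 0 || i == half) ? 0.5 : ((i < half) ? 1.0 : 0.0);
        double w2 = (i == 0 || i == half) ? 0.5 : ((i > half) ? 1.0 : 0.0);
        sv1 += w1 * v;
        sv2 += w2 * v;
        // virial reference: linear interpolation between the pins
        double f = (i <= half) ? static_cast<double>(i) / half
                               : static_cast<double>(P - i) / half;
        double r = xa + f * (xb - xa);
        vir += pot.dV(x[i]) * (x[i] - r);
      } else {
        vir += pot.dV(x[i]) * (x[i] - cent);
      }
      double dc = x[i] - (pinned ? 0.0 : cent);
      x2 += dc * dc;
    }
    double vprod = 0, gpin = 0;
    if (pinned) {
      vprod = (x[P - 1] - x[1]) * (x[half - 1] - x[half + 1]);
      // d/dxi of the symmetric stretch (xa, xb) = (-xi, +xi):
      // dU/dxb - dU/dxa with U the full pinned action
      double dUb = m * (2 * xb - x[half - 1] - x[half + 1]) / eps +
                   eps * pot.dV(xb);
      double dUa = m * (2 * xa - x[1] - x[P - 1]) / eps +
                   eps * pot.dV(xa);
      gpin = -(dUb - dUa);  // = d ln Cdd / d xi for symmetric stretch
    }
    out(swp, 0) = spr1; out(swp, 1) = spr2; out(swp, 2) = sv1;
    out(swp, 3) = sv2; out(swp, 4) = vprod; out(swp, 5) = sumV;
    out(swp, 6) = sumUw; out(swp, 7) = vir; out(swp, 8) = gpin;
    out(swp, 9) = x2; out(swp, 10) = sumG;
  }
  double ar = tries > 0 ? static_cast<double>(acc) / tries : NA_REAL;
  return List::create(_["samples"] = out, _["acceptance"] = ar,
                      _["seg"] = j, _["eps"] = eps, _["P"] = P,
                      _["final"] = NumericVector(x.begin(), x.end()));
}
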