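// Exact stochastic simulation (Gillespie direct method) of the two-enzyme
// pathway gene-expression network with growth-rate feedback: dilution and
// transcription propensities carry the factor f_tox(I) * f_gr(P), so the
// instantaneous growth state of the cell feeds back on every
// growth-coupled channel.  Propensities are re-evaluated after every event.
//
// The generator is a self-contained xoshiro256+ stream seeded per
// trajectory via splitmix64, so ensembles are reproducible independently
// of R's RNG state and of trajectory execution order.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1): 53-bit mantissa, never exactly 0
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// species indices
enum { iMA, iMB, iA, iB, iAS, iBI, iI, iP, iGA, iGAon, iGB, iGBon, NSPEC };

struct Pars {
  double ktA, ktB, kmdeg, ktsn, kg, kgon, kgoff;
  double kim, km1, kcat1, k2, km2, kcat2, ku;
  double omega, theta, delta, hill;
  bool benefit_mm;   // false: piecewise-linear min(P/(omega*delta), 1)
  double fgr_floor;  // floor on f_gr (0 by default)
  double inv_otheta, inv_odelta;  // precomputed 1/(omega*theta|delta)
};

inline double f_tox(const double* x, const Pars& p) {
  double r = x[iI] * p.inv_otheta;
  if (p.hill == 1.0) return 1.0 / (1.0 + r);
  return 1.0 / (1.0 + std::pow(r, p.hill));
}

inline double f_gr(const double* x, const Pars& p) {
  double r = x[iP] * p.inv_odelta;
  double f = p.benefit_mm ? r / (1.0 + r) : (r < 1.0 ? r : 1.0);
  return f > p.fgr_floor ? f : p.fgr_floor;
}

const int NCHAN = 22;

inline void propensities(const double* x, const Pars& p, double f,
                         double* a) {
  a[0]  = p.ktA * f * x[iGAon];          // -> mA
  a[1]  = p.ktB * f * x[iGBon];          // -> mB
  a[2]  = p.kmdeg * x[iMA];              // mA decay
  a[3]  = p.kmdeg * x[iMB];              // mB decay
  a[4]  = p.ktsn * x[iMA];               // -> A
  a[5]  = p.ktsn * x[iMB];               // -> B
  a[6]  = p.kg * f * x[iA];              // A dilution
  a[7]  = p.kg * f * x[iB];              // B dilution
  a[8]  = p.kgon * x[iGA];               // gene A on
  a[9]  = p.kgoff * x[iGAon];            // gene A off
  a[10] = p.kgon * x[iGB];               // gene B on
  a[11] = p.kgoff * x[iGBon];            // gene B off
  a[12] = p.kim * x[iA];                 // A + S -> A.S
  a[13] = p.km1 * x[iAS];                // A.S -> A + S
  a[14] = p.kcat1 * x[iAS];              // A.S -> A + I
  a[15] = (p.k2 / p.omega) * x[iB] * x[iI]; // B + I -> B.I
  a[16] = p.km2 * x[iBI];                // B.I -> B + I
  a[17] = p.kcat2 * x[iBI];              // B.I -> B + P
  a[18] = p.kg * f * x[iAS];             // A.S dilution
  a[19] = p.kg * f * x[iBI];             // B.I dilution
  a[20] = p.kg * f * x[iI];              // I dilution
  a[21] = p.ku * x[iP];                  // P -> 0 (demand)
}

inline void apply(int ch, double* x) {
  switch (ch) {
    case 0:  x[iMA] += 1; break;
    case 1:  x[iMB] += 1; break;
    case 2:  x[iMA] -= 1; break;
    case 3:  x[iMB] -= 1; break;
    case 4:  x[iA] += 1; break;
    case 5:  x[iB] += 1; break;
    case 6:  x[iA] -= 1; break;
    case 7:  x[iB] -= 1; break;
    case 8:  x[iGA] -= 1; x[iGAon] += 1; break;
    case 9:  x[iGAon] -= 1; x[iGA] += 1; break;
    case 10: x[iGB] -= 1; x[iGBon] += 1; break;
    case 11: x[iGBon] -= 1; x[iGB] += 1; break;
    case 12: x[iA] -= 1; x[iAS] += 1; break;
    case 13: x[iAS] -= 1; x[iA] += 1; break;
    case 14: x[iAS] -= 1; x[iA] += 1; x[iI] += 1; break;
    case 15: x[iB] -= 1; x[iI] -= 1; x[iBI] += 1; break;
    case 16: x[iBI] -= 1; x[iB] += 1; x[iI] += 1; break;
    case 17: x[iBI] -= 1; x[iB] += 1; x[iP] += 1; break;
    case 18: x[iAS] -= 1; break;
    case 19: x[iBI] -= 1; break;
    case 20: x[iI] -= 1; break;
    case 21: x[iP] -= 1; break;
  }
}

Pars unpack(const List& spec) {
  Pars p;
  p.ktA = spec["k_tA"]; p.ktB = spec["k_tB"];
  p.kmdeg = spec["k_mdeg"]; p.ktsn = spec["k_tsn"];
  p.kg = spec["k_g"]; p.kgon = spec["k_gon"]; p.kgoff = spec["k_goff"];
  p.kim = spec["k_im"]; p.km1 = spec["k_minus1"]; p.kcat1 = spec["k_cat1"];
  p.k2 = spec["k_2"]; p.km2 = spec["k_minus2"]; p.kcat2 = spec["k_cat2"];
  p.ku = spec["k_u"];
  p.omega = spec["omega"]; p.theta = spec["theta"]; p.delta = spec["delta"];
  p.hill = spec["hill_tox"];
  std::string bf = as<std::string>(spec["benefit_form"]);
  p.benefit_mm = (bf == "michaelis_menten");
  p.fgr_floor = spec["fgr_floor"];
  p.inv_otheta = 1.0 / (p.omega * p.theta);
  p.inv_odelta = 1.0 / (p.omega * p.delta);
  return p;
}

}  // namespace

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(List spec, NumericVector init, double t_end,
             double sample_dt, NumericVector seeds,
             double arrest_epsilon, bool keep_samples) {
  const Pars p = unpack(spec);
  const int ntraj = seeds.size();
  if (init.size() != NSPEC) stop("init must have %d species", NSPEC);
  const int nsamp = (int)std::floor(t_end / sample_dt) + 1;

  NumericMatrix avg(ntraj, NSPEC), fin(ntraj, NSPEC);
  NumericVector growth_avg(ntraj), growth_final(ntraj);
  IntegerVector arrest(ntraj);
  NumericVector nevents(ntraj);
  NumericMatrix samp_growth, samp_I;
  if (keep_samples) {
    samp_growth = NumericMatrix(ntraj, nsamp);
    samp_I = NumericMatrix(ntraj, nsamp);
  }

  for (int tr = 0; tr < ntraj; ++tr) {
    Xoshiro rng((uint64_t)(int64_t)seeds[tr]);
    double x[NSPEC];
    for (int i = 0; i < NSPEC; ++i) {
      x[i] = init[i];
      if (x[i] < 0) stop("negative initial count");
    }
    double t = 0.0, next_sample = 0.0;
    int isamp = 0;
    double acc[NSPEC] = {0.0};
    double acc_growth = 0.0;
    double a[NCHAN];
    double ev = 0.0;

    while (t < t_end) {
      const double f = f_tox(x, p) * f_gr(x, p);
      const double g_inst = p.kg * f;
      propensities(x, p, f, a);
      double a0 = 0.0;
      for (int i = 0; i < NCHAN; ++i) a0 += a[i];
      // propensities are products of nonnegative constants and counts, so
      // negativity or overflow can only follow from state corruption; a
      // single check on the total catches both
      if (!(a0 >= 0.0) || !std::isfinite(a0)) {
        for (int i = 0; i < NCHAN; ++i) {
          if (a[i] < 0 || !std::isfinite(a[i]))
            stop("invalid propensity in channel %d", i + 1);
        }
        stop("invalid total propensity");
      }
      double tau = (a0 > 0.0) ? -std::log(rng.unif()) / a0 : (t_end - t) + 1.0;
      double t_next = t + tau;
      if (t_next > t_end) t_next = t_end;

      // fill sample grid within [t, t_next)
      while (keep_samples && isamp < nsamp &&
             next_sample < t_next - 1e-12) {
        samp_growth(tr, isamp) = g_inst;
        samp_I(tr, isamp) = x[iI];
        ++isamp;
        next_sample = isamp * sample_dt;
      }
      // exact time-weighted accumulation
      const double dt = t_next - t;
      for (int i = 0; i < NSPEC; ++i) acc[i] += x[i] * dt;
      acc_growth += g_inst * dt;

      t = t_next;
      if (t >= t_end || a0 <= 0.0) {
        if (a0 <= 0.0 && t < t_end) {
          // frozen state: pad averages and samples to t_end
          const double rest = t_end - t;
          for (int i = 0; i < NSPEC; ++i) acc[i] += x[i] * rest;
          acc_growth += g_inst * rest;
          t = t_end;
        }
        break;
      }
      // pick channel
      double r = rng.unif() * a0;
      int ch = 0;
      double c = a[0];
      while (r > c && ch < NCHAN - 1) c += a[++ch];
      apply(ch, x);
      ev += 1.0;
    }
    // trailing samples at the final (frozen or end-of-run) state
    const double f_end = f_tox(x, p) * f_gr(x, p);
    const double g_end = p.kg * f_end;
    while (keep_samples && isamp < nsamp) {
      samp_growth(tr, isamp) = g_end;
      samp_I(tr, isamp) = x[iI];
      ++isamp;
      next_sample = isamp * sample_dt;
    }
    for (int i = 0; i < NSPEC; ++i) {
      avg(tr, i) = acc[i] / t_end;
      fin(tr, i) = x[i];
    }
    growth_avg[tr] = acc_growth / t_end;
    growth_final[tr] = g_end;
    // toxic growth arrest: growth stalled AND the intermediate has crossed
    // the toxicity threshold (distinguishes arrest from starvation)
    arrest[tr] = (g_end < arrest_epsilon * p.kg &&
                  x[iI] > p.theta * p.omega) ? 1 : 0;
    nevents[tr] = ev;
  }

  CharacterVector nm = CharacterVector::create(
    "mA", "mB", "A", "B", "AS", "BI", "I", "P",
    "gA", "gA_on", "gB", "gB_on");
  colnames(avg) = nm;
  colnames(fin) = nm;
  List out = List::create(
    _["avg"] = avg, _["final"] = fin,
    _["growth_avg"] = growth_avg, _["growth_final"] = growth_final,
    _["arrest"] = arrest, _["n_events"] = nevents,
    _["sample_dt"] = sample_dt, _["n_samples"] = nsamp);
  if (keep_samples) {
    out["samp_growth"] = samp_growth;
    out["samp_I"] = samp_I;
  }
  return out;
}
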