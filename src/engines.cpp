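// Compiled kernels: banded storage propagator tables for the
// Chapman-Kolmogorov solver, the exact Gillespie simulation of the full
// four-variable model (r, u, s, h), and a receptor-equilibrated hybrid
// jump simulator used for the neural mapping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// xoshiro256++ with splitmix64 seeding: one independent, reproducible
// stream per trajectory derived from (seed, trajectory index).

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0xD2B74407B1CE6E93ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

static inline double logadd(double a, double b) {
  double m = a > b ? a : b;
  return m + std::log1p(std::exp((a < b ? a : b) - m));
}

// ---------------------------------------------------------------------------
// Banded storage propagator: for every frozen readout value u (through its
// birth rate b[u]) and every initial state s0, the law after dt restricted
// to the n nearest neighbors of s0 (generator diagonal = -column sums so
// the restricted chain conserves probability).  Band k of the returned
// list holds P(s0 -> s0 + k | u) as an (len(b) x (NS+1)) matrix.

// [[Rcpp::export(name = "hab_prop_bands")]]
List hab_prop_bands(NumericVector b_of_u, int NS, double GammaS0, double dt,
                    int n) {
  const int nu = b_of_u.size(), ns = NS + 1, nb = 2 * n + 1;
  List bands(nb);
  std::vector<NumericMatrix> B;
  for (int k = 0; k < nb; ++k) B.push_back(NumericMatrix(nu, ns));

  for (int s0 = 0; s0 <= NS; ++s0) {
    int lo = std::max(0, s0 - n), hi = std::min(NS, s0 + n);
    int m = hi - lo + 1, idx0 = s0 - lo;
    arma::mat G(m, m, arma::fill::zeros);
    for (int i = 0; i < m; ++i) {
      int st = lo + i;
      if (i > 0) G(i - 1, i) = st * GammaS0;          // death
    }
    for (int iu = 0; iu < nu; ++iu) {
      double b = b_of_u[iu];
      for (int i = 0; i < m; ++i) {
        int st = lo + i;
        if (i + 1 < m && st < NS) G(i + 1, i) = b;    // birth
      }
      for (int j = 0; j < m; ++j) {
        double col = 0;
        for (int i = 0; i < m; ++i) if (i != j) col += G(i, j);
        G(j, j) = -col;
      }
      arma::mat P = arma::expmat(G * dt);
      for (int i = 0; i < m; ++i) {
        int k = (lo + i) - s0;  // jump size
        B[k + n](iu, s0) = P(i, idx0);
      }
    }
  }
  for (int k = 0; k < nb; ++k) bands[k] = B[k];
  return bands;
}

// ---------------------------------------------------------------------------
// Protocol helper: mean signal of the square wave at time t (background
// H_min outside the stimulus windows [t_k, t_k + Ts)).

struct Proto {
  double Hmin, Hmax, Ts, DT, t_start;
  int n_stim;
  double mean_at(double t) const {
    double rel = t - t_start, period = Ts + DT;
    if (rel < 0) return Hmin;
    double k = std::floor(rel / period);
    if (k >= n_stim) return Hmin;
    return (rel - k * period) < Ts ? Hmax : Hmin;
  }
  // next time > t at which the mean changes
  double next_switch(double t) const {
    double period = Ts + DT;
    if (t < t_start) return t_start;
    double rel = t - t_start;
    double k = std::floor(rel / period);
    if (k >= n_stim) return std::numeric_limits<double>::infinity();
    double in = rel - k * period;
    double nxt = (in < Ts) ? (t_start + k * period + Ts)
                           : (t_start + (k + 1) * period);
    if (nxt > t + 1e-12) {
      // the (k+1)-th onset only exists for k+1 < n_stim
      if (in >= Ts && k + 1 >= n_stim)
        return std::numeric_limits<double>::infinity();
      return nxt;
    }
    return std::numeric_limits<double>::infinity();
  }
};

static Proto proto_from_list(List pr) {
  Proto p;
  p.Hmin = pr["H_min"]; p.Hmax = pr["H_max"]; p.Ts = pr["T_s"];
  p.DT = pr["Delta_T"]; p.t_start = pr["t_start"];
  p.n_stim = as<int>(pr["n_stimuli"]);
  return p;
}

// ---------------------------------------------------------------------------
// Exact SSA of the full model.  Events: receptor flips along either
// pathway, readout birth/death, storage birth/death, and signal redraws
// (exponential waiting times of mean tau_H, plus forced redraws at every
// protocol switch).  Rates are piecewise constant between events given the
// state, so the simulation is exact.

// [[Rcpp::export(name = "hab_ssa")]]
List hab_ssa(List params, List protocol, int n_traj, double seed,
             NumericVector sample_times, IntegerVector r0, IntegerVector u0,
             IntegerVector s0, double burn_in) {
  const double beta = params["beta"], sigma = params["sigma"],
               DeltaE = params["DeltaE"], g = params["g"],
               kappa = params["kappa"], V = params["V"], cc = params["c"],
               tauU = params["tau_U"], tauR = params["tau_R"],
               tauS = params["tau_S"], tauH = params["tau_H"];
  const int NS = params["N_S"];
  Proto pr = proto_from_list(protocol);
  const int nt = sample_times.size();
  NumericMatrix R(n_traj, nt), U(n_traj, nt), S(n_traj, nt), H(n_traj, nt),
                SB(n_traj, nt), SD(n_traj, nt);

  const double uBp = std::exp(-beta * V) / tauU;          // passive birth
  const double uBa = std::exp(-beta * (V - cc)) / tauU;   // active birth
  const double esig = std::exp(-beta * sigma) / tauS;
  const double fb_step = beta * kappa * sigma / NS;
  const double intPA = std::exp(-beta * DeltaE) / (g * tauR);

  for (int traj = 0; traj < n_traj; ++traj) {
    Xoshiro rng((uint64_t)seed, (uint64_t)traj);
    int r = r0[traj % r0.size()];
    long u = u0[traj % u0.size()];
    int s = s0[traj % s0.size()];
    double t = (nt > 0 ? std::min(0.0, sample_times[0]) : 0.0) - burn_in;
    double Hm = pr.mean_at(t);
    double h = rng.expo(1.0 / Hm);
    long sb_count = 0, sd_count = 0;
    int isamp = 0;

    double sensePA = 0, fb = std::exp(fb_step * s);
    // exact simulation needs E[exp(beta h)] finite, i.e. beta <H> < 1;
    // individual draws are also capped so a tail draw cannot stall the
    // event loop with an astronomically fast receptor
    auto epoch_check = [&](double Hmean) {
      if (beta * Hmean >= 1.0)
        stop("overflow error: mean signal %f with beta %f makes the expected receptor rate diverge (beta * <H> must be < 1 for exact simulation)",
             Hmean, beta);
    };
    auto hcheck = [&](double hv) {
      if (beta * (hv - DeltaE) > 30.0)
        stop("overflow error: signal draw h = %f drives the receptor rate beyond what is simulable", hv);
    };
    epoch_check(Hm);
    hcheck(h);
    sensePA = std::exp(beta * (h - DeltaE)) / tauR;

    while (isamp < nt) {
      double rPA = (r == 0) ? (sensePA + intPA) : 0.0;
      double rAP = (r == 1) ? (1.0 / tauR + fb / (g * tauR)) : 0.0;
      double uB = (r == 1) ? uBa : uBp;
      double uD = u / tauU;
      double sB = (s < NS) ? u * esig : 0.0;
      double sD = s / tauS;
      double hR = 1.0 / tauH;
      double total = rPA + rAP + uB + uD + sB + sD + hR;
      double dt = rng.expo(total);
      double t_next = t + dt;
      double t_switch = pr.next_switch(t);
      double t_sample = sample_times[isamp];

      // protocol switches are processed before a coincident sample so the
      // epoch mean is always current when states are recorded
      if (t_switch <= t_sample && t_next > t_switch) {
        t = t_switch;
        Hm = pr.mean_at(t + 1e-12);
        epoch_check(Hm);
        h = rng.expo(1.0 / Hm);
        hcheck(h);
        sensePA = std::exp(beta * (h - DeltaE)) / tauR;
        continue;
      }
      if (t_next > t_sample) {
        // record, then continue from the sample time (memoryless)
        R(traj, isamp) = r; U(traj, isamp) = u; S(traj, isamp) = s;
        H(traj, isamp) = h; SB(traj, isamp) = sb_count;
        SD(traj, isamp) = sd_count;
        t = t_sample; ++isamp;
        fb = std::exp(fb_step * s);  // refresh cached exp against drift
        continue;
      }
      t = t_next;
      double x = rng.unif() * total;
      if ((x -= rPA) < 0) { r = 1; }
      else if ((x -= rAP) < 0) { r = 0; }
      else if ((x -= uB) < 0) { ++u; }
      else if ((x -= uD) < 0) { --u; }
      else if ((x -= sB) < 0) { ++s; ++sb_count; fb *= std::exp(fb_step); }
      else if ((x -= sD) < 0) { --s; ++sd_count; fb *= std::exp(-fb_step); }
      else {
        h = rng.expo(1.0 / Hm);
        hcheck(h);
        sensePA = std::exp(beta * (h - DeltaE)) / tauR;
      }
    }
  }
  return List::create(_["r"] = R, _["u"] = U, _["s"] = S, _["h"] = H,
                      _["s_births"] = SB, _["s_deaths"] = SD);
}

// ---------------------------------------------------------------------------
// Hybrid jump simulator: the receptor is kept at its conditional
// stationary activation probability p_A(s, h) (computed stably in log
// space), and (u, s, h) evolve as an exact jump process with the
// receptor-averaged readout birth rate.  Used for the neural mapping,
// where the full SSA would be dominated by receptor flips.

// [[Rcpp::export(name = "hab_hybrid_ssa")]]
NumericMatrix hab_hybrid_ssa(List params, List protocol, int n_units,
                             double seed, NumericVector sample_times,
                             IntegerVector u0, IntegerVector s0,
                             double burn_in, NumericVector DeltaE_units) {
  const double beta = params["beta"], sigma = params["sigma"],
               g = params["g"],
               kappa = params["kappa"], V = params["V"], cc = params["c"],
               tauU = params["tau_U"], tauS = params["tau_S"],
               tauH = params["tau_H"];
  const int NS = params["N_S"];
  Proto pr = proto_from_list(protocol);
  const int nt = sample_times.size();
  NumericMatrix U(n_units, nt);

  const double uBp = std::exp(-beta * V) / tauU;
  const double uBa = std::exp(-beta * (V - cc)) / tauU;
  const double esig = std::exp(-beta * sigma) / tauS;
  const double lg = std::log(g);

  for (int unit = 0; unit < n_units; ++unit) {
    const double DeltaE = DeltaE_units[unit % DeltaE_units.size()];
    Xoshiro rng((uint64_t)seed, (uint64_t)unit);
    long u = u0[unit % u0.size()];
    int s = s0[unit % s0.size()];
    double t = (nt > 0 ? std::min(0.0, sample_times[0]) : 0.0) - burn_in;
    double Hm = pr.mean_at(t);
    double h = rng.expo(1.0 / Hm);
    int isamp = 0;
    auto pA = [&]() {
      double log_on = logadd(beta * (h - DeltaE), -beta * DeltaE - lg);
      double log_off = logadd(0.0, beta * kappa * sigma * s / NS - lg);
      return 1.0 / (1.0 + std::exp(log_off - log_on));
    };
    double pa = pA();
    while (isamp < nt) {
      double uB = uBp * (1.0 - pa) + uBa * pa;
      double uD = u / tauU;
      double sB = (s < NS) ? u * esig : 0.0;
      double sD = s / tauS;
      double hR = 1.0 / tauH;
      double total = uB + uD + sB + sD + hR;
      double t_next = t + rng.expo(total);
      double t_switch = pr.next_switch(t);
      double t_sample = sample_times[isamp];
      if (t_switch <= t_sample && t_next > t_switch) {
        t = t_switch;
        Hm = pr.mean_at(t + 1e-12);
        h = rng.expo(1.0 / Hm);
        pa = pA();
        continue;
      }
      if (t_next > t_sample) {
        U(unit, isamp) = u;
        t = t_sample; ++isamp;
        continue;
      }
      t = t_next;
      double x = rng.unif() * total;
      if ((x -= uB) < 0) ++u;
      else if ((x -= uD) < 0) --u;
      else if ((x -= sB) < 0) { ++s; pa = pA(); }
      else if ((x -= sD) < 0) { --s; pa = pA(); }
      else { h = rng.expo(1.0 / Hm); pa = pA(); }
    }
  }
  return U;
}
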