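// Exact Gillespie-type lineage simulator for the two-gene toggle switch in a
// growing, dividing cell. Reaction propensities are re-evaluated after every
// step with the current cell volume (the volume changes slowly compared with
// the fastest reaction, so the waiting time is drawn at frozen volume).
// Scheduled events -- locus replication at its cycle age and division at age
// T -- interrupt the SSA clock; the waiting time is resampled afterwards.
//
// Units: seconds throughout. Gene copies of one locus are exchangeable, so
// only the active count per gene is tracked; bound repressor dimers live
// implicitly in (copies - active).

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct Gene {
  int copies;     // current copy count
  int active;     // active (unrepressed) copies, <= copies
  int base;       // copy count at age 0
  double rep_age; // age (s) of the within-cycle doubling; <0 => none
  bool rep_done;  // doubling already executed this cycle
};

struct Counters {
  double n_repress[2] = {0, 0};
  double n_activate[2] = {0, 0};
  double n_rep_release[2] = {0, 0};   // bound dimers freed by replication
  double n_div_bound_lost[2] = {0, 0}; // bound dimers leaving with the sibling
  double n_events = 0, n_divisions = 0;
};

inline double runif01(std::mt19937_64 &rng) {
  // 53-bit mantissa uniform in (0,1)
  return (static_cast<double>(rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

inline int rbinom_half(std::mt19937_64 &rng, int n) {
  if (n <= 0) return 0;
  std::binomial_distribution<int> bin(n, 0.5);
  return bin(rng);
}

// number of active copies retained when keeping one copy of each replicated
// pair: states are exchangeable across copies, so the kept set is a uniform
// n-subset and the retained active count is hypergeometric
inline int rhyper_keep(std::mt19937_64 &rng, int active, int total, int keep) {
  int got = 0;
  for (int i = 0; i < keep; ++i) {
    if (runif01(rng) * (total - i) < active - got) ++got;
  }
  return got;
}

// Division: halve replicated loci (keeping one random copy per pair with its
// state), release bound dimers of constant-count loci (their doubling
// coincides with division), then split all free molecules Binomial(n, 1/2).
void divide(Gene g[2], long long m[2], long long p[2], long long d[2],
            std::mt19937_64 &rng, Counters &ct) {
  for (int i = 0; i < 2; ++i) {
    int o = 1 - i;
    int bound = g[i].copies - g[i].active;
    if (g[i].rep_age < 0) {
      // doubling coincides with division: replication releases repressors,
      // both daughters inherit the same copy count, all copies active
      d[o] += bound;
      ct.n_rep_release[i] += bound;
      g[i].active = g[i].copies;
    } else {
      int keep = g[i].copies / 2;
      int keep_active = rhyper_keep(rng, g[i].active, g[i].copies, keep);
      int bound_kept = keep - keep_active;
      ct.n_div_bound_lost[i] += bound - bound_kept;
      g[i].copies = keep;
      g[i].active = keep_active;
      g[i].rep_done = false;
    }
  }
  for (int i = 0; i < 2; ++i) {
    m[i] = rbinom_half(rng, (int)m[i]);
    p[i] = rbinom_half(rng, (int)p[i]);
    d[i] = rbinom_half(rng, (int)d[i]);
  }
  ct.n_divisions += 1;
}

} // namespace

// [[Rcpp::export]]
List ssa_run_cpp(List par, List state0, double t_end, double record_dt,
                 double avg_start, double seed, bool detect_switch,
                 int dominant, bool stop_at_switch, bool collect_transitions) {
  const double T = as<double>(par["T"]);
  const double kg = as<double>(par["k_g"]);
  const double rg = as<double>(par["r_g_scale"]);
  const double km = as<double>(par["k_m"]);
  const double kp = as<double>(par["k_p"]);
  const double kd = as<double>(par["k_d_scale"]);
  const double rd = as<double>(par["r_d"]);
  const double rm = as<double>(par["r_m"]);
  const double V0 = as<double>(par["V0"]);
  const double vol_fixed = as<double>(par["vol_fixed"]); // <=0: exponential growth
  const bool no_schedule = as<bool>(par["no_schedule"]);
  NumericVector base = par["base_copies"];
  NumericVector rep_age = par["rep_age"];

  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  IntegerVector copies0 = state0["copies"], active0 = state0["active"];
  IntegerVector m0 = state0["m"], p0 = state0["p"], d0 = state0["d"];
  double age = as<double>(state0["age"]);
  if (age < 0 || age >= T) stop("initial cell age must be in [0, T)");

  Gene g[2];
  long long m[2], p[2], d[2];
  for (int i = 0; i < 2; ++i) {
    g[i].base = (int)base[i];
    g[i].rep_age = rep_age[i];
    if (no_schedule) {
      g[i].copies = copies0[i];
      g[i].rep_done = true;
    } else {
      g[i].rep_done = (g[i].rep_age >= 0 && age >= g[i].rep_age);
      g[i].copies = g[i].base * (g[i].rep_done ? 2 : 1);
    }
    g[i].active = active0[i] > g[i].copies ? g[i].copies : active0[i];
    if (g[i].active < 0) stop("negative active gene count");
    m[i] = m0[i]; p[i] = p0[i]; d[i] = d0[i];
    if (m[i] < 0 || p[i] < 0 || d[i] < 0) stop("negative molecule count");
  }

  Counters ct;
  const double lam = std::log(2.0) / T;
  double t = 0.0;
  double fpt = -1.0;

  // time-weighted averages of molecule contents over [avg_start, t_end]
  double acc_w = 0, acc_tot[2] = {0, 0}, acc_p[2] = {0, 0},
         acc_d[2] = {0, 0}, acc_m[2] = {0, 0};

  // trajectory recording
  std::vector<double> rec;
  double next_rec = 0.0;
  const bool recording = record_dt > 0;
  auto push_rec = [&](double tt, double aa) {
    double V = vol_fixed > 0 ? vol_fixed : V0 * std::exp(lam * aa);
    double row[13] = {tt, aa, (double)g[0].copies, (double)g[1].copies,
                      (double)g[0].active, (double)g[1].active,
                      (double)m[0], (double)m[1], (double)p[0], (double)p[1],
                      (double)d[0], (double)d[1], V};
    rec.insert(rec.end(), row, row + 13);
  };

  // successive state-to-state passages: on each detected crossing record the
  // waiting time since the previous one, relabel the dominant state, restart
  double clock_start = 0.0;
  std::vector<double> trans_dur, trans_dir;
  auto check_switch = [&](double tt) {
    if (!detect_switch || (fpt >= 0 && !collect_transitions)) return;
    int nd = 1 - dominant;
    if (p[nd] > p[dominant] && d[nd] > d[dominant]) {
      if (fpt < 0) fpt = tt;
      if (collect_transitions) {
        trans_dur.push_back(tt - clock_start);
        trans_dir.push_back(dominant);
        dominant = nd;
        clock_start = tt;
      }
    }
  };
  check_switch(0.0);

  long long iter_guard = 0;
  while (t < t_end) {
    if (++iter_guard > 20000000000LL) stop("event budget exceeded");
    // next scheduled event (age units)
    double sched_age = -1; int sched_kind = -1; // 0/1 replication, 2 division
    if (!no_schedule) {
      sched_age = T; sched_kind = 2;
      for (int i = 0; i < 2; ++i)
        if (g[i].rep_age >= 0 && !g[i].rep_done && g[i].rep_age < sched_age) {
          sched_age = g[i].rep_age; sched_kind = i;
        }
    }

    double V = vol_fixed > 0 ? vol_fixed : V0 * std::exp(lam * age);
    double a[14];
    for (int i = 0; i < 2; ++i) {
      int o = 1 - i;
      a[7 * i + 0] = kg * (g[i].copies - g[i].active);
      a[7 * i + 1] = (rg / V) * (double)d[o] * g[i].active;
      a[7 * i + 2] = km * g[i].active;
      a[7 * i + 3] = rm * (double)m[i];
      a[7 * i + 4] = kp * (double)m[i];
      a[7 * i + 5] = (kd / V) * (double)p[i] * (double)(p[i] - 1);
      a[7 * i + 6] = rd * (double)d[i];
    }
    double A = 0;
    for (int k = 0; k < 14; ++k) A += a[k];

    double dt; bool fire_sched = false, fire_rxn = false;
    if (A > 0) {
      double tau = -std::log(runif01(rng)) / A;
      if (sched_kind >= 0 && age + tau >= sched_age) {
        dt = sched_age - age; fire_sched = true;
      } else {
        dt = tau; fire_rxn = true;
      }
    } else if (sched_kind >= 0) {
      dt = sched_age - age; fire_sched = true;
    } else {
      dt = t_end - t;
    }
    if (t + dt >= t_end) { // clamp at the horizon; no event fires there
      dt = t_end - t;
      fire_sched = fire_rxn = false;
    }

    // accumulate time-weighted averages over the constant-state segment
    double seg_lo = t > avg_start ? t : avg_start;
    double seg_hi = t + dt;
    if (seg_hi > seg_lo) {
      double w = seg_hi - seg_lo;
      acc_w += w;
      for (int i = 0; i < 2; ++i) {
        acc_tot[i] += w * (double)(p[i] + 2 * d[i]);
        acc_p[i] += w * (double)p[i];
        acc_d[i] += w * (double)d[i];
        acc_m[i] += w * (double)m[i];
      }
    }
    if (recording) {
      while (next_rec <= t + dt && next_rec <= t_end) {
        push_rec(next_rec, age + (next_rec - t));
        next_rec += record_dt;
      }
    }

    t += dt; age += dt;

    if (fire_sched) {
      if (sched_kind == 2) {
        age = 0.0;
        divide(g, m, p, d, rng, ct);
      } else {
        int i = sched_kind, o = 1 - i;
        int bound = g[i].copies - g[i].active;
        d[o] += bound;
        ct.n_rep_release[i] += bound;
        g[i].copies *= 2;
        g[i].active = g[i].copies;
        g[i].rep_done = true;
      }
      ct.n_events += 1;
      check_switch(t);
    } else if (fire_rxn) {
      double r = runif01(rng) * A, cum = 0;
      int k = 0;
      for (; k < 13; ++k) { cum += a[k]; if (r < cum) break; }
      int i = k / 7, o = 1 - i;
      switch (k % 7) {
        case 0: g[i].active += 1; d[o] += 1; ct.n_activate[i] += 1; break;
        case 1: g[i].active -= 1; d[o] -= 1; ct.n_repress[i] += 1; break;
        case 2: m[i] += 1; break;
        case 3: m[i] -= 1; break;
        case 4: p[i] += 1; break;
        case 5: p[i] -= 2; d[i] += 1; break;
        case 6: d[i] -= 1; p[i] += 2; break;
      }
      if (m[i] < 0 || p[i] < 0 || d[i] < 0 || g[i].active < 0)
        stop("negative count: invariant violation");
      ct.n_events += 1;
      check_switch(t);
    }

    if (stop_at_switch && fpt >= 0) break;
    if (collect_transitions && trans_dur.size() >= 2000000) break;
  }

  NumericMatrix traj;
  if (recording) {
    int nrow = rec.size() / 13;
    traj = NumericMatrix(nrow, 13);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < 13; ++c) traj(r, c) = rec[r * 13 + c];
  }

  double w = acc_w > 0 ? acc_w : 1.0;
  return List::create(
    _["trajectory"] = traj,
    _["final"] = List::create(
      _["copies"] = IntegerVector::create(g[0].copies, g[1].copies),
      _["active"] = IntegerVector::create(g[0].active, g[1].active),
      _["m"] = IntegerVector::create((int)m[0], (int)m[1]),
      _["p"] = IntegerVector::create((int)p[0], (int)p[1]),
      _["d"] = IntegerVector::create((int)d[0], (int)d[1]),
      _["age"] = age, _["time"] = t),
    _["avg"] = List::create(
      _["window"] = acc_w,
      _["total_protein"] = NumericVector::create(acc_tot[0] / w, acc_tot[1] / w),
      _["p"] = NumericVector::create(acc_p[0] / w, acc_p[1] / w),
      _["d"] = NumericVector::create(acc_d[0] / w, acc_d[1] / w),
      _["m"] = NumericVector::create(acc_m[0] / w, acc_m[1] / w)),
    _["fpt"] = fpt,
    _["transitions"] = DataFrame::create(
      _["duration_s"] = NumericVector(trans_dur.begin(), trans_dur.end()),
      _["from_gene"] = NumericVector(trans_dir.begin(), trans_dir.end())),
    _["audit"] = List::create(
      _["n_repress"] = NumericVector::create(ct.n_repress[0], ct.n_repress[1]),
      _["n_activate"] = NumericVector::create(ct.n_activate[0], ct.n_activate[1]),
      _["n_rep_release"] = NumericVector::create(ct.n_rep_release[0], ct.n_rep_release[1]),
      _["n_div_bound_lost"] = NumericVector::create(ct.n_div_bound_lost[0], ct.n_div_bound_lost[1]),
      _["n_events"] = ct.n_events, _["n_divisions"] = ct.n_divisions));
}

// [[Rcpp::export]]
List ssa_partition_cpp(IntegerVector copies, IntegerVector active,
                       IntegerVector m, IntegerVector p, IntegerVector d,
                       NumericVector rep_age, double seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  Gene g[2];
  long long mm[2], pp[2], dd[2];
  for (int i = 0; i < 2; ++i) {
    g[i] = Gene{copies[i], active[i], copies[i], rep_age[i], true};
    mm[i] = m[i]; pp[i] = p[i]; dd[i] = d[i];
  }
  Counters ct;
  divide(g, mm, pp, dd, rng, ct);
  return List::create(
    _["copies"] = IntegerVector::create(g[0].copies, g[1].copies),
    _["active"] = IntegerVector::create(g[0].active, g[1].active),
    _["m"] = IntegerVector::create((int)mm[0], (int)mm[1]),
    _["p"] = IntegerVector::create((int)pp[0], (int)pp[1]),
    _["d"] = IntegerVector::create((int)dd[0], (int)dd[1]),
    _["bound_lost"] = NumericVector::create(ct.n_div_bound_lost[0],
                                            ct.n_div_bound_lost[1]),
    _["released"] = NumericVector::create(ct.n_rep_release[0],
                                          ct.n_rep_release[1]));
}
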