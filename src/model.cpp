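// Stochastic single-cell model of hematopoietic niche competition.
//
// Two stem-cell compartments: A (niche-attached, non-proliferating) and
// Omega (actively cycling). Each cell carries an attachment affinity a in
// [a_min, a_max] that regenerates multiplicatively in A and attenuates in
// Omega; transition probabilities couple the affinity to compartment-size-
// dependent sigmoids, so niche crowding suppresses (re)attachment and a
// crowded cycling pool suppresses release. Cells whose affinity falls below
// a_min leave the stem pool as differentiated output. Transplanted cells
// start in a pre-engraftment state and attempt niche attachment for a
// limited window before being lost.
//
// All randomness flows through R's RNG so set.seed() governs; draws are
// skipped when a transition probability is exactly zero, so impossible
// events consume no random numbers.

#include <Rcpp.h>
using namespace Rcpp;

static const int N_CLASS = 4; // host, bulk, A, B

struct Pars {
  double a_min, a_max, r, d, tau_c, dt;
  double fa[4], fo[4];          // f_max, x_half, slope, f_min
  double NA_bar, NO_bar;
  double alpha_mult[N_CLASS], omega_mult[N_CLASS], death_rate[N_CLASS];
};

static inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// 4-coefficient sigmoid in the scaled census x = N / N_bar
static inline double sig4(double x, const double* c) {
  return clip01(c[3] + (c[0] - c[3]) / (1.0 + std::exp(c[2] * (x - c[1]))));
}

static inline double alpha_prob(double a, double N_A, const Pars& p, int cls) {
  return clip01((a / p.a_max) * sig4(N_A / p.NA_bar, p.fa) * p.alpha_mult[cls]);
}

static inline double omega_prob(double a, double N_O, const Pars& p, int cls) {
  return clip01((p.a_min / a) * sig4(N_O / p.NO_bar, p.fo) * p.omega_mult[cls]);
}

static Pars unpack(const List& par) {
  Pars p;
  p.a_min = as<double>(par["a_min"]);
  p.a_max = as<double>(par["a_max"]);
  p.r = as<double>(par["r"]);
  p.d = as<double>(par["d"]);
  p.tau_c = as<double>(par["tau_c"]);
  p.dt = as<double>(par["dt"]);
  NumericVector fa = par["f_alpha"], fo = par["f_omega"];
  for (int i = 0; i < 4; ++i) { p.fa[i] = fa[i]; p.fo[i] = fo[i]; }
  p.NA_bar = as<double>(par["N_bar_A"]);
  p.NO_bar = as<double>(par["N_bar_Omega"]);
  NumericVector am = par["alpha_mult"], om = par["omega_mult"],
                dr = par["death_rate"];
  for (int i = 0; i < N_CLASS; ++i) {
    p.alpha_mult[i] = am[i];
    p.omega_mult[i] = om[i];
    p.death_rate[i] = dr[i];
  }
  return p;
}

// [[Rcpp::export(name = ".ck_transition_probabilities")]]
NumericMatrix ck_transition_probabilities(NumericVector a, NumericVector N_A,
                                          NumericVector N_Omega,
                                          IntegerVector cls, List par) {
  Pars p = unpack(par);
  int n = a.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    if (a[i] < p.a_min - 1e-12 || a[i] > p.a_max + 1e-12)
      stop("affinity out of [a_min, a_max]");
    out(i, 0) = alpha_prob(a[i], N_A[i % N_A.size()], p, cls[i % cls.size()]);
    out(i, 1) = omega_prob(a[i], N_Omega[i % N_Omega.size()], p,
                           cls[i % cls.size()]);
  }
  colnames(out) = CharacterVector::create("alpha", "omega");
  return out;
}

// Advance the population n_steps. When check_every > 0 the leukemic disease
// criterion is evaluated every check_every steps: the run stops early once
// leukemic cells (live non-pre cells of classes other than host, plus their
// cumulative differentiated output) reach leu_threshold of all live cells
// plus all output, or - exactly, not approximately - once no leukemic cell
// (live or pre-engraftment) remains, since the fraction can then never rise.
// [[Rcpp::export(name = ".ck_run_model")]]
List ck_run_model(IntegerVector clone0, IntegerVector cls0, IntegerVector comp0,
                  NumericVector aff0, NumericVector cyc0, NumericVector win0,
                  List par, int n_steps, int n_clones,
                  int check_every = 0, double leu_threshold = -1.0) {
  Pars p = unpack(par);
  std::vector<int> clone(clone0.begin(), clone0.end());
  std::vector<int> cls(cls0.begin(), cls0.end());
  std::vector<int> comp(comp0.begin(), comp0.end());
  std::vector<double> aff(aff0.begin(), aff0.end());
  std::vector<double> cyc(cyc0.begin(), cyc0.end());
  std::vector<double> win(win0.begin(), win0.end());

  NumericVector diff_out(n_clones), engrafted(n_clones);
  int lost = 0;
  IntegerMatrix ledger(n_steps, 6);
  colnames(ledger) = CharacterVector::create("before", "births", "diffs",
                                             "deaths", "lost", "after");
  // census trajectory: N_A then N_Omega per class, recorded after each step
  NumericMatrix traj(n_steps, 2 * N_CLASS);

  int steps_run = 0;
  bool crossed = false;

  for (int step = 0; step < n_steps; ++step) {
    int n = (int) clone.size();
    // census at step start (pre-engraftment cells do not occupy compartments)
    double N_A = 0.0, N_O = 0.0;
    for (int i = 0; i < n; ++i) {
      if (comp[i] == 0) N_A += 1.0;
      else if (comp[i] == 1) N_O += 1.0;
    }
    std::vector<int> n_clone2, n_cls2, n_comp2;
    std::vector<double> n_aff2, n_cyc2, n_win2;
    n_clone2.reserve(n + 16);
    n_cls2.reserve(n + 16);
    n_comp2.reserve(n + 16);
    n_aff2.reserve(n + 16);
    n_cyc2.reserve(n + 16);
    n_win2.reserve(n + 16);
    int births = 0, diffs = 0, deaths = 0, lost_step = 0;

    for (int i = 0; i < n; ++i) {
      int ci = cls[i];
      double dr = p.death_rate[ci];
      if (dr > 0.0 && comp[i] != 2 && unif_rand() < dr) {
        ++deaths;
        continue;
      }
      if (comp[i] == 0) {
        // niche: affinity regenerates; stochastic release to Omega
        double a = std::min(aff[i] * p.r, p.a_max);
        double pw = omega_prob(a, N_O, p, ci);
        int newcomp = 0;
        double newcyc = 0.0;
        if (pw > 0.0 && unif_rand() < pw) {
          newcomp = 1;
          newcyc = 0.0;
        }
        n_clone2.push_back(clone[i]);
        n_cls2.push_back(ci);
        n_comp2.push_back(newcomp);
        n_aff2.push_back(a);
        n_cyc2.push_back(newcyc);
        n_win2.push_back(0.0);
      } else if (comp[i] == 1) {
        // cycling pool: affinity attenuates; differentiate, re-attach, or cycle
        double a = aff[i] / p.d;
        if (a < p.a_min) {
          diff_out[clone[i]] += 1.0;
          ++diffs;
          continue;
        }
        double pa = alpha_prob(a, N_A, p, ci);
        if (pa > 0.0 && unif_rand() < pa) {
          n_clone2.push_back(clone[i]);
          n_cls2.push_back(ci);
          n_comp2.push_back(0);
          n_aff2.push_back(a);
          n_cyc2.push_back(0.0);
          n_win2.push_back(0.0);
        } else {
          double c = cyc[i] + p.dt;
          if (c >= p.tau_c - 1e-9) {
            // division: two daughters, affinity inherited, cycle restarts
            for (int k = 0; k < 2; ++k) {
              n_clone2.push_back(clone[i]);
              n_cls2.push_back(ci);
              n_comp2.push_back(1);
              n_aff2.push_back(a);
              n_cyc2.push_back(0.0);
              n_win2.push_back(0.0);
            }
            ++births;
          } else {
            n_clone2.push_back(clone[i]);
            n_cls2.push_back(ci);
            n_comp2.push_back(1);
            n_aff2.push_back(a);
            n_cyc2.push_back(c);
            n_win2.push_back(0.0);
          }
        }
      } else {
        // pre-engraftment: attempt attachment against the full niche
        double pa = alpha_prob(aff[i], N_A, p, ci);
        if (pa > 0.0 && unif_rand() < pa) {
          engrafted[clone[i]] += 1.0;
          double a = aff[i];
          if (a < p.a_min) a = p.a_min;
          if (a > p.a_max) a = p.a_max;
          n_clone2.push_back(clone[i]);
          n_cls2.push_back(cls[i]);
          n_comp2.push_back(0);
          n_aff2.push_back(a);
          n_cyc2.push_back(0.0);
          n_win2.push_back(0.0);
        } else {
          double w = win[i] - p.dt;
          if (w <= 0.0) {
            ++lost_step;
          } else {
            n_clone2.push_back(clone[i]);
            n_cls2.push_back(cls[i]);
            n_comp2.push_back(2);
            n_aff2.push_back(aff[i]);
            n_cyc2.push_back(0.0);
            n_win2.push_back(w);
          }
        }
      }
    }

    clone.swap(n_clone2);
    cls.swap(n_cls2);
    comp.swap(n_comp2);
    aff.swap(n_aff2);
    cyc.swap(n_cyc2);
    win.swap(n_win2);
    lost += lost_step;

    ledger(step, 0) = n;
    ledger(step, 1) = births;
    ledger(step, 2) = diffs;
    ledger(step, 3) = deaths;
    ledger(step, 4) = lost_step;
    ledger(step, 5) = (int) clone.size();

    for (int i = 0; i < (int) clone.size(); ++i) {
      if (comp[i] == 0) traj(step, cls[i]) += 1.0;
      else if (comp[i] == 1) traj(step, N_CLASS + cls[i]) += 1.0;
    }

    steps_run = step + 1;
    if (check_every > 0 && steps_run % check_every == 0) {
      double leu_live = 0.0, live = 0.0;
      bool any_leu = false;
      for (int i = 0; i < (int) clone.size(); ++i) {
        if (cls[i] != 0) any_leu = true;
        if (comp[i] == 2) continue;
        live += 1.0;
        if (cls[i] != 0) leu_live += 1.0;
      }
      double leu_out = 0.0, all_out = 0.0;
      for (int c = 0; c < n_clones; ++c) all_out += diff_out[c];
      // leukemic output: diff_out of clones whose class is leukemic; clone
      // ids partition by class, so the flag follows from the initial cells
      std::vector<int> leu_flag(n_clones, 0);
      for (int i = 0; i < (int) clone0.size(); ++i)
        leu_flag[clone0[i]] = (cls0[i] != 0);
      for (int c = 0; c < n_clones; ++c)
        if (leu_flag[c] == 1) leu_out += diff_out[c];
      double denom = live + all_out;
      double frac = denom > 0 ? (leu_live + leu_out) / denom : 0.0;
      if (leu_threshold >= 0 && frac >= leu_threshold) {
        crossed = true;
        break;
      }
      if (!any_leu) break;
    }
  }

  if (check_every > 0 && steps_run < n_steps) {
    ledger = ledger(Range(0, steps_run - 1), _);
    traj = traj(Range(0, steps_run - 1), _);
  }

  return List::create(
    _["clone"] = wrap(clone), _["cls"] = wrap(cls), _["comp"] = wrap(comp),
    _["aff"] = wrap(aff), _["cyc"] = wrap(cyc), _["win"] = wrap(win),
    _["diff_out"] = diff_out, _["engrafted"] = engrafted, _["lost"] = lost,
    _["ledger"] = ledger, _["traj"] = traj,
    _["steps_run"] = steps_run, _["crossed"] = crossed);
}
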