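#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Division-level segregation rules. All rules act on the doubled parental
// complement (2*N_j per species) and conserve copies exactly:
// daughter2 = 2*N_j - daughter1.
//
// Model codes: 1 = element_level, 2 = cell_level, 3 = fraction_coupled.
// The first species passed in is the anchor; callers swap for anchor = 2.

struct Division {
  int d1_a;      // anchor copies in daughter 1
  int d1_b;      // other-species copies in daughter 1
  double coup1;  // deterministic / coupled part in daughter 1 (NA if n/a)
  double coup2;  // coupled part in daughter 2
};

// 32 random bits from R's uniform stream.
static inline uint32_t rand_bits32() {
  double u = unif_rand() * 4294967296.0;
  if (u >= 4294967295.0) u = 4294967295.0;
  return (uint32_t) u;
}

// Exact Binomial(n, 1/2) as the popcount of n independent fair bits; every
// split in the segregation rules is a fair split, so this replaces the
// general-purpose binomial sampler at a fraction of its cost.
static inline int rbinom_half(int n) {
  int s = 0;
  while (n >= 32) {
    s += __builtin_popcount(rand_bits32());
    n -= 32;
  }
  if (n > 0) {
    s += __builtin_popcount(rand_bits32() & ((1u << n) - 1u));
  }
  return s;
}

static inline int rbinom_int(int size, double prob) {
  if (size <= 0) return 0;
  if (prob == 0.5) return rbinom_half(size);
  return (int) R::rbinom((double) size, prob);
}

// Anchor split Binomial(2Na, 1/2); the other species receives a deterministic
// coupled share floor(gamma * 2Nb * n_a^(i) / (2Na)) per daughter and the
// remainder is split Binomial(rem, 1/2). Na = 0 disables coupling.
static Division div_element(int Na, int Nb, double gamma) {
  Division out;
  int tot_a = 2 * Na, tot_b = 2 * Nb;
  int a1 = rbinom_int(tot_a, 0.5);
  int c1 = 0, c2 = 0;
  if (Na > 0 && tot_b > 0) {
    c1 = (int) std::floor(gamma * tot_b * ((double) a1 / tot_a));
    c2 = (int) std::floor(gamma * tot_b * ((double) (tot_a - a1) / tot_a));
  }
  int rem = tot_b - c1 - c2;
  int r1 = rbinom_int(rem, 0.5);
  out.d1_a = a1;
  out.d1_b = c1 + r1;
  out.coup1 = (double) c1;
  out.coup2 = (double) c2;
  return out;
}

// Both species split Binomial(2N, 1/2) independently; with probability gamma
// the larger half of the other species joins the daughter holding the larger
// anchor half, with probability 1 - gamma the opposite daughter. An exactly
// even anchor split is a tie: daughter labelling is uniform.
static Division div_cell(int Na, int Nb, double gamma) {
  Division out;
  int tot_a = 2 * Na, tot_b = 2 * Nb;
  int a1 = rbinom_int(tot_a, 0.5);
  int b = rbinom_int(tot_b, 0.5);
  int hi_b = b > tot_b - b ? b : tot_b - b;
  int lo_b = tot_b - hi_b;
  bool pair_high;
  if (2 * a1 > tot_a) {
    pair_high = unif_rand() < gamma;
  } else if (2 * a1 < tot_a) {
    pair_high = unif_rand() >= gamma;
  } else {
    pair_high = unif_rand() < 0.5;  // tie: label-invariant
  }
  out.d1_a = a1;
  out.d1_b = pair_high ? hi_b : lo_b;
  out.coup1 = NA_REAL;
  out.coup2 = NA_REAL;
  return out;
}

// A rounded fraction phi of each species' doubled copies is split at one
// shared ratio drawn as Binomial(coupled anchor copies, 1/2) / coupled anchor
// copies; the remainder of each species splits independently Binomial(., 1/2).
static Division div_fraction(int Na, int Nb, double phi) {
  Division out;
  int tot_a = 2 * Na, tot_b = 2 * Nb;
  int ca = (int) std::llround(phi * tot_a);
  int cb = (int) std::llround(phi * tot_b);
  int a_coup, b_coup;
  if (ca > 0) {
    a_coup = rbinom_int(ca, 0.5);
    double ratio = (double) a_coup / ca;
    // stochastic rounding keeps the two daughters exchangeable (fixed
    // half-up rounding would systematically favour daughter 1)
    double x = ratio * cb;
    b_coup = (int) std::floor(x);
    if (unif_rand() < x - b_coup) ++b_coup;
  } else {
    a_coup = 0;
    b_coup = rbinom_int(cb, 0.5);  // no anchor copies to couple to
  }
  int a_free = rbinom_int(tot_a - ca, 0.5);
  int b_free = rbinom_int(tot_b - cb, 0.5);
  out.d1_a = a_coup + a_free;
  out.d1_b = b_coup + b_free;
  out.coup1 = (double) b_coup;
  out.coup2 = (double) (cb - b_coup);
  return out;
}

static inline Division divide_cell(int Na, int Nb, int model, double coef) {
  switch (model) {
    case 1: return div_element(Na, Nb, coef);
    case 2: return div_cell(Na, Nb, coef);
    default: return div_fraction(Na, Nb, coef);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_segregate(IntegerVector N1, IntegerVector N2, int model,
                            NumericVector coef) {
  R_xlen_t n = std::max(std::max(N1.size(), N2.size()), coef.size());
  NumericMatrix out(n, 6);
  for (R_xlen_t i = 0; i < n; ++i) {
    int a = N1[i % N1.size()];
    int b = N2[i % N2.size()];
    double cf = coef[i % coef.size()];
    Division d = divide_cell(a, b, model, cf);
    out(i, 0) = d.d1_a;
    out(i, 1) = 2 * a - d.d1_a;
    out(i, 2) = d.d1_b;
    out(i, 3) = 2 * b - d.d1_b;
    out(i, 4) = d.coup1;
    out(i, 5) = d.coup2;
  }
  colnames(out) = CharacterVector::create("n1_d1", "n1_d2", "n2_d1", "n2_d2",
                                          "coupled_d1", "coupled_d2");
  return out;
}

// Continuous-time birth-death process over cells carrying two ecDNA species.
// Exact stochastic simulation (Gillespie direct method) with four
// presence-category birth channels (rate lambda_base * (1 + s_cat) per cell)
// and one death channel (rate mu per cell). Equivalent to racing per-cell
// exponential birth/death clocks, by memorylessness.
// [[Rcpp::export]]
List cpp_simulate_population(IntegerVector init_k1, IntegerVector init_k2,
                             NumericVector s, double lambda_base, double mu,
                             int model, double coef, int anchor,
                             int target_cells, double target_time,
                             double start_time,
                             bool record_tree, bool record_traj) {
  const int n0 = init_k1.size();
  std::vector<int> k1, k2;           // state per slot (slots never reused)
  std::vector<signed char> alive;
  std::vector<int> cat_of;           // presence category per slot
  std::vector<int> bucket[4];        // alive slots per category
  std::vector<int> pos_in_bucket;
  // optional lineage records
  std::vector<int> parent;           // 0-based slot of parent, -1 for founders
  std::vector<double> t_birth, t_end;
  std::vector<int> fate;             // 0 alive, 1 divided, 2 died

  double rate[4];
  for (int c = 0; c < 4; ++c) rate[c] = lambda_base * (1.0 + s[c]);

  auto category = [](int a, int b) { return (a > 0 ? 1 : 0) + (b > 0 ? 2 : 0); };
  auto push_cell = [&](int a, int b, int par, double t) {
    int slot = (int) k1.size();
    int c = category(a, b);
    k1.push_back(a); k2.push_back(b);
    alive.push_back(1);
    cat_of.push_back(c);
    pos_in_bucket.push_back((int) bucket[c].size());
    bucket[c].push_back(slot);
    if (record_tree) {
      parent.push_back(par);
      t_birth.push_back(t);
      t_end.push_back(NA_REAL);
      fate.push_back(0);
    }
    return slot;
  };
  auto remove_from_bucket = [&](int slot) {
    int c = cat_of[slot], p = pos_in_bucket[slot];
    int last = bucket[c].back();
    bucket[c][p] = last;
    pos_in_bucket[last] = p;
    bucket[c].pop_back();
  };

  for (int i = 0; i < n0; ++i) push_cell(init_k1[i], init_k2[i], -1, start_time);
  int n_alive = n0;

  std::vector<double> tr_t, tr_mean1, tr_mean2;
  std::vector<int> tr_n;
  double sum1 = 0, sum2 = 0;
  for (int i = 0; i < n0; ++i) { sum1 += init_k1[i]; sum2 += init_k2[i]; }
  auto record_point = [&](double t) {
    if (!record_traj) return;
    tr_t.push_back(t);
    tr_n.push_back(n_alive);
    tr_mean1.push_back(n_alive > 0 ? sum1 / n_alive : NA_REAL);
    tr_mean2.push_back(n_alive > 0 ? sum2 / n_alive : NA_REAL);
  };

  double t = start_time;
  record_point(t);
  bool hit_time = false;
  long n_events = 0;

  while (n_alive > 0 && n_alive < target_cells) {
    double birth_tot = 0;
    for (int c = 0; c < 4; ++c) birth_tot += rate[c] * bucket[c].size();
    double death_tot = mu * n_alive;
    double tot = birth_tot + death_tot;
    if (tot <= 0) break;  // frozen population (all rates zero)
    double dt = R::rexp(1.0 / tot);
    if (t + dt > target_time) { t = target_time; hit_time = true; break; }
    t += dt;
    ++n_events;
    double u = unif_rand() * tot;
    if (u < death_tot) {
      // uniform death across alive cells
      int idx = (int) (unif_rand() * n_alive);
      if (idx >= n_alive) idx = n_alive - 1;
      int slot = -1;
      for (int c = 0; c < 4; ++c) {
        int bc = (int) bucket[c].size();
        if (idx < bc) { slot = bucket[c][idx]; break; }
        idx -= bc;
      }
      sum1 -= k1[slot]; sum2 -= k2[slot];
      remove_from_bucket(slot);
      alive[slot] = 0;
      if (record_tree) { t_end[slot] = t; fate[slot] = 2; }
      --n_alive;
    } else {
      double v = u - death_tot;
      int c = 0;
      for (; c < 3; ++c) {
        double w = rate[c] * bucket[c].size();
        if (v < w) break;
        v -= w;
      }
      int within = (int) (v / rate[c]);
      if (within >= (int) bucket[c].size()) within = (int) bucket[c].size() - 1;
      int slot = bucket[c][within];
      int Na = k1[slot], Nb = k2[slot];
      Division d = (anchor == 1) ? divide_cell(Na, Nb, model, coef)
                                 : divide_cell(Nb, Na, model, coef);
      int d1a, d1b;
      if (anchor == 1) { d1a = d.d1_a; d1b = d.d1_b; }
      else             { d1a = d.d1_b; d1b = d.d1_a; }
      int d2a = 2 * Na - d1a, d2b = 2 * Nb - d1b;
      sum1 += Na; sum2 += Nb;  // doubled then conserved across daughters
      remove_from_bucket(slot);
      alive[slot] = 0;
      if (record_tree) { t_end[slot] = t; fate[slot] = 1; }
      --n_alive;
      push_cell(d1a, d1b, slot, t);
      push_cell(d2a, d2b, slot, t);
      n_alive += 2;
    }
    record_point(t);
    if ((n_events & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (!hit_time && n_alive > 0) {
    // stopped on target_cells (or frozen); clock stays at last event
  }

  // collect leaves = alive cells
  IntegerVector lk1(n_alive), lk2(n_alive);
  int j = 0;
  for (int c = 0; c < 4; ++c)
    for (int slot : bucket[c]) { lk1[j] = k1[slot]; lk2[j] = k2[slot]; ++j; }

  List out = List::create(
    _["k1"] = lk1, _["k2"] = lk2,
    _["n_cells"] = n_alive,
    _["final_time"] = t,
    _["extinct"] = (n_alive == 0),
    _["n_events"] = (double) n_events);
  if (record_traj) {
    out["trajectory"] = List::create(
      _["time"] = wrap(tr_t), _["n_cells"] = wrap(tr_n),
      _["mean_k1"] = wrap(tr_mean1), _["mean_k2"] = wrap(tr_mean2));
  }
  if (record_tree) {
    out["lineage"] = List::create(
      _["parent"] = wrap(parent), _["t_birth"] = wrap(t_birth),
      _["t_end"] = wrap(t_end), _["fate"] = wrap(fate),
      _["alive"] = wrap(std::vector<int>(alive.begin(), alive.end())),
      _["k1"] = wrap(k1), _["k2"] = wrap(k2));
  }
  return out;
}
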