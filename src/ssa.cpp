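#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Direct-method Gillespie sampler of the chemical master equation for the
// package's reaction networks. Propensity forms:
//   0 const:   a = rate
//   1 uni:     a = rate * x[s1]
//   2 bi:      a = rate * x[s1] * x[s2]
//   3 hill:    a = rate * (x[s1]/e1)^e2 / ((x[s1]/e1)^e2 + 1)
//   4 repress: a = rate / (1 + x[s1]/e1)
// Hill and Michaelis-Menten propensities are used directly as mesoscopic
// rates, matching the model's granularity (no elementary-step expansion).
// The inner loop keeps a running propensity sum, updated through a
// species->reaction dependency graph and refreshed in full periodically to
// wash out floating-point drift.

static inline std::uint64_t splitmix64(std::uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// one RNG stream per (seed, run) pair: reproducible and order-independent
static inline std::mt19937_64 run_stream(std::uint64_t seed, std::uint64_t run) {
  std::uint64_t s = splitmix64(seed ^ splitmix64(run));
  return std::mt19937_64(s);
}

struct Net {
  int n_species, n_rxn;
  std::vector<int> type, s1, s2;
  std::vector<double> rate, e1, e2;
  // sparse stoichiometry: per reaction, list of (species, delta)
  std::vector<std::vector<std::pair<int, int>>> change;
  // per reaction, list of propensities to refresh after it fires
  std::vector<std::vector<int>> affects;
};

static Net build_net(IntegerMatrix stoich, IntegerVector type,
                     NumericVector rate, IntegerVector s1, IntegerVector s2,
                     NumericVector e1, NumericVector e2) {
  Net net;
  net.n_species = stoich.nrow();
  net.n_rxn = stoich.ncol();
  net.type.assign(type.begin(), type.end());
  net.s1.assign(s1.begin(), s1.end());
  net.s2.assign(s2.begin(), s2.end());
  net.rate.assign(rate.begin(), rate.end());
  net.e1.assign(e1.begin(), e1.end());
  net.e2.assign(e2.begin(), e2.end());
  net.change.resize(net.n_rxn);
  std::vector<std::vector<int>> dep(net.n_species);  // species -> reactions
  for (int j = 0; j < net.n_rxn; ++j) {
    if (net.s1[j] >= 0) dep[net.s1[j]].push_back(j);
    if (net.s2[j] >= 0) dep[net.s2[j]].push_back(j);
  }
  net.affects.resize(net.n_rxn);
  for (int j = 0; j < net.n_rxn; ++j) {
    for (int i = 0; i < net.n_species; ++i) {
      if (stoich(i, j) != 0) {
        net.change[j].push_back({i, stoich(i, j)});
        for (int k : dep[i]) {
          if (std::find(net.affects[j].begin(), net.affects[j].end(), k) ==
              net.affects[j].end())
            net.affects[j].push_back(k);
        }
      }
    }
  }
  return net;
}

static inline double propensity(const Net& net, int j,
                                const std::vector<double>& x) {
  switch (net.type[j]) {
  case 0: return net.rate[j];
  case 1: return net.rate[j] * x[net.s1[j]];
  case 2: return net.rate[j] * x[net.s1[j]] * x[net.s2[j]];
  case 3: {
    if (x[net.s1[j]] <= 0.0) return 0.0;
    double u = std::pow(x[net.s1[j]] / net.e1[j], net.e2[j]);
    return net.rate[j] * u / (u + 1.0);
  }
  case 4: return net.rate[j] / (1.0 + x[net.s1[j]] / net.e1[j]);
  default: return 0.0;
  }
}

[[noreturn]] static void bad_propensity(const Net& net, int j,
                                        const std::vector<double>& x) {
  std::string msg = "invalid propensity in reaction " + std::to_string(j + 1) +
    " at state:";
  for (double xi : x) msg += " " + std::to_string(xi);
  stop(msg);
}

// advance one realization from time 0 to t_end; x modified in place.
// Returns the event count.
static long advance(const Net& net, std::vector<double>& x, double t_end,
                    std::mt19937_64& gen) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> a(net.n_rxn);
  double a0 = 0.0;
  for (int j = 0; j < net.n_rxn; ++j) {
    a[j] = propensity(net, j, x);
    if (!(a[j] >= 0.0) || !std::isfinite(a[j])) bad_propensity(net, j, x);
    a0 += a[j];
  }
  double t = 0.0;
  long n_events = 0;
  while (true) {
    if ((n_events & 0xFFF) == 0xFFF) {  // periodic exact refresh of a0
      a0 = 0.0;
      for (int j = 0; j < net.n_rxn; ++j) a0 += a[j];
    }
    if (a0 <= 0.0) return n_events;  // absorbing state
    double u1 = unif(gen);
    if (u1 <= 0.0) u1 = std::numeric_limits<double>::min();
    double tau = -std::log(u1) / a0;
    if (t + tau > t_end) return n_events;
    t += tau;
    double target = unif(gen) * a0, cum = 0.0;
    int j = net.n_rxn - 1;
    for (int k = 0; k < net.n_rxn; ++k) {
      cum += a[k];
      if (target <= cum) { j = k; break; }
    }
    for (auto& ci : net.change[j]) x[ci.first] += ci.second;
    for (int k : net.affects[j]) {
      double an = propensity(net, k, x);
      if (!(an >= 0.0) || !std::isfinite(an)) bad_propensity(net, k, x);
      a0 += an - a[k];
      a[k] = an;
    }
    ++n_events;
  }
}

// [[Rcpp::export(name = ".ssa_final_states")]]
NumericMatrix ssa_final_states(IntegerMatrix stoich, IntegerVector type,
                               NumericVector rate, IntegerVector s1,
                               IntegerVector s2, NumericVector e1,
                               NumericVector e2, NumericVector x0,
                               double t_end, int n_runs, double seed) {
  Net net = build_net(stoich, type, rate, s1, s2, e1, e2);
  NumericMatrix out(n_runs, net.n_species);
  for (int r = 0; r < n_runs; ++r) {
    std::mt19937_64 gen = run_stream((std::uint64_t)seed, (std::uint64_t)r + 1);
    std::vector<double> x(x0.begin(), x0.end());
    advance(net, x, t_end, gen);
    for (int i = 0; i < net.n_species; ++i) out(r, i) = x[i];
    if ((r & 0xFF) == 0) checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".ssa_path")]]
List ssa_path(IntegerMatrix stoich, IntegerVector type, NumericVector rate,
              IntegerVector s1, IntegerVector s2, NumericVector e1,
              NumericVector e2, NumericVector x0, double t_end, double seed,
              int max_events) {
  Net net = build_net(stoich, type, rate, s1, s2, e1, e2);
  std::mt19937_64 gen = run_stream((std::uint64_t)seed, 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(net.n_rxn);
  std::vector<double> times;
  std::vector<double> states;
  times.push_back(0.0);
  states.insert(states.end(), x.begin(), x.end());
  double t = 0.0;
  while ((int)times.size() - 1 < max_events) {
    double a0 = 0.0;
    for (int j = 0; j < net.n_rxn; ++j) {
      a[j] = propensity(net, j, x);
      if (!(a[j] >= 0.0) || !std::isfinite(a[j])) bad_propensity(net, j, x);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;
    double u1 = unif(gen);
    if (u1 <= 0.0) u1 = std::numeric_limits<double>::min();
    double tau = -std::log(u1) / a0;
    if (t + tau > t_end) break;
    t += tau;
    double target = unif(gen) * a0, cum = 0.0;
    int j = net.n_rxn - 1;
    for (int k = 0; k < net.n_rxn; ++k) {
      cum += a[k];
      if (target <= cum) { j = k; break; }
    }
    for (auto& ci : net.change[j]) x[ci.first] += ci.second;
    times.push_back(t);
    states.insert(states.end(), x.begin(), x.end());
  }
  if ((int)times.size() - 1 >= max_events) {
    stop("SSA event budget exceeded (max_events = " +
         std::to_string(max_events) + "); raise max_events or shorten t_end");
  }
  int n = times.size();
  NumericMatrix sm(n, net.n_species);
  for (int r = 0; r < n; ++r)
    for (int i = 0; i < net.n_species; ++i)
      sm(r, i) = states[(std::size_t)r * net.n_species + i];
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["state"] = sm);
}
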