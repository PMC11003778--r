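// Native Wright-Fisher engine for TE copy-number dynamics.
//
// A genome is n_chroms chromosomes x 2 homologs, each a sorted vector of
// integer insertion positions.  The per-generation cycle is:
// fitness-weighted parent sampling -> recombinant gametes -> offspring ->
// silencing draw -> transposition -> ectopic viability -> fitness.
//
// Silencing magnitudes M_i ~ Poisson(a' n) are drawn per copy only when a
// consumer needs the per-copy values (b > 0 together with k > 0,
// multiplicative fitness with b > 0, or threshold suppression of ectopic
// recombination alongside b/k effects).  Otherwise the exact aggregate
// distributions are used: sum(M) ~ Poisson(a' n^2) for additive fitness,
// and a duplication count ~ Binomial(n, u E[(1-kM)^+]) for transposition.
// All randomness comes from R's RNG, so R-level seeds govern every run.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

// Inline xoshiro256+ uniform generator for the hot loops (gamete walks,
// coin flips, insertion placement).  Re-seeded from R's RNG at every
// engine entry point, so R-level set.seed() fully determines all output;
// low-volume draws (Poisson, binomial) stay on R's generators.
struct FastRng {
  uint64_t s[4];
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = static_cast<uint64_t>(unif_rand() * 4294967296.0);
      uint64_t lo = static_cast<uint64_t>(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    for (int i = 0; i < 16; ++i) next();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {  // uniform in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline bool coin() { return next() >> 63; }
};

FastRng g_rng;

struct Cfg {
  int N;
  double u, s, r;
  int mode;              // 0 additive, 1 multiplicative, 2 synergistic
  double a, b, k;
  int n0;
  double L;              // chromosome length (bp)
  int n_chroms;
  int mod_dir;           // 0 none, 1 enhance, 2 weaken
  int mod_chrom;
  double mod_pos;
  double re;
  bool suppress;
  double T;
};

Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.N = as<int>(cfg["N"]);
  c.u = as<double>(cfg["u"]);
  c.s = as<double>(cfg["s"]);
  c.r = as<double>(cfg["r"]);
  std::string mode = as<std::string>(cfg["fitness_mode"]);
  c.mode = mode == "additive" ? 0 : (mode == "multiplicative" ? 1 : 2);
  c.a = as<double>(cfg["a"]);
  c.b = as<double>(cfg["b"]);
  c.k = as<double>(cfg["k"]);
  c.n0 = as<int>(cfg["n0"]);
  c.L = as<double>(cfg["chrom_length"]);
  c.n_chroms = as<int>(cfg["n_chroms"]);
  std::string dir = as<std::string>(cfg["modifier_direction"]);
  c.mod_dir = dir == "none" ? 0 : (dir == "enhance" ? 1 : 2);
  c.mod_chrom = as<int>(cfg["modifier_chrom"]);
  c.mod_pos = as<double>(cfg["modifier_pos"]);
  c.re = as<double>(cfg["r_e"]);
  c.suppress = as<bool>(cfg["ectopic_suppression"]);
  c.T = as<double>(cfg["T"]);
  return c;
}

struct Ind {
  std::vector<std::vector<int>> g;   // [chrom * 2 + homolog] sorted positions
  std::vector<std::vector<int>> M;   // parallel magnitudes (only if per-copy)
  int mod[2];                        // modifier allele per homolog
  int sex;                           // 0 female, 1 male
  double W;
  bool has_M;

  void init(int n_chroms) {
    g.assign(2 * n_chroms, {});
    M.clear();
    mod[0] = mod[1] = 0;
    sex = 0;
    W = -1.0;
    has_M = false;
  }
  int copy_number() const {
    size_t n = 0;
    for (const auto& v : g) n += v.size();
    return static_cast<int>(n);
  }
};

// does (chrom, pos) exist on homolog h?
inline bool occupied(const Ind& ind, int chrom, int h, int pos) {
  const auto& v = ind.g[2 * chrom + h];
  return std::binary_search(v.begin(), v.end(), pos);
}

double a_effective(const Cfg& cfg, const Ind& ind) {
  if (cfg.mod_dir == 0) return cfg.a;
  double H = (ind.mod[0] + ind.mod[1]) / 2.0;
  return cfg.mod_dir == 1 ? cfg.a * (1.0 + 0.5 * H) : cfg.a * (1.0 - 0.5 * H);
}

// E[(1 - k M)^+] for M ~ Poisson(lambda)
double mean_clamped_suppression(double k, double lambda) {
  if (k <= 0.0) return 1.0;
  double acc = 0.0;
  for (int m = 0; k * m < 1.0; ++m)
    acc += (1.0 - k * m) * R::dpois(m, lambda, 0);
  return acc;
}

// one recombinant haploid genome; fills `sites` (one sorted vector per
// chromosome) and returns the transmitted modifier allele
int make_gamete_impl(const Cfg& cfg, const Ind& parent,
                     std::vector<std::vector<int>>& sites) {
  sites.assign(cfg.n_chroms, {});
  int mod_allele = 0;
  std::vector<double> bp;
  for (int c = 0; c < cfg.n_chroms; ++c) {
    int cur = unif_rand() < 0.5 ? 0 : 1;
    int n_x = static_cast<int>(R::rpois(cfg.r * cfg.L));
    const auto& v0 = parent.g[2 * c];
    const auto& v1 = parent.g[2 * c + 1];
    auto& out = sites[c];
    if (n_x == 0) {
      out = cur == 0 ? v0 : v1;
      if (c == cfg.mod_chrom) mod_allele = parent.mod[cur];
      continue;
    }
    bp.clear();
    for (int i = 0; i < n_x; ++i) bp.push_back(unif_rand() * cfg.L);
    std::sort(bp.begin(), bp.end());
    bp.push_back(cfg.L + 1.0);
    out.reserve(std::max(v0.size(), v1.size()));
    size_t i0 = 0, i1 = 0;
    double prev = -1.0;
    for (double bnd : bp) {
      if (c == cfg.mod_chrom && prev <= cfg.mod_pos && cfg.mod_pos < bnd)
        mod_allele = parent.mod[cur];
      const auto& src = cur == 0 ? v0 : v1;
      size_t& idx = cur == 0 ? i0 : i1;
      while (idx < src.size() && src[idx] < prev) ++idx;
      while (idx < src.size() && src[idx] < bnd) out.push_back(src[idx++]);
      cur ^= 1;
      prev = bnd;
    }
  }
  return mod_allele;
}

// Engine gamete path: walk the union of relevant coordinates (parental TE
// positions and the modifier locus) in order and flip the active homolog
// between consecutive coordinates with the recombination fraction
// p = (1 - exp(-2 r d)) / 2 for a gap of d bp -- the probability of an odd
// Poisson(r d) crossover count.  Distributionally identical to drawing
// explicit Poisson breakpoints (gametes depend on the parity of crossover
// counts between relevant sites only), but O(copies) without a sort.
// Interpolation table for p(x) = (1 - exp(-x)) / 2 with x = 2 r d, built
// once per engine entry; linear interpolation on 4096 bins over [0, 20]
// keeps the absolute error below 2e-6 (x >= 20 saturates at 1/2).
struct SwitchTable {
  static constexpr double XMAX = 20.0;
  static constexpr int NBIN = 4096;
  std::vector<double> p;
  void build() {
    p.resize(NBIN + 2);
    for (int i = 0; i <= NBIN + 1; ++i)
      p[i] = -0.5 * std::expm1(-XMAX * i / NBIN);
  }
  inline double operator()(double x) const {
    if (x >= XMAX) return 0.5;
    double t = x * (NBIN / XMAX);
    int i = static_cast<int>(t);
    double f = t - i;
    return p[i] * (1.0 - f) + p[i + 1] * f;
  }
};

SwitchTable g_switch;

inline bool switch_homolog(double r, double d) {
  if (r <= 0.0 || d <= 0.0) return false;
  return g_rng.runif() < g_switch(2.0 * r * d);
}

int make_gamete_walk(const Cfg& cfg, const Ind& parent, Ind& child,
                     int which) {
  int mod_allele = 0;
  const double INF = std::numeric_limits<double>::infinity();
  for (int c = 0; c < cfg.n_chroms; ++c) {
    const auto& v0 = parent.g[2 * c];
    const auto& v1 = parent.g[2 * c + 1];
    int cur = g_rng.coin() ? 1 : 0;
    bool mod_pending = (c == cfg.mod_chrom);
    auto& out = child.g[2 * c + which];
    if (v0.empty() && v1.empty()) {
      if (mod_pending) {
        if (switch_homolog(cfg.r, cfg.mod_pos)) cur ^= 1;
        mod_allele = parent.mod[cur];
      }
      continue;
    }
    out.reserve(std::max(v0.size(), v1.size()));
    size_t i0 = 0, i1 = 0;
    double prev = 0.0;
    while (i0 < v0.size() || i1 < v1.size() || mod_pending) {
      double p0 = i0 < v0.size() ? v0[i0] : INF;
      double p1 = i1 < v1.size() ? v1[i1] : INF;
      double pm = mod_pending ? cfg.mod_pos : INF;
      double p = std::min(p0, std::min(p1, pm));
      if (switch_homolog(cfg.r, p - prev)) cur ^= 1;
      prev = p;
      if (pm == p) {
        mod_allele = parent.mod[cur];
        mod_pending = false;
      }
      bool on0 = (p0 == p), on1 = (p1 == p);
      if ((cur == 0 && on0) || (cur == 1 && on1))
        out.push_back(static_cast<int>(p));
      if (on0) ++i0;
      if (on1) ++i1;
    }
  }
  return mod_allele;
}

// insert a new copy keeping position (and optional M) vectors sorted
void insert_copy(Ind& ind, int chrom, int h, int pos, int m_val) {
  auto& v = ind.g[2 * chrom + h];
  auto it = std::lower_bound(v.begin(), v.end(), pos);
  size_t at = it - v.begin();
  v.insert(it, pos);
  if (ind.has_M) {
    auto& mv = ind.M[2 * chrom + h];
    mv.insert(mv.begin() + at, m_val);
  }
}

void place_new_copies(const Cfg& cfg, Ind& ind, int n_new) {
  for (int j = 0; j < n_new; ++j) {
    for (int tries = 0;; ++tries) {
      if (tries > 1000000)
        stop("genome saturated: no free insertion site found");
      int chrom = std::min(cfg.n_chroms - 1,
                           static_cast<int>(g_rng.runif() * cfg.n_chroms));
      int h = g_rng.coin() ? 1 : 0;
      int pos = std::min(static_cast<int>(cfg.L) - 1,
                         static_cast<int>(g_rng.runif() * cfg.L));
      if (!occupied(ind, chrom, h, pos)) {
        insert_copy(ind, chrom, h, pos, 0);
        break;
      }
    }
  }
}

// Silencing draw + (optional) transposition + ectopic viability + fitness.
void evaluate(const Cfg& cfg, Ind& ind, bool do_transpose) {
  int n_pre = ind.copy_number();
  if (n_pre == 0) {
    ind.W = 1.0;
    return;
  }
  double a_eff = a_effective(cfg, ind);
  double lambda = a_eff * n_pre;
  bool need_any_M = cfg.b > 0 || cfg.k > 0 || (cfg.re > 0 && cfg.suppress);
  bool percopy = need_any_M &&
    ((cfg.b > 0 && cfg.k > 0) || (cfg.mode == 1 && cfg.b > 0) ||
     (cfg.suppress && cfg.re > 0 && (cfg.b > 0 || cfg.k > 0)));

  double sumM = 0.0;
  if (percopy) {
    ind.has_M = true;
    ind.M.assign(ind.g.size(), {});
    for (size_t vi = 0; vi < ind.g.size(); ++vi) {
      ind.M[vi].resize(ind.g[vi].size());
      for (size_t j = 0; j < ind.g[vi].size(); ++j) {
        int m = static_cast<int>(R::rpois(lambda));
        ind.M[vi][j] = m;
        sumM += m;
      }
    }
  } else if (cfg.b > 0) {
    // sum of n iid Poisson(lambda) magnitudes
    sumM = R::rpois(static_cast<double>(n_pre) * lambda);
  }

  int n_new = 0;
  if (do_transpose && cfg.u > 0) {
    if (percopy && cfg.k > 0) {
      for (size_t vi = 0; vi < ind.g.size(); ++vi)
        for (size_t j = 0; j < ind.M[vi].size(); ++j) {
          double ui = cfg.u * std::max(0.0, 1.0 - cfg.k * ind.M[vi][j]);
          if (ui > 0 && g_rng.runif() < ui) ++n_new;
        }
    } else if (cfg.k > 0) {
      double q = cfg.u * mean_clamped_suppression(cfg.k, lambda);
      n_new = static_cast<int>(R::rbinom(n_pre, q));
    } else {
      n_new = static_cast<int>(R::rbinom(n_pre, cfg.u));
    }
    place_new_copies(cfg, ind, n_new);
  }
  int n_post = n_pre + n_new;

  double W;
  if (cfg.mode == 0) {                     // additive
    W = 1.0 - cfg.s * n_post - cfg.s * cfg.b * sumM;
  } else if (cfg.mode == 1) {              // multiplicative
    if (cfg.b > 0) {
      // per-copy magnitudes cover all n_post copies (newborns carry M = 0)
      W = 1.0;
      for (size_t vi = 0; vi < ind.g.size() && W > 0; ++vi)
        for (size_t j = 0; j < ind.M[vi].size(); ++j)
          W *= std::max(0.0, 1.0 - cfg.s * (1.0 + cfg.b * ind.M[vi][j]));
    } else {
      W = std::pow(1.0 - cfg.s, n_post);
    }
  } else {                                  // synergistic
    W = 1.0 - cfg.s * static_cast<double>(n_post) * n_post;
  }
  if (W < 0.0) W = 0.0;
  if (W > 1.0) W = 1.0;

  if (cfg.re > 0 && W > 0) {
    long long elig = 0;
    if (cfg.suppress && percopy) {
      for (size_t vi = 0; vi < ind.g.size(); ++vi) {
        int chrom = static_cast<int>(vi / 2);
        int other = static_cast<int>(vi % 2) ^ 1;
        for (size_t j = 0; j < ind.g[vi].size(); ++j) {
          if (ind.M[vi][j] <= cfg.T &&
              !occupied(ind, chrom, other, ind.g[vi][j]))
            ++elig;
        }
      }
    } else {
      long long het = 0;
      for (size_t vi = 0; vi < ind.g.size(); ++vi) {
        int chrom = static_cast<int>(vi / 2);
        int other = static_cast<int>(vi % 2) ^ 1;
        for (size_t j = 0; j < ind.g[vi].size(); ++j)
          if (!occupied(ind, chrom, other, ind.g[vi][j])) ++het;
      }
      if (cfg.suppress) {
        // magnitudes are independent of position; the eligible count among
        // het copies is Binomial(het, P(M <= T))
        double p_keep = R::ppois(cfg.T, lambda, 1, 0);
        elig = static_cast<long long>(R::rbinom(static_cast<double>(het),
                                                p_keep));
      } else {
        elig = het;
      }
    }
    long long pairs = elig * (elig - 1) / 2;
    if (pairs > 0) {
      double p_dead = 1.0 - std::exp(pairs * std::log1p(-cfg.re));
      if (g_rng.runif() < p_dead) W = 0.0;
    }
  }
  ind.W = W;
}

// ---- conversions between the R column representation and Ind ----

Ind ind_from_R(const Cfg& cfg, const IntegerMatrix& ins, int sex,
               int mod0, int mod1, double W) {
  Ind ind;
  ind.init(cfg.n_chroms);
  for (int i = 0; i < ins.nrow(); ++i) {
    int chrom = ins(i, 0), pos = ins(i, 1), h = ins(i, 2);
    if (chrom < 0 || chrom >= cfg.n_chroms)
      stop("insertion chromosome index out of range");
    if (h < 0 || h > 1) stop("homolog index must be 0 or 1");
    ind.g[2 * chrom + h].push_back(pos);
  }
  for (auto& v : ind.g) {
    std::sort(v.begin(), v.end());
    if (std::adjacent_find(v.begin(), v.end()) != v.end())
      stop("duplicate (chromosome, position, homolog) insertion");
  }
  ind.sex = sex;
  ind.mod[0] = mod0;
  ind.mod[1] = mod1;
  ind.W = W;
  return ind;
}

IntegerMatrix ind_to_R(const Ind& ind) {
  int n = ind.copy_number();
  IntegerMatrix out(n, 3);
  int row = 0;
  for (size_t vi = 0; vi < ind.g.size(); ++vi) {
    int chrom = static_cast<int>(vi / 2), h = static_cast<int>(vi % 2);
    for (int pos : ind.g[vi]) {
      out(row, 0) = chrom;
      out(row, 1) = pos;
      out(row, 2) = h;
      ++row;
    }
  }
  return out;
}

std::vector<Ind> pop_from_R(const Cfg& cfg, const List& parts) {
  List ins = parts["ins"];
  IntegerVector sex = parts["sex"];
  IntegerMatrix mod = parts["mod"];
  NumericVector fit = parts["fitness"];
  int n = ins.size();
  std::vector<Ind> pop;
  pop.reserve(n);
  for (int i = 0; i < n; ++i) {
    double W = NumericVector::is_na(fit[i]) ? -1.0 : fit[i];
    pop.push_back(ind_from_R(cfg, as<IntegerMatrix>(ins[i]), sex[i],
                             mod(i, 0), mod(i, 1), W));
  }
  return pop;
}

List pop_to_R(const std::vector<Ind>& pop, int generation) {
  int n = static_cast<int>(pop.size());
  List ins(n);
  IntegerVector sex(n);
  IntegerMatrix mod(n, 2);
  NumericVector fit(n);
  for (int i = 0; i < n; ++i) {
    ins[i] = ind_to_R(pop[i]);
    sex[i] = pop[i].sex;
    mod(i, 0) = pop[i].mod[0];
    mod(i, 1) = pop[i].mod[1];
    fit[i] = pop[i].W < 0 ? NA_REAL : pop[i].W;
  }
  return List::create(_["ins"] = ins, _["sex"] = sex, _["mod"] = mod,
                      _["fitness"] = fit, _["generation"] = generation);
}

// weighted parent index sampling: cumulative weights + binary search
struct WeightedSampler {
  std::vector<double> cum;
  std::vector<int> idx;
  double total = 0.0;

  void build(const std::vector<Ind>& pop, int sex) {
    cum.clear();
    idx.clear();
    total = 0.0;
    for (size_t i = 0; i < pop.size(); ++i) {
      if (pop[i].sex != sex) continue;
      total += pop[i].W;
      cum.push_back(total);
      idx.push_back(static_cast<int>(i));
    }
  }
  bool ok() const { return !cum.empty() && total > 0.0; }
  int draw() const {
    double x = g_rng.runif() * total;
    size_t j = std::lower_bound(cum.begin(), cum.end(), x) - cum.begin();
    if (j >= cum.size()) j = cum.size() - 1;
    return idx[j];
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_init_population(List cfg_list) {
  Cfg cfg = parse_cfg(cfg_list);
  g_switch.build();
  g_rng.seed_from_R();
  std::vector<Ind> pop(cfg.N);
  for (int i = 0; i < cfg.N; ++i) {
    pop[i].init(cfg.n_chroms);
    pop[i].sex = unif_rand() < 0.5 ? 0 : 1;
    for (int j = 0; j < cfg.n0; ++j) {
      for (;;) {
        int chrom = std::min(cfg.n_chroms - 1,
                             static_cast<int>(unif_rand() * cfg.n_chroms));
        int pos = std::min(static_cast<int>(cfg.L) - 1,
                           static_cast<int>(unif_rand() * cfg.L));
        // distinct (chromosome, position) sites within the individual
        if (occupied(pop[i], chrom, 0, pos) || occupied(pop[i], chrom, 1, pos))
          continue;
        int h = unif_rand() < 0.5 ? 0 : 1;
        insert_copy(pop[i], chrom, h, pos, 0);
        break;
      }
    }
  }
  return pop_to_R(pop, 0);
}

// [[Rcpp::export]]
List cpp_make_gamete(List cfg_list, IntegerMatrix ins, IntegerVector mod,
                     std::string method = "breakpoints") {
  Cfg cfg = parse_cfg(cfg_list);
  g_switch.build();
  g_rng.seed_from_R();
  Ind parent = ind_from_R(cfg, ins, 0, mod[0], mod[1], -1.0);
  std::vector<std::vector<int>> sites;
  int allele;
  if (method == "walk") {
    Ind child;
    child.init(cfg.n_chroms);
    allele = make_gamete_walk(cfg, parent, child, 0);
    sites.assign(cfg.n_chroms, {});
    for (int c = 0; c < cfg.n_chroms; ++c) sites[c] = child.g[2 * c];
  } else {
    allele = make_gamete_impl(cfg, parent, sites);
  }
  int n = 0;
  for (const auto& v : sites) n += static_cast<int>(v.size());
  IntegerMatrix out(n, 2);
  int row = 0;
  for (size_t c = 0; c < sites.size(); ++c)
    for (int pos : sites[c]) {
      out(row, 0) = static_cast<int>(c);
      out(row, 1) = pos;
      ++row;
    }
  return List::create(_["sites"] = out, _["modifier"] = allele);
}

// [[Rcpp::export]]
IntegerMatrix cpp_transpose_genome(List cfg_list, IntegerMatrix ins,
                                   NumericVector u_i) {
  Cfg cfg = parse_cfg(cfg_list);
  g_switch.build();
  g_rng.seed_from_R();
  Ind ind = ind_from_R(cfg, ins, 0, 0, 0, -1.0);
  if (u_i.size() != ins.nrow())
    stop("per-copy transposition rates must match the copy number");
  int n_new = 0;
  for (int i = 0; i < u_i.size(); ++i)
    if (u_i[i] > 0 && unif_rand() < u_i[i]) ++n_new;
  place_new_copies(cfg, ind, n_new);
  return ind_to_R(ind);
}

// [[Rcpp::export]]
double cpp_individual_fitness(List cfg_list, IntegerMatrix ins,
                              IntegerVector M) {
  // engine fitness with externally supplied magnitudes (no transposition,
  // no ectopic hazard); cross-check surface for the R implementation
  Cfg cfg = parse_cfg(cfg_list);
  g_switch.build();
  g_rng.seed_from_R();
  Ind ind = ind_from_R(cfg, ins, 0, 0, 0, -1.0);
  int n = ind.copy_number();
  if (n == 0) return 1.0;
  if (cfg.b > 0 && M.size() != n)
    stop("per-copy magnitudes must match the copy number");
  double W;
  if (cfg.mode == 0) {
    double sumM = 0.0;
    for (int i = 0; i < M.size(); ++i) sumM += M[i];
    W = 1.0 - cfg.s * n - (cfg.b > 0 ? cfg.s * cfg.b * sumM : 0.0);
  } else if (cfg.mode == 1) {
    if (cfg.b > 0) {
      W = 1.0;
      for (int i = 0; i < M.size(); ++i)
        W *= std::max(0.0, 1.0 - cfg.s * (1.0 + cfg.b * M[i]));
    } else {
      W = std::pow(1.0 - cfg.s, n);
    }
  } else {
    W = 1.0 - cfg.s * static_cast<double>(n) * n;
  }
  return std::min(1.0, std::max(0.0, W));
}

// [[Rcpp::export]]
List cpp_run_simulation(List cfg_list, Nullable<List> start, int n_generations,
                        int record_stride, bool return_population) {
  Cfg cfg = parse_cfg(cfg_list);
  g_switch.build();
  g_rng.seed_from_R();
  std::vector<Ind> pop;
  int gen0 = 0;
  if (start.isNotNull()) {
    List parts(start);
    pop = pop_from_R(cfg, parts);
    gen0 = as<int>(parts["generation"]);
  } else {
    List init = cpp_init_population(cfg_list);
    pop = pop_from_R(cfg, init);
  }
  int N = static_cast<int>(pop.size());

  // evaluate the starting cohort where fitness is not yet cached
  for (auto& ind : pop)
    if (ind.W < 0) evaluate(cfg, ind, /*do_transpose=*/false);

  std::vector<double> t_gen, t_cn, t_w, t_mod;
  std::string status = "completed";
  int gen = gen0;

  auto record = [&](int g) {
    double cn = 0.0, w = 0.0, mo = 0.0;
    for (const auto& ind : pop) {
      cn += ind.copy_number();
      w += ind.W;
      mo += ind.mod[0] + ind.mod[1];
    }
    cn /= N;
    w /= N;
    mo /= 2.0 * N;
    t_gen.push_back(g);
    t_cn.push_back(cn);
    t_w.push_back(w);
    t_mod.push_back(mo);
    return std::make_pair(cn, w);
  };

  auto st = record(gen);
  if (st.first <= 0.0) status = "te_loss";
  else if (st.second < 1e-3) status = "population_crash";

  WeightedSampler females, males;
  std::vector<Ind> next(N);

  if (status == "completed") {
    for (int t = 0; t < n_generations; ++t) {
      females.build(pop, 0);
      males.build(pop, 1);
      if (!females.ok() || !males.ok()) {
        status = "extinct";
        break;
      }
      for (int i = 0; i < N; ++i) {
        const Ind& mother = pop[females.draw()];
        const Ind& father = pop[males.draw()];
        Ind& child = next[i];
        child.init(cfg.n_chroms);
        child.mod[0] = make_gamete_walk(cfg, mother, child, 0);
        child.mod[1] = make_gamete_walk(cfg, father, child, 1);
        child.sex = g_rng.coin() ? 1 : 0;
        evaluate(cfg, child, /*do_transpose=*/true);
      }
      pop.swap(next);
      ++gen;
      bool last = (t == n_generations - 1);
      double cn = 0.0, w = 0.0;
      for (const auto& ind : pop) {
        cn += ind.copy_number();
        w += ind.W;
      }
      cn /= N;
      w /= N;
      bool terminal = false;
      if (cn <= 0.0) {
        status = "te_loss";
        terminal = true;
      } else if (w < 1e-3) {
        status = "population_crash";
        terminal = true;
      }
      if (last || terminal || ((gen - gen0) % record_stride == 0)) record(gen);
      if (terminal) break;
      if (t % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }

  int n_rows = static_cast<int>(t_gen.size());
  NumericMatrix traj(n_rows, 4);
  for (int i = 0; i < n_rows; ++i) {
    traj(i, 0) = t_gen[i];
    traj(i, 1) = t_cn[i];
    traj(i, 2) = t_w[i];
    traj(i, 3) = t_mod[i];
  }
  List out = List::create(_["trajectory"] = traj, _["status"] = status,
                          _["generations_run"] = gen);
  if (return_population) out["final_population"] = pop_to_R(pop, gen);
  return out;
}
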