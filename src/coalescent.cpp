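// Structured-coalescent engine for a two-population split model:
// backwards in time, a derived population (pop 2, "EU") merges into the
// ancestral population (pop 1, "AF") at T_split; pop 2 size interpolates
// exponentially between nu_eu (present) and nu_bot (at the split); pop 1
// has size nu_af until T_exp and the reference size 1 earlier. Migration
// is active for t < min(T_mig, T_split).
//
// Units: time in 2*N_ANC generations, sizes relative to N_ANC, so the
// pairwise coalescence rate within a population of relative size nu is
// 1/nu. Per-lineage backward migration rates are the scaled rates
// (2*N_ANC*m) of the forward direction into the lineage's current deme.
//
// Uses R's RNG (unif_rand/exp_rand) so set.seed() in R governs all draws.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Demog {
  double nu_af, nu_bot, nu_eu, T_exp, T_split, m_af, m_eu, T_mig;
  double beta; // log(nu_eu/nu_bot)/T_split: backward growth rate of 1/nu_eu(t)
};

static Demog unpack(const NumericVector& p) {
  Demog d;
  d.nu_af = p[0]; d.nu_bot = p[1]; d.nu_eu = p[2];
  d.T_exp = p[3]; d.T_split = p[4];
  d.m_af = p[5]; d.m_eu = p[6]; d.T_mig = p[7];
  d.beta = (std::isfinite(d.T_split) && d.T_split > 0.0)
    ? std::log(d.nu_eu / d.nu_bot) / d.T_split : 0.0;
  return d;
}

static inline int pick(int k) {
  int i = (int)std::floor(unif_rand() * k);
  return (i >= k) ? k - 1 : i;
}

// Simulate one genealogy. Fills parent (0-based index, -1 for root) and
// node times. Leaves 0..n1-1 are pop 1, n1..n1+n2-1 pop 2; internal nodes
// n..2n-2 are created in increasing time order, so parent index > child
// index always holds.
static void sim_tree(int n1, int n2, const Demog& d,
                     std::vector<int>& parent, std::vector<double>& tim) {
  const int n = n1 + n2;
  parent.assign(2 * n - 1, -1);
  tim.assign(2 * n - 1, 0.0);
  std::vector<int> af, eu;
  af.reserve(n); eu.reserve(n);
  for (int i = 0; i < n1; ++i) af.push_back(i);
  for (int i = n1; i < n; ++i) eu.push_back(i);

  double t = 0.0;
  int nxt = n;
  const double INF = std::numeric_limits<double>::infinity();

  while ((int)(af.size() + eu.size()) > 1) {
    const int kA = (int)af.size(), kE = (int)eu.size();
    double bnd = INF;
    if (t < d.T_mig && d.T_mig < bnd) bnd = d.T_mig;
    if (t < d.T_split && d.T_split < bnd) bnd = d.T_split;
    if (t < d.T_exp && d.T_exp < bnd) bnd = d.T_exp;

    const double nuA = (t < d.T_exp) ? d.nu_af : 1.0;
    const double rate_coalA = kA * (kA - 1) / 2.0 / nuA;
    const bool mig_on = (t < d.T_mig) && (t < d.T_split);
    const double rate_mig = mig_on ? (kA * d.m_af + kE * d.m_eu) : 0.0;
    const double rate_const = rate_coalA + rate_mig;

    double s_const = INF;
    if (rate_const > 0.0) s_const = exp_rand() / rate_const;

    double s_eu = INF;
    if (kE >= 2 && t < d.T_split) {
      const double C = kE * (kE - 1) / 2.0;
      const double E = exp_rand();
      if (std::fabs(d.beta) < 1e-12) {
        s_eu = E * d.nu_eu / C;
      } else {
        // invert the cumulative intensity of rate C/nu_eu(t),
        // nu_eu(t) = nu_eu * exp(-beta t)
        const double arg = std::exp(d.beta * t) + E * d.nu_eu * d.beta / C;
        s_eu = (arg > 0.0) ? std::log(arg) / d.beta - t : INF;
      }
    }

    const double s = (s_const < s_eu) ? s_const : s_eu;
    if (t + s >= bnd) {
      t = bnd;
      if (bnd == d.T_split) { // derived population merges into ancestral
        for (size_t i = 0; i < eu.size(); ++i) af.push_back(eu[i]);
        eu.clear();
      }
      continue;
    }
    t += s;

    if (s_eu < s_const) { // coalescence within pop 2
      int a = pick(kE); int x = eu[a]; eu[a] = eu.back(); eu.pop_back();
      int b = pick(kE - 1); int y = eu[b]; eu[b] = eu.back(); eu.pop_back();
      parent[x] = nxt; parent[y] = nxt; tim[nxt] = t;
      eu.push_back(nxt); ++nxt;
    } else {
      const double u = unif_rand() * rate_const;
      if (u < rate_coalA) { // coalescence within pop 1
        int a = pick(kA); int x = af[a]; af[a] = af.back(); af.pop_back();
        int b = pick(kA - 1); int y = af[b]; af[b] = af.back(); af.pop_back();
        parent[x] = nxt; parent[y] = nxt; tim[nxt] = t;
        af.push_back(nxt); ++nxt;
      } else if (u < rate_coalA + kA * d.m_af) { // pop1 lineage jumps to pop2
        int a = pick(kA); int x = af[a]; af[a] = af.back(); af.pop_back();
        eu.push_back(x);
      } else { // pop2 lineage jumps to pop1
        int a = pick(kE); int x = eu[a]; eu[a] = eu.back(); eu.pop_back();
        af.push_back(x);
      }
    }
  }
}

// Per-branch descendant counts (pop1 leaves, pop2 leaves) via one pass in
// index order (children precede parents).
static void leaf_counts(int n1, int n2, const std::vector<int>& parent,
                        std::vector<int>& c1, std::vector<int>& c2) {
  const int m = 2 * (n1 + n2) - 1;
  c1.assign(m, 0); c2.assign(m, 0);
  for (int i = 0; i < n1; ++i) c1[i] = 1;
  for (int i = n1; i < n1 + n2; ++i) c2[i] = 1;
  for (int v = 0; v < m - 1; ++v) {
    c1[parent[v]] += c1[v];
    c2[parent[v]] += c2[v];
  }
}

// [[Rcpp::export]]
List cpp_sim_trees(int n1, int n2, NumericVector pars, int n_reps) {
  Demog d = unpack(pars);
  List out(n_reps);
  std::vector<int> parent; std::vector<double> tim;
  for (int r = 0; r < n_reps; ++r) {
    sim_tree(n1, n2, d, parent, tim);
    out[r] = List::create(_["parent"] = IntegerVector(parent.begin(), parent.end()),
                          _["time"] = NumericVector(tim.begin(), tim.end()));
  }
  return out;
}

// Monte-Carlo expected joint SFS per unit theta: mean over replicates of
// the branch-category length matrix divided by 2, plus its standard error.
// [[Rcpp::export]]
List cpp_expected_jsfs(int n1, int n2, NumericVector pars, int n_reps) {
  Demog d = unpack(pars);
  const int nr = n1 + 1, nc = n2 + 1;
  NumericMatrix sum(nr, nc), sumsq(nr, nc), T(nr, nc);
  std::vector<int> parent, c1, c2; std::vector<double> tim;
  for (int r = 0; r < n_reps; ++r) {
    sim_tree(n1, n2, d, parent, tim);
    leaf_counts(n1, n2, parent, c1, c2);
    std::fill(T.begin(), T.end(), 0.0);
    const int m = 2 * (n1 + n2) - 1;
    for (int v = 0; v < m - 1; ++v)
      T(c1[v], c2[v]) += (tim[parent[v]] - tim[v]) * 0.5;
    for (int i = 0; i < nr * nc; ++i) {
      sum[i] += T[i]; sumsq[i] += T[i] * T[i];
    }
  }
  NumericMatrix mean(nr, nc), se(nr, nc);
  for (int i = 0; i < nr * nc; ++i) {
    mean[i] = sum[i] / n_reps;
    double var = (sumsq[i] - sum[i] * sum[i] / n_reps) / std::max(1, n_reps - 1);
    se[i] = std::sqrt(std::max(0.0, var) / n_reps);
  }
  return List::create(_["mean"] = mean, _["se"] = se, _["n_reps"] = n_reps);
}

// Fast path for likelihood evaluations: accumulates the mean of T/2 only
// (no per-replicate matrix, no standard errors).
// [[Rcpp::export]]
NumericMatrix cpp_jsfs_mean(int n1, int n2, NumericVector pars, int n_reps) {
  Demog d = unpack(pars);
  const int nr = n1 + 1, nc = n2 + 1;
  NumericMatrix sum(nr, nc);
  const int m = 2 * (n1 + n2) - 1;
  std::vector<int> parent, c1, c2; std::vector<double> tim;
  for (int r = 0; r < n_reps; ++r) {
    sim_tree(n1, n2, d, parent, tim);
    leaf_counts(n1, n2, parent, c1, c2);
    for (int v = 0; v < m - 1; ++v)
      sum(c1[v], c2[v]) += tim[parent[v]] - tim[v];
  }
  for (int i = 0; i < nr * nc; ++i) sum[i] /= 2.0 * n_reps;
  return sum;
}

// One row per non-root branch across independent loci:
// (locus, pop1 descendants, pop2 descendants, branch length).
// [[Rcpp::export]]
NumericMatrix cpp_branch_table(int n1, int n2, NumericVector pars, int n_loci) {
  Demog d = unpack(pars);
  const int m = 2 * (n1 + n2) - 1;
  NumericMatrix out((m - 1) * n_loci, 4);
  std::vector<int> parent, c1, c2; std::vector<double> tim;
  int row = 0;
  for (int l = 0; l < n_loci; ++l) {
    sim_tree(n1, n2, d, parent, tim);
    leaf_counts(n1, n2, parent, c1, c2);
    for (int v = 0; v < m - 1; ++v, ++row) {
      out(row, 0) = l + 1;
      out(row, 1) = c1[v];
      out(row, 2) = c2[v];
      out(row, 3) = tim[parent[v]] - tim[v];
    }
  }
  colnames(out) = CharacterVector::create("locus", "i", "j", "length");
  return out;
}
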