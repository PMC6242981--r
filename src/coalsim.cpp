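// Simulation core: forward Wright-Fisher trajectories under heterozygote
// advantage, structured coalescent conditional on a trajectory, and a batch
// path that turns prior draws into (pi_anc, pi_der, dxy) for rejection ABC.
//
// All randomness goes through R's RNG so set.seed() on the R side gives full
// reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Deterministic selection update for overdominance with w_het = 1,
// w_der_hom = 1 - s1, w_anc_hom = 1 - s2.
static inline double sel_update(double p, double w_der, double w_anc) {
  double q = 1.0 - p;
  double wbar = p * p * w_der + 2.0 * p * q + q * q * w_anc;
  return p * (p * w_der + q) / wbar;
}

// Forward WF trajectory from a single copy, conditioned on segregation
// (neither loss nor fixation) through n_gen generations. Writes the path in
// forward order (index 0 = origin) into `out`. Returns the number of
// rejected (absorbed) attempts, or -1 if max_rejects was hit.
static int wf_trajectory(double s1, double s2, int n_gen, int N,
                         int max_rejects, std::vector<double> &out) {
  const double w_der = 1.0 - s1, w_anc = 1.0 - s2;
  const double twoN = 2.0 * N;
  const double p0 = 1.0 / twoN;
  out.assign(n_gen + 1, 0.0);
  int rejects = 0;
  for (;;) {
    bool ok = true;
    double p = p0;
    out[0] = p0;
    for (int g = 1; g <= n_gen; ++g) {
      double pe = sel_update(p, w_der, w_anc);
      p = R::rbinom(twoN, pe) / twoN;
      if (p <= 0.0 || p >= 1.0) { ok = false; break; }
      out[g] = p;
    }
    if (ok) return rejects;
    if (++rejects >= max_rejects) return -1;
  }
}

// [[Rcpp::export(name = ".wf_trajectory_cpp")]]
List wf_trajectory_cpp(double s1, double s2, int n_gen, int N,
                       int max_rejects) {
  std::vector<double> buf;
  int rejects = wf_trajectory(s1, s2, n_gen, N, max_rejects, buf);
  if (rejects < 0)
    return List::create(_["freqs"] = R_NilValue, _["rejects"] = max_rejects);
  return List::create(_["freqs"] = NumericVector(buf.begin(), buf.end()),
                      _["rejects"] = rejects);
}

// Growing genealogy under construction. Leaves are 0..n-1 (ancestral class
// first), internal nodes appended as coalescences happen. `parent` is -1
// until a node coalesces; times are in generations before present.
struct Tree {
  std::vector<double> time;
  std::vector<int> parent;
  std::vector<int> a_below, d_below;  // leaves of each class beneath a node
  void init(int n_anc, int n_der) {
    int n = n_anc + n_der;
    time.assign(n, 0.0);
    parent.assign(n, -1);
    a_below.assign(n, 0);
    d_below.assign(n, 0);
    for (int i = 0; i < n_anc; ++i) a_below[i] = 1;
    for (int i = n_anc; i < n; ++i) d_below[i] = 1;
  }
  // merge the nodes listed in `ids` (>= 2 of them) at time t; returns new id
  int merge(const std::vector<int> &ids, double t) {
    int id = (int)time.size();
    int a = 0, d = 0;
    for (int c : ids) { parent[c] = id; a += a_below[c]; d += d_below[c]; }
    time.push_back(t);
    parent.push_back(-1);
    a_below.push_back(a);
    d_below.push_back(d);
    return id;
  }
};

// remove two random distinct entries from `act`, merge them, push the result
static void merge_random_pair(Tree &tr, std::vector<int> &act, double t) {
  int k = (int)act.size();
  int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
  int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
  if (j >= i) ++j;
  std::vector<int> pair = {act[i], act[j]};
  if (i < j) std::swap(i, j);      // remove larger index first
  act.erase(act.begin() + i);
  act.erase(act.begin() + j);
  act.push_back(tr.merge(pair, t));
}

static void merge_all(Tree &tr, std::vector<int> &act, double t) {
  if (act.size() < 2) return;
  int id = tr.merge(act, t);
  act.clear();
  act.push_back(id);
}

static inline double npairs(size_t k) { return 0.5 * k * (k - 1); }

// Structured coalescent conditional on a trajectory. `freqs` is in backward
// order: index 0 = present, last = origin (frequency 1/2N). With n_der = 0
// (or an empty trajectory) this is a plain Kingman coalescent of size N.
static void structured_genealogy(const std::vector<double> &freqs, int N,
                                 int n_anc, int n_der, Tree &tr) {
  tr.init(n_anc, n_der);
  std::vector<int> act_a, act_d;
  for (int i = 0; i < n_anc; ++i) act_a.push_back(i);
  for (int i = 0; i < n_der; ++i) act_d.push_back(n_anc + i);
  const double twoN = 2.0 * N;
  double t = 0.0;

  if (n_der > 0 && freqs.size() >= 1) {
    int n_gen = (int)freqs.size() - 1;
    // per-class cumulative hazards against unit-exponential thresholds
    double Hd = 0.0, Ha = 0.0;
    double Ed = exp_rand(), Ea = exp_rand();
    for (int g = 1; g < n_gen; ++g) {
      double x = freqs[g];
      if (act_d.size() >= 2) {
        double pd = 1.0 / (twoN * x);
        if (pd >= 1.0) {           // back to a single copy mid-path
          merge_all(tr, act_d, (double)g);
        } else {
          Hd += -npairs(act_d.size()) * std::log1p(-pd);
          if (Hd >= Ed) {
            merge_random_pair(tr, act_d, (double)g);
            Hd = 0.0; Ed = exp_rand();
          }
        }
      }
      if (act_a.size() >= 2) {
        double pa = 1.0 / (twoN * (1.0 - x));
        if (pa >= 1.0) {
          merge_all(tr, act_a, (double)g);
        } else {
          Ha += -npairs(act_a.size()) * std::log1p(-pa);
          if (Ha >= Ea) {
            merge_random_pair(tr, act_a, (double)g);
            Ha = 0.0; Ea = exp_rand();
          }
        }
      }
    }
    t = (double)n_gen;
    // allele origin: any derived lineages still distinct are forced to merge
    merge_all(tr, act_d, t);
    // the surviving derived lineage joins the ancestral class at the origin
    for (int id : act_d) act_a.push_back(id);
    act_d.clear();
  }

  // single-class Kingman phase, geometric waiting times
  while (act_a.size() >= 2) {
    double P = 1.0 - std::pow(1.0 - 1.0 / twoN, npairs(act_a.size()));
    t += 1.0 + R::rgeom(P);
    merge_random_pair(tr, act_a, t);
  }
}

// [[Rcpp::export(name = ".structured_genealogy_cpp")]]
List structured_genealogy_cpp(NumericVector freqs, int N, int n_anc,
                              int n_der) {
  std::vector<double> f(freqs.begin(), freqs.end());
  Tree tr;
  structured_genealogy(f, N, n_anc, n_der, tr);
  return List::create(
      _["time"] = NumericVector(tr.time.begin(), tr.time.end()),
      _["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
      _["a_below"] = IntegerVector(tr.a_below.begin(), tr.a_below.end()),
      _["d_below"] = IntegerVector(tr.d_below.begin(), tr.d_below.end()));
}

// Batch path for ABC: one trajectory + genealogy + Poisson mutation counts
// per prior draw, reduced straight to the three summary statistics without
// materialising haplotype matrices. params columns: S, f_eq, T_age.
// Returns columns pi_anc, pi_der, dxy, rejects (NA row = failed draw).
// [[Rcpp::export(name = ".abc_table_cpp")]]
NumericMatrix abc_table_cpp(NumericMatrix params, int N, int n_anc, int n_der,
                            double theta, double L, int max_rejects) {
  int n = params.nrow();
  NumericMatrix out(n, 4);
  std::vector<double> traj;
  Tree tr;
  const double mu = theta / (4.0 * N);       // per bp per generation
  const double pairs_a = npairs(n_anc), pairs_d = npairs(n_der);
  for (int r = 0; r < n; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    double S = params(r, 0), f = params(r, 1), T = params(r, 2);
    double s2 = S / (4.0 * N), s1 = s2 * (1.0 - f) / f;
    int n_gen = (int)std::lround(T * 4.0 * N);
    bool fail = (s1 >= 1.0 || s2 >= 1.0);
    int rejects = 0;
    if (!fail) {
      rejects = wf_trajectory(s1, s2, n_gen, N, max_rejects, traj);
      fail = (rejects < 0);
    }
    if (fail) {
      out(r, 0) = NA_REAL; out(r, 1) = NA_REAL; out(r, 2) = NA_REAL;
      out(r, 3) = NA_REAL;
      continue;
    }
    std::reverse(traj.begin(), traj.end());  // backward order for coalescent
    structured_genealogy(traj, N, n_anc, n_der, tr);
    double sa = 0.0, sd = 0.0, sx = 0.0;
    int nn = (int)tr.time.size();
    for (int v = 0; v < nn; ++v) {
      int p = tr.parent[v];
      if (p < 0) continue;                   // root
      double len = tr.time[p] - tr.time[v];
      if (len <= 0.0) continue;
      double m = R::rpois(len * mu * L);
      if (m == 0.0) continue;
      double a = tr.a_below[v], d = tr.d_below[v];
      sa += m * a * (n_anc - a);
      sd += m * d * (n_der - d);
      sx += m * (a * (n_der - d) + d * (n_anc - a));
    }
    out(r, 0) = pairs_a > 0 ? sa / (pairs_a * L) : NA_REAL;
    out(r, 1) = pairs_d > 0 ? sd / (pairs_d * L) : NA_REAL;
    out(r, 2) = (n_anc > 0 && n_der > 0)
                    ? sx / ((double)n_anc * n_der * L) : NA_REAL;
    out(r, 3) = rejects;
  }
  colnames(out) = CharacterVector::create("pi_anc", "pi_der", "dxy",
                                          "rejects");
  return out;
}
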