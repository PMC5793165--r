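// Score-based greedy DAG search (hill climbing) with a linear-Gaussian
// BIC score, plus the nonparametric bootstrap over rows used for edge
// strengths. Family scores are computed from the Gram matrix of the
// centred data, so a family rescore is a k x k solve with k <= the
// parent cap.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double IMPROVE_TOL = 1e-9;

// BIC family score of node j given parents `par`. Parameters counted:
// |par| coefficients + intercept + residual variance.
double family_score(const arma::mat &G, double n, int j,
                    const std::vector<int> &par, double logn,
                    bool &ridge_used) {
  double rss;
  const int k = (int)par.size();
  if (k == 0) {
    rss = G(j, j);
  } else {
    arma::uvec P(k);
    arma::vec spj(k);
    for (int i = 0; i < k; ++i) {
      P[i] = par[i];
      spj[i] = G(par[i], j);
    }
    arma::mat Spp = G.submat(P, P);
    arma::vec beta;
    bool ok = arma::solve(beta, Spp, spj,
                          arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok) {
      ridge_used = true;
      arma::solve(beta, Spp + 1e-8 * arma::eye(k, k), spj);
    }
    rss = G(j, j) - arma::dot(spj, beta);
  }
  double sigma2 = rss / n;
  if (sigma2 < 1e-12) sigma2 = 1e-12;
  return -0.5 * n * (std::log(2.0 * M_PI * sigma2) + 1.0) -
         0.5 * logn * (k + 2);
}

struct Climber {
  int p;
  double n, logn;
  int max_parents;
  const arma::mat &G;
  std::vector<std::vector<int>> par, ch;
  arma::Mat<unsigned char> adj;
  arma::vec fam;
  arma::mat gainAdd, gainDel; // gainAdd(i,j): score gain of i -> par(j)
  bool ridge_used = false;
  std::vector<double> trace;

  Climber(const arma::mat &G_, double n_, int max_parents_)
      : G(G_), n(n_), logn(std::log(n_)), max_parents(max_parents_) {
    p = G.n_rows;
  }

  void init(const arma::Mat<unsigned char> &start) {
    adj = start;
    par.assign(p, {});
    ch.assign(p, {});
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (adj(i, j)) {
          par[j].push_back(i);
          ch[i].push_back(j);
        }
    fam.set_size(p);
    gainAdd.set_size(p, p);
    gainDel.set_size(p, p);
    for (int j = 0; j < p; ++j) refresh_node(j);
    trace.clear();
    trace.push_back(arma::accu(fam));
  }

  // recompute fam[j] and column j of the gain tables
  void refresh_node(int j) {
    fam[j] = family_score(G, n, j, par[j], logn, ridge_used);
    for (int i = 0; i < p; ++i) {
      gainAdd(i, j) = NA_REAL;
      gainDel(i, j) = NA_REAL;
      if (i == j) continue;
      if (adj(i, j)) {
        std::vector<int> q;
        for (int x : par[j]) if (x != i) q.push_back(x);
        gainDel(i, j) = family_score(G, n, j, q, logn, ridge_used) - fam[j];
      } else {
        std::vector<int> q = par[j];
        q.push_back(i);
        gainAdd(i, j) = family_score(G, n, j, q, logn, ridge_used) - fam[j];
      }
    }
  }

  // is dst reachable from src, optionally ignoring edge (skip_from, skip_to)
  bool reachable(int src, int dst, int skip_from = -1, int skip_to = -1) const {
    if (src == dst) return true;
    std::vector<char> seen(p, 0);
    std::vector<int> stack{src};
    seen[src] = 1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      for (int w : ch[v]) {
        if (v == skip_from && w == skip_to) continue;
        if (w == dst) return true;
        if (!seen[w]) {
          seen[w] = 1;
          stack.push_back(w);
        }
      }
    }
    return false;
  }

  void set_edge(int i, int j, bool on) {
    if (on) {
      adj(i, j) = 1;
      par[j].push_back(i);
      ch[i].push_back(j);
    } else {
      adj(i, j) = 0;
      par[j].erase(std::find(par[j].begin(), par[j].end(), i));
      ch[i].erase(std::find(ch[i].begin(), ch[i].end(), j));
    }
  }

  // one greedy step; moves scanned in lexicographic (op, from, to) order
  // with a strict improvement rule, so the first best move wins ties
  bool step() {
    double best = IMPROVE_TOL;
    int bop = -1, bi = -1, bj = -1;
    for (int i = 0; i < p; ++i) // op 0: add i -> j
      for (int j = 0; j < p; ++j) {
        if (i == j || adj(i, j) || adj(j, i)) continue;
        if ((int)par[j].size() >= max_parents) continue;
        double d = gainAdd(i, j);
        if (d > best && !reachable(j, i)) {
          best = d; bop = 0; bi = i; bj = j;
        }
      }
    for (int i = 0; i < p; ++i) // op 1: delete i -> j
      for (int j = 0; j < p; ++j) {
        if (!adj(i, j)) continue;
        double d = gainDel(i, j);
        if (d > best) {
          best = d; bop = 1; bi = i; bj = j;
        }
      }
    for (int i = 0; i < p; ++i) // op 2: reverse i -> j
      for (int j = 0; j < p; ++j) {
        if (!adj(i, j)) continue;
        if ((int)par[i].size() >= max_parents) continue;
        double d = gainDel(i, j) + gainAdd(j, i);
        if (d > best && !reachable(i, j, i, j)) {
          best = d; bop = 2; bi = i; bj = j;
        }
      }
    if (bop < 0) return false;
    if (bop == 0) {
      set_edge(bi, bj, true);
      refresh_node(bj);
    } else if (bop == 1) {
      set_edge(bi, bj, false);
      refresh_node(bj);
    } else {
      set_edge(bi, bj, false);
      set_edge(bj, bi, true);
      refresh_node(bi);
      refresh_node(bj);
    }
    trace.push_back(arma::accu(fam));
    return true;
  }

  bool climb(int max_iter) {
    for (int it = 0; it < max_iter; ++it)
      if (!step()) return true;
    return !step(); // converged iff no further move exists
  }

  double score() const { return arma::accu(fam); }
};

arma::Mat<unsigned char> random_dag(int p, int max_parents, std::mt19937 &rng) {
  std::vector<int> order(p);
  for (int i = 0; i < p; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  arma::Mat<unsigned char> adj(p, p, arma::fill::zeros);
  std::vector<int> npar(p, 0);
  double q = p > 1 ? std::min(1.0, 2.0 / (p - 1)) : 0.0;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int a = 0; a < p; ++a)
    for (int b = a + 1; b < p; ++b) {
      int i = order[a], j = order[b];
      if (npar[j] < max_parents && unif(rng) < q) {
        adj(i, j) = 1;
        ++npar[j];
      }
    }
  return adj;
}

arma::mat center_scale(const arma::mat &X) {
  arma::mat Z = X;
  for (arma::uword j = 0; j < Z.n_cols; ++j) {
    arma::vec c = Z.col(j);
    c -= arma::mean(c);
    double s = arma::stddev(c);
    if (s < 1e-12) c.zeros(); else c /= s;
    Z.col(j) = c;
  }
  return Z;
}

struct FitResult {
  arma::Mat<unsigned char> adj;
  double score;
  bool converged, ridge_used;
  std::vector<double> trace;
};

FitResult fit_one(const arma::mat &Z, int restarts, int max_iter,
                  int max_parents, unsigned int seed) {
  const int p = Z.n_cols;
  arma::mat G = Z.t() * Z;
  Climber cl(G, (double)Z.n_rows, max_parents);
  FitResult best;
  best.score = -std::numeric_limits<double>::infinity();
  best.converged = false;
  best.ridge_used = false;
  for (int r = 0; r < std::max(1, restarts); ++r) {
    arma::Mat<unsigned char> start(p, p, arma::fill::zeros);
    if (r > 0) {
      std::mt19937 rng(seed + 7919u * (unsigned)r);
      start = random_dag(p, max_parents, rng);
    }
    cl.init(start);
    bool conv = cl.climb(max_iter);
    if (cl.score() > best.score) {
      best.adj = cl.adj;
      best.score = cl.score();
      best.converged = conv;
      best.trace = cl.trace;
    }
  }
  best.ridge_used = cl.ridge_used;
  return best;
}

} // namespace

// [[Rcpp::export]]
List hc_fit(const arma::mat &X, int restarts, int max_iter, int max_parents,
            int seed) {
  arma::mat Z = center_scale(X);
  FitResult res = fit_one(Z, restarts, max_iter, max_parents,
                          (unsigned)seed);
  IntegerMatrix adj(Z.n_cols, Z.n_cols);
  for (arma::uword i = 0; i < Z.n_cols; ++i)
    for (arma::uword j = 0; j < Z.n_cols; ++j)
      adj(i, j) = res.adj(i, j);
  return List::create(_["adj"] = adj, _["score"] = res.score,
                      _["converged"] = res.converged,
                      _["ridge_used"] = res.ridge_used,
                      _["trace"] = NumericVector(res.trace.begin(),
                                                 res.trace.end()));
}

// [[Rcpp::export]]
IntegerMatrix hc_bootstrap(const arma::mat &X, int R, int restarts,
                           int max_iter, int max_parents, int seed,
                           bool identity_resample) {
  const int n = X.n_rows, p = X.n_cols;
  IntegerMatrix count(p, p);
  for (int r = 0; r < R; ++r) {
    arma::mat Xb(n, p);
    if (identity_resample) {
      Xb = X;
    } else {
      std::mt19937 rng((unsigned)seed + 15485863u * (unsigned)(r + 1));
      std::uniform_int_distribution<int> pick(0, n - 1);
      for (int i = 0; i < n; ++i) Xb.row(i) = X.row(pick(rng));
    }
    arma::mat Z = center_scale(Xb);
    FitResult res = fit_one(Z, restarts, max_iter, max_parents,
                            (unsigned)seed + 15485863u * (unsigned)(r + 1) + 7u);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (res.adj(i, j)) count(i, j) += 1;
  }
  return count;
}
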