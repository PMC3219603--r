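// Relaxed-clock node dating on a fixed rooted topology.
//
// Likelihood: Felsenstein pruning over compressed site patterns with a
// reversible substitution model given by its stationary frequencies and
// exchangeabilities (JC/K80/HKY/GTR are all instances). Branch length in
// expected substitutions/site = (parent age - child age) * mu * m[edge],
// with m[edge] iid lognormal (mean 1, log-sd sigma): the uncorrelated
// lognormal relaxed clock.
//
// Sampler: Metropolis-Hastings sweeps. Node-age sliding windows reflected
// at order constraints; multiplicative proposals for rates; partial
// likelihoods are cached per node and only the path from the touched node
// to the root is recomputed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Model {
  arma::mat U, Uinv;
  arma::vec lam, pi;
};

// Build normalized reversible Q from exchangeabilities r (AC,AG,AT,CG,CT,GT)
// and frequencies pi; eigendecompose via the symmetrized form.
static Model build_model(const arma::vec &r, const arma::vec &pi) {
  arma::mat Q(4, 4, arma::fill::zeros);
  int idx = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      Q(i, j) = r(idx) * pi(j);
      Q(j, i) = r(idx) * pi(i);
      ++idx;
    }
  for (int i = 0; i < 4; ++i) {
    double s = 0;
    for (int j = 0; j < 4; ++j) if (j != i) s += Q(i, j);
    Q(i, i) = -s;
  }
  double mean_rate = 0;
  for (int i = 0; i < 4; ++i) mean_rate -= pi(i) * Q(i, i);
  Q /= mean_rate;
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = arma::diagmat(sq) * Q * arma::diagmat(1.0 / sq);
  B = 0.5 * (B + B.t());
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, B);
  Model m;
  m.U = arma::diagmat(1.0 / sq) * evec;
  m.Uinv = evec.t() * arma::diagmat(sq);
  m.lam = eval;
  m.pi = pi;
  return m;
}

static void pmat_into(const Model &m, double t, arma::mat &P) {
  if (t < 0) t = 0;
  double ex[4];
  for (int k = 0; k < 4; ++k) ex[k] = std::exp(m.lam(k) * t);
  const double *U = m.U.memptr(), *V = m.Uinv.memptr();  // column-major
  double *out = P.memptr();
  for (int j = 0; j < 4; ++j) {
    for (int i = 0; i < 4; ++i) {
      double s = 0;
      for (int k = 0; k < 4; ++k) s += U[4 * k + i] * ex[k] * V[4 * j + k];
      out[4 * j + i] = s < 0 ? 0.0 : s;
    }
  }
}

static arma::mat pmat(const Model &m, double t) {
  arma::mat P(4, 4);
  pmat_into(m, t, P);
  return P;
}

struct State {
  int ntip, nnode, nn, root, nedge, npat;
  std::vector<int> parent, edge_of_child;          // by node id
  std::vector<std::vector<int>> kids;              // by node id
  std::vector<int> postorder;                      // internal nodes
  arma::vec ages;                                  // by node id (1-based)
  arma::vec mult;                                  // by edge
  double mu, sigma, kappa;
  std::vector<arma::mat> P;                        // by edge, 4x4
  std::vector<arma::mat> partial;                  // by node id, 4 x npat
  arma::imat pat;                                  // ntip x npat
  arma::mat work;                                  // 4 x npat scratch
  std::vector<arma::mat> bakPart;                  // preallocated partial backups
  std::vector<arma::mat> bakP;                     // preallocated P backups
  arma::vec w;
  double loglik;
  bool use_lik;
  Model mod;
};

class Engine {
public:
  IntegerMatrix edge;
  State S;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  double runif01() { return unif(rng); }

  std::vector<int> path_buf, edges_buf;

  void set_P(int e) {
    int p = edge(e, 0), c = edge(e, 1);
    double t = (S.ages(p - 1) - S.ages(c - 1)) * S.mu * S.mult(e);
    pmat_into(S.mod, t, S.P[e]);
  }

  void compute_partial(int v) {
    arma::mat &out = S.partial[v - 1];
    bool first = true;
    for (int c : S.kids[v]) {
      int e = S.edge_of_child[c];
      const arma::mat &P = S.P[e];
      if (c <= S.ntip) {
        if (first) {
          for (int s = 0; s < S.npat; ++s) {
            int x = S.pat(c - 1, s);
            double *o = out.colptr(s);
            if (x < 4) {
              const double *p = P.colptr(x);
              o[0] = p[0]; o[1] = p[1]; o[2] = p[2]; o[3] = p[3];
            } else { // missing: factor of 1 (rows of P sum to 1)
              o[0] = o[1] = o[2] = o[3] = 1.0;
            }
          }
          first = false;
        } else {
          for (int s = 0; s < S.npat; ++s) {
            int x = S.pat(c - 1, s);
            if (x < 4) {
              const double *p = P.colptr(x);
              double *o = out.colptr(s);
              o[0] *= p[0]; o[1] *= p[1]; o[2] *= p[2]; o[3] *= p[3];
            }
          }
        }
      } else {
        const arma::mat &cp = S.partial[c - 1];
        const double *Pm = P.memptr();  // column-major 4x4
        if (first) {
          for (int s = 0; s < S.npat; ++s) {
            const double *q = cp.colptr(s);
            double *o = out.colptr(s);
            for (int i = 0; i < 4; ++i) {
              o[i] = Pm[i] * q[0] + Pm[4 + i] * q[1] +
                     Pm[8 + i] * q[2] + Pm[12 + i] * q[3];
            }
          }
          first = false;
        } else {
          for (int s = 0; s < S.npat; ++s) {
            const double *q = cp.colptr(s);
            double *o = out.colptr(s);
            for (int i = 0; i < 4; ++i) {
              o[i] *= Pm[i] * q[0] + Pm[4 + i] * q[1] +
                      Pm[8 + i] * q[2] + Pm[12 + i] * q[3];
            }
          }
        }
      }
    }
  }

  double root_loglik() {
    const arma::mat &rp = S.partial[S.root - 1];
    const double p0 = S.mod.pi(0), p1 = S.mod.pi(1),
                 p2 = S.mod.pi(2), p3 = S.mod.pi(3);
    double ll = 0;
    // weight-1 patterns dominate; accumulate their product with periodic
    // renormalisation and take a single log per chunk
    double prod = 1.0;
    int in_chunk = 0;
    for (int s = 0; s < S.npat; ++s) {
      const double *c = rp.colptr(s);
      double site = p0 * c[0] + p1 * c[1] + p2 * c[2] + p3 * c[3];
      if (site <= 0) return -INFINITY;
      if (S.w(s) == 1.0) {
        prod *= site;
        if (prod < 1e-200) {  // flush before underflow
          ll += std::log(prod);
          prod = 1.0;
        }
        in_chunk = 1;
      } else {
        ll += S.w(s) * std::log(site);
      }
    }
    if (in_chunk) ll += std::log(prod);
    return ll;
  }

  void full_likelihood() {
    if (!S.use_lik) { S.loglik = 0; return; }
    for (int e = 0; e < S.nedge; ++e) set_P(e);
    for (int v : S.postorder) compute_partial(v);
    S.loglik = root_loglik();
  }

  // recompute partials from node v (inclusive) up to the root
  void update_path(int v) {
    while (v > 0) {
      compute_partial(v);
      v = S.parent[v];
    }
  }

  const std::vector<int> &path_to_root(int v) {
    path_buf.clear();
    while (v > 0) { path_buf.push_back(v); v = S.parent[v]; }
    return path_buf;
  }

  // calibration lookup
  std::vector<double> cal_offset, cal_meanlog, cal_sdlog; // by node id (-1 = none)
  double mu_meanlog, mu_sdlog;
  bool sample_sigma_flag, sample_kappa_flag;
  double sigma_rate, kappa_meanlog, kappa_sdlog;

  double age_logprior(int v) {
    double lp = 0.0;
    // uniform-given-root tree prior: the conditional density of the other
    // internal ages is 1/Vol(order polytope) with Vol proportional to
    // R^(n-1); without this normalisation the polytope volume overwhelms
    // the calibration densities and ages drift without bound
    if (v == S.root && S.nnode > 1) {
      double R = S.ages(v - 1);
      if (R <= 0) return -INFINITY;
      lp -= (S.nnode - 1) * std::log(R);
    }
    if (cal_offset[v] < -0.5) return lp; // no calibration at this node
    double x = S.ages(v - 1) - cal_offset[v];
    if (x <= 0) return -INFINITY;
    double lx = std::log(x);
    double z = (lx - cal_meanlog[v]) / cal_sdlog[v];
    return lp - 0.5 * z * z - lx - std::log(cal_sdlog[v]) - 0.918938533204672742;
  }

  double dlnorm_log(double x, double meanlog, double sdlog) {
    if (x <= 0) return -INFINITY;
    double lx = std::log(x);
    double z = (lx - meanlog) / sdlog;
    return -0.5 * z * z - lx - std::log(sdlog) - 0.918938533204672742;
  }

  double log_prior() {
    double lp = 0;
    for (int v = S.ntip + 1; v <= S.nn; ++v) lp += age_logprior(v);
    for (int e = 0; e < S.nedge; ++e)
      lp += dlnorm_log(S.mult(e), -0.5 * S.sigma * S.sigma, S.sigma);
    lp += dlnorm_log(S.mu, mu_meanlog, mu_sdlog);
    if (sample_sigma_flag) lp += std::log(sigma_rate) - sigma_rate * S.sigma;
    if (sample_kappa_flag) lp += dlnorm_log(S.kappa, kappa_meanlog, kappa_sdlog);
    return lp;
  }

  void rebuild_model() {
    arma::vec r(6);
    r(0) = 1; r(1) = S.kappa; r(2) = 1; r(3) = 1; r(4) = S.kappa; r(5) = 1;
    S.mod = build_model(r, S.mod.pi);
  }

  // reflect x into [lo, hi] by exact modular folding (symmetric for any
  // window width); hi may be +inf (single reflection at lo)
  double reflect(double x, double lo, double hi) {
    if (std::isfinite(hi)) {
      double R = hi - lo;
      if (R <= 0) return lo;
      double d = x - lo, p = 2 * R;
      double y = d - std::floor(d / p) * p;
      if (y < 0) y += 2 * R;
      if (y > R) y = 2 * R - y;
      return lo + y;
    }
    if (x < lo) x = 2 * lo - x;
    return x;
  }
};

// [[Rcpp::export]]
List mcmc_date_cpp(IntegerMatrix edge, int ntip,
                   IntegerMatrix patterns, NumericVector weights,
                   bool use_likelihood,
                   NumericVector pi, NumericVector gtr_rates,
                   double kappa0, bool sample_kappa,
                   double kappa_meanlog, double kappa_sdlog,
                   NumericVector ages0, double mu0, double sigma0,
                   NumericVector mult0,
                   IntegerVector calib_node, NumericVector calib_offset,
                   NumericVector calib_meanlog, NumericVector calib_sdlog,
                   double mu_meanlog, double mu_sdlog,
                   bool sample_sigma, double sigma_rate,
                   int n_sweeps, int sample_every, int burnin_sweeps,
                   NumericVector w_age_node, double w_mult, double w_mu,
                   double w_kappa, double w_sigma, double w_scale,
                   int seed) {
  Engine E;
  E.edge = edge;
  State &S = E.S;
  S.nedge = edge.nrow();
  S.ntip = ntip;
  S.nn = 0;
  for (int e = 0; e < S.nedge; ++e)
    S.nn = std::max(S.nn, std::max(edge(e, 0), edge(e, 1)));
  S.nnode = S.nn - ntip;
  S.root = ntip + 1;
  S.parent.assign(S.nn + 1, 0);
  S.edge_of_child.assign(S.nn + 1, -1);
  S.kids.assign(S.nn + 1, {});
  for (int e = 0; e < S.nedge; ++e) {
    S.parent[edge(e, 1)] = edge(e, 0);
    S.edge_of_child[edge(e, 1)] = e;
    S.kids[edge(e, 0)].push_back(edge(e, 1));
  }
  // postorder over internal nodes
  {
    std::vector<int> stack = {S.root}, order;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      for (int c : S.kids[v]) if (c > S.ntip) stack.push_back(c);
    }
    S.postorder.assign(order.rbegin(), order.rend());
  }
  S.npat = patterns.ncol();
  S.pat.set_size(ntip, std::max(S.npat, 1));
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < S.npat; ++s) S.pat(i, s) = patterns(i, s);
  S.w = as<arma::vec>(weights);
  S.use_lik = use_likelihood && S.npat > 0;
  S.ages.set_size(S.nn);
  S.ages.zeros();
  for (int k = 0; k < S.nnode; ++k) S.ages(ntip + k) = ages0[k];
  S.mu = mu0; S.sigma = sigma0; S.kappa = kappa0;
  S.mult = as<arma::vec>(mult0);
  S.P.assign(S.nedge, arma::mat(4, 4));
  S.partial.assign(S.nn, arma::mat(4, std::max(S.npat, 1)));
  S.work.set_size(4, std::max(S.npat, 1));
  S.bakPart.assign(S.nn + 1, arma::mat(4, std::max(S.npat, 1)));
  S.bakP.assign(8, arma::mat(4, 4));
  arma::vec piv = as<arma::vec>(pi);
  arma::vec rv = as<arma::vec>(gtr_rates);
  S.mod = build_model(rv, piv);
  if (sample_kappa) { E.S.kappa = kappa0; E.rebuild_model(); }

  E.cal_offset.assign(S.nn + 1, -1.0);
  E.cal_meanlog.assign(S.nn + 1, 0.0);
  E.cal_sdlog.assign(S.nn + 1, 1.0);
  for (int k = 0; k < calib_node.size(); ++k) {
    int v = calib_node[k];
    E.cal_offset[v] = calib_offset[k];
    E.cal_meanlog[v] = calib_meanlog[k];
    E.cal_sdlog[v] = calib_sdlog[k];
  }
  E.mu_meanlog = mu_meanlog; E.mu_sdlog = mu_sdlog;
  E.sample_sigma_flag = sample_sigma; E.sigma_rate = sigma_rate;
  E.sample_kappa_flag = sample_kappa;
  E.kappa_meanlog = kappa_meanlog; E.kappa_sdlog = kappa_sdlog;
  E.rng.seed(static_cast<uint64_t>(seed));

  E.full_likelihood();
  double logprior = E.log_prior();

  int n_samples = 0;
  for (int sw = burnin_sweeps; sw < n_sweeps; sw += sample_every) ++n_samples;
  NumericMatrix out(n_samples, S.nnode + 5);
  int row = 0;
  long acc = 0, tot = 0;

  std::vector<int> internal_nodes;
  for (int v = ntip + 1; v <= S.nn; ++v) internal_nodes.push_back(v);

  for (int sw = 0; sw < n_sweeps; ++sw) {
    // --- node ages ---
    for (int v : internal_nodes) {
      double lo = 0;
      for (int c : S.kids[v]) lo = std::max(lo, S.ages(c - 1));
      double hi = (v == S.root) ? INFINITY : S.ages(S.parent[v] - 1);
      double cur = S.ages(v - 1);
      double prop = E.reflect(cur + w_age_node[v - ntip - 1] * (E.runif01() - 0.5),
                              lo, hi);
      double lp_old = E.age_logprior(v);
      double ll_old = S.loglik;
      // save touched P and partials
      std::vector<int> &edges_touched = E.edges_buf;
      edges_touched.clear();
      if (v != S.root) edges_touched.push_back(S.edge_of_child[v]);
      for (int c : S.kids[v]) edges_touched.push_back(S.edge_of_child[c]);
      for (size_t k = 0; k < edges_touched.size(); ++k)
        S.bakP[k] = S.P[edges_touched[k]];
      const std::vector<int> &path = E.path_to_root(v);
      for (size_t k = 0; k < path.size(); ++k)
        S.bakPart[k] = S.partial[path[k] - 1];

      S.ages(v - 1) = prop;
      double lp_new = E.age_logprior(v);
      double lratio = lp_new - lp_old;
      if (S.use_lik) {
        for (int e : edges_touched) E.set_P(e);
        E.update_path(v);
        double ll_new = E.root_loglik();
        lratio += ll_new - ll_old;
        ++tot;
        if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
          S.loglik = ll_new; logprior += lp_new - lp_old; ++acc;
        } else {
          S.ages(v - 1) = cur;
          for (size_t k = 0; k < edges_touched.size(); ++k)
            S.P[edges_touched[k]] = S.bakP[k];
          for (size_t k = 0; k < path.size(); ++k)
            S.partial[path[k] - 1] = S.bakPart[k];
        }
      } else {
        ++tot;
        if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
          logprior += lp_new - lp_old; ++acc;
        } else {
          S.ages(v - 1) = cur;
        }
      }
    }
    // --- age-rate exchange: slide a node age, rescaling the multipliers of
    // adjacent branches so branch lengths (hence the likelihood) stay put ---
    for (int v : internal_nodes) {
      double lo = 0;
      for (int c : S.kids[v]) lo = std::max(lo, S.ages(c - 1));
      double hi = (v == S.root) ? INFINITY : S.ages(S.parent[v] - 1);
      double cur = S.ages(v - 1);
      double prop = E.reflect(cur + w_age_node[v - ntip - 1] * (E.runif01() - 0.5), lo, hi);
      std::vector<int> &adj = E.edges_buf;
      adj.clear();
      if (v != S.root) adj.push_back(S.edge_of_child[v]);
      for (int c : S.kids[v]) adj.push_back(S.edge_of_child[c]);
      bool feasible = true;
      double lp_old = E.age_logprior(v), lp_new, ljac = 0;
      double newm[8], savedm[8];
      for (size_t k = 0; k < adj.size(); ++k) {
        int e = adj[k];
        int p = edge(e, 0), c = edge(e, 1);
        double d_old = S.ages(p - 1) - S.ages(c - 1);
        double d_new = (c == v) ? S.ages(p - 1) - prop : prop - S.ages(c - 1);
        if (d_new <= 1e-12 || d_old <= 1e-12) { feasible = false; break; }
        newm[k] = S.mult(e) * d_old / d_new;
        ljac += std::log(d_old / d_new);
        lp_old += E.dlnorm_log(S.mult(e), -0.5 * S.sigma * S.sigma, S.sigma);
      }
      ++tot;
      if (!feasible) continue;
      double saved_age = cur;
      for (size_t k = 0; k < adj.size(); ++k) savedm[k] = S.mult(adj[k]);
      S.ages(v - 1) = prop;
      for (size_t k = 0; k < adj.size(); ++k) S.mult(adj[k]) = newm[k];
      lp_new = E.age_logprior(v);
      for (size_t k = 0; k < adj.size(); ++k)
        lp_new += E.dlnorm_log(S.mult(adj[k]), -0.5 * S.sigma * S.sigma, S.sigma);
      double lratio = lp_new - lp_old + ljac;
      if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
        logprior += lp_new - lp_old; ++acc;
      } else {
        S.ages(v - 1) = saved_age;
        for (size_t k = 0; k < adj.size(); ++k) S.mult(adj[k]) = savedm[k];
      }
    }
    // --- branch-rate multipliers ---
    for (int e = 0; e < S.nedge; ++e) {
      double cur = S.mult(e);
      double prop = cur * std::exp(w_mult * (E.runif01() - 0.5));
      double lp_old = E.dlnorm_log(cur, -0.5 * S.sigma * S.sigma, S.sigma);
      double lp_new = E.dlnorm_log(prop, -0.5 * S.sigma * S.sigma, S.sigma);
      double lratio = lp_new - lp_old + std::log(prop / cur);
      double ll_old = S.loglik;
      int c = edge(e, 1);
      int up = edge(e, 0);
      S.bakP[0] = S.P[e];
      const std::vector<int> &path = E.path_to_root(up);
      for (size_t k = 0; k < path.size(); ++k)
        S.bakPart[k] = S.partial[path[k] - 1];
      S.mult(e) = prop;
      if (S.use_lik) {
        E.set_P(e);
        E.update_path(up);
        double ll_new = E.root_loglik();
        lratio += ll_new - ll_old;
        ++tot;
        if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
          S.loglik = ll_new; logprior += lp_new - lp_old; ++acc;
        } else {
          S.mult(e) = cur;
          S.P[e] = S.bakP[0];
          for (size_t k = 0; k < path.size(); ++k)
            S.partial[path[k] - 1] = S.bakPart[k];
        }
      } else {
        ++tot;
        if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
          logprior += lp_new - lp_old; ++acc;
        } else {
          S.mult(e) = cur;
        }
      }
    }
    // --- global clock rate mu (full recompute) ---
    {
      double cur = S.mu;
      double prop = cur * std::exp(w_mu * (E.runif01() - 0.5));
      double lp_old = E.dlnorm_log(cur, mu_meanlog, mu_sdlog);
      double lp_new = E.dlnorm_log(prop, mu_meanlog, mu_sdlog);
      double lratio = lp_new - lp_old + std::log(prop / cur);
      double ll_old = S.loglik;
      S.mu = prop;
      E.full_likelihood();
      lratio += S.loglik - ll_old;
      ++tot;
      if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
        logprior += lp_new - lp_old; ++acc;
      } else {
        S.mu = cur;
        E.full_likelihood();
      }
    }
    // --- trade mu against all branch multipliers (branch lengths fixed) ---
    {
      double c = std::exp(w_scale * (E.runif01() - 0.5));
      double lp_old = E.dlnorm_log(S.mu, mu_meanlog, mu_sdlog);
      for (int e = 0; e < S.nedge; ++e)
        lp_old += E.dlnorm_log(S.mult(e), -0.5 * S.sigma * S.sigma, S.sigma);
      double saved_mu = S.mu;
      arma::vec saved_mult = S.mult;
      S.mu *= c;
      S.mult /= c;
      double lp_new = E.dlnorm_log(S.mu, mu_meanlog, mu_sdlog);
      for (int e = 0; e < S.nedge; ++e)
        lp_new += E.dlnorm_log(S.mult(e), -0.5 * S.sigma * S.sigma, S.sigma);
      double lratio = lp_new - lp_old + (1 - S.nedge) * std::log(c);
      ++tot;
      if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
        logprior += lp_new - lp_old; ++acc;
      } else {
        S.mu = saved_mu;
        S.mult = saved_mult;
      }
    }
    // --- joint scale of all node ages against mu ---
    // branch lengths (and hence the likelihood) are invariant; the move
    // walks along the age/rate ridge that single-parameter moves cross slowly
    {
      double c = std::exp(w_scale * (E.runif01() - 0.5));
      double lp_old = E.dlnorm_log(S.mu, mu_meanlog, mu_sdlog);
      for (int v = ntip + 1; v <= S.nn; ++v) lp_old += E.age_logprior(v);
      arma::vec saved_ages = S.ages;
      double saved_mu = S.mu;
      for (int v = ntip + 1; v <= S.nn; ++v) S.ages(v - 1) *= c;
      S.mu /= c;
      double lp_new = E.dlnorm_log(S.mu, mu_meanlog, mu_sdlog);
      for (int v = ntip + 1; v <= S.nn; ++v) lp_new += E.age_logprior(v);
      double lratio = lp_new - lp_old + (S.nnode - 1) * std::log(c);
      ++tot;
      if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
        logprior += lp_new - lp_old; ++acc;
      } else {
        S.ages = saved_ages;
        S.mu = saved_mu;
      }
    }
    // --- kappa ---
    if (sample_kappa) {
      double cur = S.kappa;
      double prop = cur * std::exp(w_kappa * (E.runif01() - 0.5));
      double lp_old = E.dlnorm_log(cur, kappa_meanlog, kappa_sdlog);
      double lp_new = E.dlnorm_log(prop, kappa_meanlog, kappa_sdlog);
      double lratio = lp_new - lp_old + std::log(prop / cur);
      double ll_old = S.loglik;
      S.kappa = prop;
      E.rebuild_model();
      E.full_likelihood();
      lratio += S.loglik - ll_old;
      ++tot;
      if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
        logprior += lp_new - lp_old; ++acc;
      } else {
        S.kappa = cur;
        E.rebuild_model();
        E.full_likelihood();
      }
    }
    // --- clock sd sigma (prior-only move) ---
    if (sample_sigma) {
      double cur = S.sigma;
      double prop = cur * std::exp(w_sigma * (E.runif01() - 0.5));
      double lp_old = std::log(sigma_rate) - sigma_rate * cur;
      double lp_new = std::log(sigma_rate) - sigma_rate * prop;
      for (int e = 0; e < S.nedge; ++e) {
        lp_old += E.dlnorm_log(S.mult(e), -0.5 * cur * cur, cur);
        lp_new += E.dlnorm_log(S.mult(e), -0.5 * prop * prop, prop);
      }
      double lratio = lp_new - lp_old + std::log(prop / cur);
      ++tot;
      if (std::isfinite(lratio) && std::log(E.runif01()) < lratio) {
        S.sigma = prop;
        logprior += lp_new - lp_old; ++acc;
      }
    }
    if (sw >= burnin_sweeps && (sw - burnin_sweeps) % sample_every == 0) {
      for (int k = 0; k < S.nnode; ++k) out(row, k) = S.ages(ntip + k);
      out(row, S.nnode) = S.mu;
      out(row, S.nnode + 1) = S.sigma;
      out(row, S.nnode + 2) = S.kappa;
      out(row, S.nnode + 3) = S.loglik;
      out(row, S.nnode + 4) = E.log_prior();
      ++row;
    }
  }
  return List::create(_["samples"] = out,
                      _["acceptance"] = static_cast<double>(acc) / tot,
                      _["final_ages"] = NumericVector(S.ages.begin() + ntip,
                                                      S.ages.end()),
                      _["final_mult"] = NumericVector(S.mult.begin(), S.mult.end()),
                      _["final_mu"] = S.mu,
                      _["final_sigma"] = S.sigma,
                      _["final_kappa"] = S.kappa);
}

// Standalone pruning log-likelihood for a tree with given branch lengths
// (substitutions/site); used to cross-check the R implementation.
// [[Rcpp::export]]
double pruning_loglik_cpp(IntegerMatrix edge, int ntip,
                          IntegerMatrix patterns, NumericVector weights,
                          NumericVector blens,
                          NumericVector pi, NumericVector gtr_rates) {
  Engine E;
  E.edge = edge;
  State &S = E.S;
  S.nedge = edge.nrow();
  S.ntip = ntip;
  S.nn = 0;
  for (int e = 0; e < S.nedge; ++e)
    S.nn = std::max(S.nn, std::max(edge(e, 0), edge(e, 1)));
  S.nnode = S.nn - ntip;
  S.root = ntip + 1;
  S.parent.assign(S.nn + 1, 0);
  S.edge_of_child.assign(S.nn + 1, -1);
  S.kids.assign(S.nn + 1, {});
  for (int e = 0; e < S.nedge; ++e) {
    S.parent[edge(e, 1)] = edge(e, 0);
    S.edge_of_child[edge(e, 1)] = e;
    S.kids[edge(e, 0)].push_back(edge(e, 1));
  }
  std::vector<int> stack = {S.root}, order;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (int c : S.kids[v]) if (c > S.ntip) stack.push_back(c);
  }
  S.postorder.assign(order.rbegin(), order.rend());
  S.npat = patterns.ncol();
  S.pat.set_size(ntip, std::max(S.npat, 1));
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < S.npat; ++s) S.pat(i, s) = patterns(i, s);
  S.w = as<arma::vec>(weights);
  S.use_lik = true;
  S.mod = build_model(as<arma::vec>(gtr_rates), as<arma::vec>(pi));
  S.P.assign(S.nedge, arma::mat(4, 4));
  S.partial.assign(S.nn, arma::mat(4, std::max(S.npat, 1)));
  S.work.set_size(4, std::max(S.npat, 1));
  S.bakPart.assign(S.nn + 1, arma::mat(4, std::max(S.npat, 1)));
  S.bakP.assign(8, arma::mat(4, 4));
  for (int e = 0; e < S.nedge; ++e) S.P[e] = pmat(S.mod, blens[e]);
  for (int v : S.postorder) E.compute_partial(v);
  return E.root_loglik();
}
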