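// Blocked Gibbs sampler for outcome-supervised Dirichlet-process mixture
// clustering of categorical exposure profiles (truncated stick-breaking
// representation), with an optional Gaussian outcome sub-model, global
// confounder effects, and "continuous" variable-selection weights.
//
// All randomness comes from R's RNG so set.seed() on the R side controls
// every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Marsaglia-Tsang gamma generator on R's uniform/normal streams; much
// cheaper than R::rgamma for the C*P*K Dirichlet refreshes per sweep.
double fast_rgamma(double shape) {
  if (shape < 1.0) {
    double u = unif_rand();
    return fast_rgamma(shape + 1.0) * std::pow(u, 1.0 / shape);
  }
  double d = shape - 1.0 / 3.0;
  double c = 1.0 / std::sqrt(9.0 * d);
  for (;;) {
    double x, v;
    do {
      x = norm_rand();
      v = 1.0 + c * x;
    } while (v <= 0.0);
    v = v * v * v;
    double u = unif_rand();
    if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
    if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
  }
}

// log of a Gamma(shape) draw, stable for tiny shapes (boosted sampling:
// G = G1 * U^(1/shape) with G1 ~ Gamma(shape + 1)).
double fast_rgamma_log(double shape) {
  if (shape < 0.2) {
    return std::log(fast_rgamma(shape + 1.0)) + std::log(unif_rand()) / shape;
  }
  return std::log(fast_rgamma(shape));
}

// (log v, log(1 - v)) for v ~ Beta(a, b), computed entirely in log space so
// that sticks with tiny shape parameters never round to 0 or 1 (a rounded
// stick would otherwise trap the concentration parameter near zero).
void rbeta_log(double a, double b, double& logv, double& log1mv) {
  double lg1 = fast_rgamma_log(a), lg2 = fast_rgamma_log(b);
  double m = std::max(lg1, lg2);
  double lse = m + std::log(std::exp(lg1 - m) + std::exp(lg2 - m));
  logv = lg1 - lse;
  log1mv = lg2 - lse;
}

struct BPR {
  // data
  arma::imat x;     // n x P, categories 1..K
  arma::vec y;      // outcome (ignored unless has_y)
  arma::mat W;      // n x q confounder design (q may be 0)
  bool has_y;
  int n, P, K, C, q;

  // priors / constants
  double a_alpha, b_alpha;  // Gamma(shape, rate) on DP concentration
  bool fix_alpha;
  double a_phi;             // Dirichlet mass per category
  double theta_mu0, theta_var0;
  double beta_var;
  double a_sigma, b_sigma;  // Inverse-Gamma on sigma^2
  bool var_select;
  arma::mat rho;            // P x K observed marginal category frequencies
  double zeta_a, zeta_b;    // Beta prior on selection weights
  double zeta_step;         // random-walk sd on logit zeta

  // state
  arma::ivec z;             // 0-based allocations
  arma::vec logv, log1mv;   // C-1 stick fractions, log scale
  arma::vec logw;           // C log mixture weights
  double alpha;
  arma::cube phi;           // C x P x K
  arma::vec theta;          // C
  arma::vec beta;           // q
  double sigma2;
  arma::vec zeta;           // P
  arma::imat gam;           // n x P selection indicators

  long zeta_try = 0, zeta_acc = 0;

  void compute_logw() {
    double acc = 0.0;
    for (int c = 0; c < C; ++c) {
      logw[c] = (c < C - 1) ? logv[c] + acc : acc;  // last stick takes the rest
      if (c < C - 1) acc += log1mv[c];
    }
  }

  void update_gamma() {
    if (!var_select) return;
    for (int i = 0; i < n; ++i) {
      int c = z[i];
      for (int p = 0; p < P; ++p) {
        int k = x(i, p) - 1;
        double p1 = zeta[p] * phi(c, p, k);
        double p0 = (1.0 - zeta[p]) * rho(p, k);
        gam(i, p) = (unif_rand() * (p1 + p0) < p1) ? 1 : 0;
      }
    }
  }

  arma::cube lph;  // log phi buffer, refreshed each sweep

  void update_z() {
    if (lph.n_elem != phi.n_elem) lph.set_size(C, P, K);
    const double* ph = phi.memptr();
    double* lp = lph.memptr();
    for (arma::uword e = 0; e < phi.n_elem; ++e) lp[e] = std::log(ph[e]);
    arma::vec wb(n, arma::fill::zeros);
    if (has_y && q > 0) wb = W * beta;
    std::vector<double> ll(C);
    const double inv2s2 = has_y ? 0.5 / sigma2 : 0.0;
    for (int i = 0; i < n; ++i) {
      std::copy(logw.begin(), logw.end(), ll.begin());
      for (int p = 0; p < P; ++p) {
        if (var_select && gam(i, p) == 0) continue;
        int k = x(i, p) - 1;
        const double* col = lp + (static_cast<size_t>(k) * P + p) * C;
        for (int c = 0; c < C; ++c) ll[c] += col[c];
      }
      if (has_y) {
        double ya = y[i] - wb[i];
        for (int c = 0; c < C; ++c) {
          double d = ya - theta[c];
          ll[c] -= d * d * inv2s2;
        }
      }
      double m = ll[0];
      for (int c = 1; c < C; ++c) if (ll[c] > m) m = ll[c];
      double tot = 0.0;
      for (int c = 0; c < C; ++c) { ll[c] = std::exp(ll[c] - m); tot += ll[c]; }
      double u = unif_rand() * tot, cum = 0.0;
      int zi = C - 1;
      for (int c = 0; c < C; ++c) { cum += ll[c]; if (u <= cum) { zi = c; break; } }
      z[i] = zi;
    }
  }

  void update_sticks() {
    arma::ivec nc(C, arma::fill::zeros);
    for (int i = 0; i < n; ++i) nc[z[i]]++;
    // tail = number allocated beyond component c
    int tail = 0;
    for (int c = C - 1; c >= 1; --c) tail += nc[c];
    for (int c = 0; c < C - 1; ++c) {
      rbeta_log(1.0 + nc[c], alpha + tail, logv[c], log1mv[c]);
      tail -= nc[c + 1];
    }
    compute_logw();
  }

  void update_alpha() {
    if (fix_alpha) return;
    double s = arma::accu(log1mv);
    alpha = R::rgamma(a_alpha + C - 1, 1.0 / (b_alpha - s));
  }

  void update_phi() {
    arma::cube cnt(C, P, K, arma::fill::zeros);
    for (int i = 0; i < n; ++i)
      for (int p = 0; p < P; ++p)
        if (!var_select || gam(i, p) == 1)
          cnt(z[i], p, x(i, p) - 1) += 1.0;
    double g[64];
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < P; ++p) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          g[k] = fast_rgamma(a_phi + cnt(c, p, k));
          s += g[k];
        }
        for (int k = 0; k < K; ++k) phi(c, p, k) = g[k] / s;
      }
  }

  // Random-walk Metropolis on logit zeta_p targeting its Beta full
  // conditional given the selection indicators.
  void update_zeta() {
    if (!var_select) return;
    for (int p = 0; p < P; ++p) {
      int s = 0;
      for (int i = 0; i < n; ++i) s += gam(i, p);
      double a = zeta_a + s, b = zeta_b + n - s;
      double lo = std::log(zeta[p] / (1.0 - zeta[p]));
      double lp = lo + zeta_step * norm_rand();
      double zp = 1.0 / (1.0 + std::exp(-lp));
      if (zp <= 0.0 || zp >= 1.0) { zeta_try++; continue; }
      // density on the logit scale is z^a (1-z)^b up to a constant
      double la = a * std::log(zp) + b * std::log1p(-zp)
                - a * std::log(zeta[p]) - b * std::log1p(-zeta[p]);
      zeta_try++;
      if (std::log(unif_rand()) < la) { zeta[p] = zp; zeta_acc++; }
    }
  }

  void update_theta() {
    arma::vec wb(n, arma::fill::zeros);
    if (q > 0) wb = W * beta;
    arma::vec sr(C, arma::fill::zeros);
    arma::ivec nc(C, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      sr[z[i]] += y[i] - wb[i];
      nc[z[i]]++;
    }
    for (int c = 0; c < C; ++c) {
      double prec = 1.0 / theta_var0 + nc[c] / sigma2;
      double mean = (theta_mu0 / theta_var0 + sr[c] / sigma2) / prec;
      theta[c] = R::rnorm(mean, std::sqrt(1.0 / prec));
    }
  }

  void update_beta() {
    if (q == 0) return;
    arma::vec r = y;
    for (int i = 0; i < n; ++i) r[i] -= theta[z[i]];
    arma::mat A = W.t() * W / sigma2;
    A.diag() += 1.0 / beta_var;
    arma::vec bv = W.t() * r / sigma2;
    arma::mat L = arma::chol(A, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), bv));
    arma::vec e(q);
    for (int j = 0; j < q; ++j) e[j] = norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), e);
  }

  void update_sigma2() {
    arma::vec wb(n, arma::fill::zeros);
    if (q > 0) wb = W * beta;
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = y[i] - theta[z[i]] - wb[i];
      rss += e * e;
    }
    sigma2 = 1.0 / R::rgamma(a_sigma + 0.5 * n, 1.0 / (b_sigma + 0.5 * rss));
  }

  void sweep() {
    update_gamma();
    update_z();
    update_sticks();
    update_alpha();
    update_phi();
    update_zeta();
    if (has_y) {
      update_theta();
      update_beta();
      update_sigma2();
    }
  }
};

BPR make_model(const List& data, const List& priors, const List& state) {
  BPR m;
  m.x = as<arma::imat>(data["x"]);
  m.n = m.x.n_rows;
  m.P = m.x.n_cols;
  m.K = as<int>(data["K"]);
  if (m.K < 2 || m.K > 64) stop("K must lie in 2..64");
  m.has_y = as<bool>(data["has_y"]);
  if (m.has_y) m.y = as<arma::vec>(data["y"]); else m.y = arma::vec(m.n, arma::fill::zeros);
  m.W = as<arma::mat>(data["W"]);
  m.q = m.W.n_cols;

  m.a_alpha = as<double>(priors["a_alpha"]);
  m.b_alpha = as<double>(priors["b_alpha"]);
  m.fix_alpha = as<bool>(priors["fix_alpha"]);
  m.a_phi = as<double>(priors["a_phi"]);
  m.theta_mu0 = as<double>(priors["theta_mu0"]);
  m.theta_var0 = as<double>(priors["theta_var0"]);
  m.beta_var = as<double>(priors["beta_var"]);
  m.a_sigma = as<double>(priors["a_sigma"]);
  m.b_sigma = as<double>(priors["b_sigma"]);
  m.var_select = as<bool>(priors["var_select"]);
  m.rho = as<arma::mat>(priors["rho"]);
  m.zeta_a = as<double>(priors["zeta_a"]);
  m.zeta_b = as<double>(priors["zeta_b"]);
  m.zeta_step = as<double>(priors["zeta_step"]);

  m.C = as<int>(priors["C"]);
  m.z = as<arma::ivec>(state["z"]) - 1;
  m.logv = as<arma::vec>(state["logv"]);
  m.log1mv = as<arma::vec>(state["log1mv"]);
  m.alpha = as<double>(state["alpha"]);
  NumericVector ph = state["phi"];
  m.phi = arma::cube(ph.begin(), m.C, m.P, m.K);
  m.theta = as<arma::vec>(state["theta"]);
  m.beta = as<arma::vec>(state["beta"]);
  m.sigma2 = as<double>(state["sigma2"]);
  m.zeta = as<arma::vec>(state["zeta"]);
  m.gam = as<arma::imat>(state["gamma"]);
  m.logw = arma::vec(m.C);
  m.compute_logw();
  return m;
}

List pack_state(const BPR& m) {
  IntegerVector z(m.n);
  for (int i = 0; i < m.n; ++i) z[i] = m.z[i] + 1;
  NumericVector ph(m.phi.begin(), m.phi.end());
  ph.attr("dim") = IntegerVector::create(m.C, m.P, m.K);
  IntegerMatrix gm(m.n, m.P);
  for (int i = 0; i < m.n; ++i)
    for (int p = 0; p < m.P; ++p) gm(i, p) = m.gam(i, p);
  return List::create(
    _["z"] = z,
    _["logv"] = NumericVector(m.logv.begin(), m.logv.end()),
    _["log1mv"] = NumericVector(m.log1mv.begin(), m.log1mv.end()),
    _["alpha"] = m.alpha, _["phi"] = ph,
    _["theta"] = NumericVector(m.theta.begin(), m.theta.end()),
    _["beta"] = NumericVector(m.beta.begin(), m.beta.end()),
    _["sigma2"] = m.sigma2,
    _["zeta"] = NumericVector(m.zeta.begin(), m.zeta.end()),
    _["gamma"] = gm,
    _["zeta_acc_rate"] = m.zeta_try > 0 ? (double)m.zeta_acc / m.zeta_try : NA_REAL);
}

}  // namespace

// Full MCMC run: burn-in, then keep every `thin`-th sweep.
// [[Rcpp::export]]
List bpr_mcmc_cpp(List data, List priors, List state,
                  int n_burn, int n_sweeps, int thin) {
  BPR m = make_model(data, priors, state);
  for (int t = 0; t < n_burn; ++t) m.sweep();

  int n_keep = n_sweeps / thin;
  IntegerMatrix zk(n_keep, m.n);
  NumericMatrix thetak(n_keep, m.C), betak(n_keep, m.q), zetak(n_keep, m.P);
  NumericVector sigma2k(n_keep), alphak(n_keep);
  IntegerVector nocc(n_keep), maxocc(n_keep);

  int kept = 0;
  for (int t = 1; t <= n_sweeps; ++t) {
    m.sweep();
    if (t % thin == 0 && kept < n_keep) {
      std::vector<int> seen(m.C, 0);
      int no = 0, mo = 0;
      for (int i = 0; i < m.n; ++i) {
        zk(kept, i) = m.z[i] + 1;
        if (!seen[m.z[i]]) { seen[m.z[i]] = 1; no++; }
        if (m.z[i] > mo) mo = m.z[i];
      }
      nocc[kept] = no;
      maxocc[kept] = mo + 1;
      for (int c = 0; c < m.C; ++c) thetak(kept, c) = m.theta[c];
      for (int j = 0; j < m.q; ++j) betak(kept, j) = m.beta[j];
      for (int p = 0; p < m.P; ++p) zetak(kept, p) = m.zeta[p];
      sigma2k[kept] = m.sigma2;
      alphak[kept] = m.alpha;
      kept++;
    }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["z"] = zk, _["theta"] = thetak, _["beta"] = betak,
    _["sigma2"] = sigma2k, _["alpha"] = alphak, _["zeta"] = zetak,
    _["n_occupied"] = nocc, _["max_occupied"] = maxocc,
    _["final_state"] = pack_state(m));
}

// Run `n_sweeps` transition kernels from a given state and return the state:
// used by the successive-conditional ("getting it right") validator.
// [[Rcpp::export]]
List bpr_kernel_cpp(List data, List priors, List state, int n_sweeps) {
  BPR m = make_model(data, priors, state);
  for (int t = 0; t < n_sweeps; ++t) m.sweep();
  return pack_state(m);
}

// Posterior co-clustering probabilities from kept allocation draws (T x n).
// [[Rcpp::export]]
NumericMatrix coclustering_cpp(IntegerMatrix zdraws) {
  int T = zdraws.nrow(), n = zdraws.ncol();
  NumericMatrix S(n, n);
  std::vector<std::vector<int> > members;
  for (int t = 0; t < T; ++t) {
    int cmax = 0;
    for (int i = 0; i < n; ++i) if (zdraws(t, i) > cmax) cmax = zdraws(t, i);
    members.assign(cmax, std::vector<int>());
    for (int i = 0; i < n; ++i) members[zdraws(t, i) - 1].push_back(i);
    for (size_t c = 0; c < members.size(); ++c) {
      const std::vector<int>& mb = members[c];
      for (size_t a = 0; a < mb.size(); ++a)
        for (size_t b = a + 1; b < mb.size(); ++b)
          S(mb[a], mb[b]) += 1.0;
    }
  }
  for (int i = 0; i < n; ++i) {
    S(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      S(i, j) /= T;
      S(j, i) = S(i, j);
    }
  }
  return S;
}

// Least-squares score of each sampled partition against S:
//   sum_{i<j} (1[z_i = z_j] - S_ij)^2
// expanded as sum_{i<j} S^2 + sum_{same-cluster pairs} (1 - 2 S_ij).
// [[Rcpp::export]]
NumericVector partition_scores_cpp(IntegerMatrix zdraws, NumericMatrix S) {
  int T = zdraws.nrow(), n = zdraws.ncol();
  double base = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) base += S(i, j) * S(i, j);
  NumericVector out(T);
  std::vector<std::vector<int> > members;
  for (int t = 0; t < T; ++t) {
    int cmax = 0;
    for (int i = 0; i < n; ++i) if (zdraws(t, i) > cmax) cmax = zdraws(t, i);
    members.assign(cmax, std::vector<int>());
    for (int i = 0; i < n; ++i) members[zdraws(t, i) - 1].push_back(i);
    double sc = base;
    for (size_t c = 0; c < members.size(); ++c) {
      const std::vector<int>& mb = members[c];
      for (size_t a = 0; a < mb.size(); ++a)
        for (size_t b = a + 1; b < mb.size(); ++b)
          sc += 1.0 - 2.0 * S(mb[a], mb[b]);
    }
    out[t] = sc;
  }
  return out;
}
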