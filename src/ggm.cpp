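// Gaussian graphical model estimation core: graphical-lasso coordinate
// descent over a lambda path, unregularized refits under edge-set
// constraints, EBIC model selection with greedy stepwise refinement, and
// the permutation loop of the network comparison test.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// lasso subproblem for one glasso column:
//   minimize 0.5 b' W11 b - s12' b + rho ||b||_1
static void lasso_cd(const arma::mat& W11, const arma::vec& s12, double rho,
                     arma::vec& beta, double tol, int maxit) {
  const arma::uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (arma::uword k = 0; k < q; ++k) {
      double grad = s12(k) - arma::dot(W11.col(k), beta) + W11(k, k) * beta(k);
      double bnew = soft(grad, rho) / W11(k, k);
      double d = std::fabs(bnew - beta(k));
      if (d > maxdiff) maxdiff = d;
      beta(k) = bnew;
    }
    if (maxdiff < tol) break;
  }
}

// Friedman-Hastie-Tibshirani block coordinate descent. W and B act as
// warm starts and are overwritten.
static void glasso_fit(const arma::mat& S, double rho, arma::mat& W,
                       arma::mat& B, double tol, int maxit) {
  const arma::uword p = S.n_rows;
  for (arma::uword j = 0; j < p; ++j) W(j, j) = S(j, j) + rho;
  if (p < 2) return;
  double offscale = 0.0;
  for (arma::uword j = 0; j < p; ++j)
    for (arma::uword i = 0; i < p; ++i)
      if (i != j) offscale += std::fabs(S(i, j));
  double thr = tol * std::max(offscale / double(p * p - p), 1e-4);
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      arma::uvec idx = arma::find(all != j);
      arma::mat W11 = W(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12(idx);
      arma::vec beta = B.col(j);
      beta = beta(idx);
      lasso_cd(W11, s12, rho, beta, thr * 0.1, 200);
      arma::vec w12 = W11 * beta;
      for (arma::uword k = 0; k < idx.n_elem; ++k) {
        double d = std::fabs(w12(k) - W(idx(k), j));
        if (d > maxdiff) maxdiff = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
      B(j, j) = 0.0;
    }
    if (maxdiff < thr) break;
  }
}

// Unregularized Gaussian MLE constrained to a given edge set
// (modified-regression algorithm). Returns false on numerical failure.
static bool cmle(const arma::mat& S, const arma::umat& adj, arma::mat& Theta,
                 double tol, int maxit, arma::mat* warmW = nullptr) {
  const arma::uword p = S.n_rows;
  arma::mat W = (warmW != nullptr && warmW->n_rows == p) ? *warmW : S;
  W.diag() = S.diag();  // diagonal is unconstrained at the MLE
  arma::mat B(p, p, arma::fill::zeros);
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      arma::uvec nb = arma::find(adj.col(j));
      arma::vec w12new(p, arma::fill::zeros);
      arma::vec beta(p, arma::fill::zeros);
      if (nb.n_elem > 0) {
        arma::mat W11 = W(nb, nb);
        arma::vec s12 = S.col(j);
        s12 = s12(nb);
        arma::vec bstar;
        bool ok = arma::solve(bstar, W11, s12,
                              arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
        if (!ok) return false;
        beta(nb) = bstar;
        w12new = W.cols(nb) * bstar;
      }
      for (arma::uword i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::fabs(w12new(i) - W(i, j));
        if (d > maxdiff) maxdiff = d;
        W(i, j) = w12new(i);
        W(j, i) = w12new(i);
      }
      B.col(j) = beta;
    }
    if (maxdiff < tol) break;
  }
  if (warmW != nullptr) *warmW = W;
  Theta.set_size(p, p);
  Theta.zeros();
  for (arma::uword j = 0; j < p; ++j) {
    const arma::vec beta = B.col(j);
    double denom = W(j, j) - arma::dot(W.col(j), beta);
    if (denom <= 0 || !std::isfinite(denom)) return false;
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (arma::uword i = 0; i < p; ++i)
      if (i != j && adj(i, j)) Theta(i, j) = -beta(i) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());
  return true;
}

static double ebic_value(const arma::mat& Theta, const arma::mat& S, int n,
                         double gamma, int nedges) {
  double ld, sign;
  arma::log_det(ld, sign, Theta);
  if (sign <= 0 || !std::isfinite(ld)) return arma::datum::inf;
  const arma::uword p = S.n_rows;
  double ll = 0.5 * double(n) * (ld - arma::trace(S * Theta));
  return -2.0 * ll + double(nedges) * std::log(double(n)) +
         4.0 * gamma * double(nedges) * std::log(double(p));
}

static int edge_count(const arma::umat& adj) {
  const arma::uword p = adj.n_rows;
  int e = 0;
  for (arma::uword j = 1; j < p; ++j)
    for (arma::uword i = 0; i < j; ++i)
      if (adj(i, j)) ++e;
  return e;
}

static arma::mat pcor_from_theta(const arma::mat& Theta, const arma::umat& adj) {
  const arma::uword p = Theta.n_rows;
  arma::mat pc(p, p, arma::fill::zeros);
  for (arma::uword j = 1; j < p; ++j)
    for (arma::uword i = 0; i < j; ++i)
      if (adj(i, j)) {
        double w = -Theta(i, j) / std::sqrt(Theta(i, i) * Theta(j, j));
        pc(i, j) = w;
        pc(j, i) = w;
      }
  return pc;
}

struct GgmSelection {
  arma::umat adj;
  arma::mat theta;
  arma::mat pcor;
  double ebic;
  std::vector<double> path_ebic;
  std::vector<int> path_edges;
  std::vector<double> step_ebic;
  bool ok;
};

// Core selector. Path models are refit without regularization before EBIC
// comparison (ggmModSelect-style); optional greedy stepwise search over
// single-edge additions/removals with deterministic tie-breaking.
static GgmSelection ggm_select_core(const arma::mat& S, int n, double gamma,
                                    int nlambda, double lambda_min_ratio,
                                    bool stepwise) {
  GgmSelection out;
  out.ok = true;
  const arma::uword p = S.n_rows;

  double lmax = 0.0;
  for (arma::uword j = 1; j < p; ++j)
    for (arma::uword i = 0; i < j; ++i)
      lmax = std::max(lmax, std::fabs(S(i, j)));
  if (lmax <= 0.0) lmax = 1e-4;

  arma::vec lambdas =
      arma::exp(arma::linspace(std::log(lmax), std::log(lmax * lambda_min_ratio),
                               nlambda));

  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  std::vector<arma::umat> supports;
  // empty model is always a candidate (lambda_max yields it anyway)
  supports.push_back(arma::umat(p, p, arma::fill::zeros));
  for (int l = 0; l < nlambda; ++l) {
    glasso_fit(S, lambdas(l), W, B, 1e-4, 100);
    arma::umat adj(p, p, arma::fill::zeros);
    for (arma::uword j = 1; j < p; ++j)
      for (arma::uword i = 0; i < j; ++i)
        if (std::fabs(B(i, j)) > 0.0 || std::fabs(B(j, i)) > 0.0) {
          adj(i, j) = 1;
          adj(j, i) = 1;
        }
    bool seen = false;
    for (size_t k = 0; k < supports.size(); ++k)
      if (arma::accu(adj != supports[k]) == 0) { seen = true; break; }
    if (!seen) supports.push_back(adj);
  }

  double best_ebic = arma::datum::inf;
  arma::umat best_adj;
  arma::mat best_theta;
  arma::mat best_W;
  arma::mat Wwarm = S;
  for (size_t k = 0; k < supports.size(); ++k) {
    arma::mat Theta;
    if (!cmle(S, supports[k], Theta, 2e-5, 60, &Wwarm)) continue;
    double e = ebic_value(Theta, S, n, gamma, edge_count(supports[k]));
    out.path_ebic.push_back(e);
    out.path_edges.push_back(edge_count(supports[k]));
    if (e < best_ebic) {
      best_ebic = e;
      best_adj = supports[k];
      best_theta = Theta;
      best_W = Wwarm;
    }
  }
  if (!std::isfinite(best_ebic)) {
    out.ok = false;
    return out;
  }

  if (stepwise) {
    out.step_ebic.push_back(best_ebic);
    const double tie_tol = 1e-9;
    for (int move = 0; move < int(p * (p - 1)); ++move) {
      double cand_best = arma::datum::inf;
      bool cand_removal = false;
      int cand_i = -1, cand_j = -1;
      arma::mat cand_theta, cand_W;
      for (arma::uword j = 1; j < p; ++j) {
        for (arma::uword i = 0; i < j; ++i) {
          arma::umat adj = best_adj;
          bool removal = adj(i, j) == 1;
          adj(i, j) = removal ? 0 : 1;
          adj(j, i) = adj(i, j);
          arma::mat Theta;
          arma::mat Wc = best_W;
          if (!cmle(S, adj, Theta, 2e-5, 60, &Wc)) continue;
          double e = ebic_value(Theta, S, n, gamma, edge_count(adj));
          bool better = e < cand_best - tie_tol;
          bool tied = std::fabs(e - cand_best) <= tie_tol;
          // ties: prefer removal over addition, then lowest edge index
          // (pairs enumerated in (i, j), i < j column-major order)
          if (tied && removal && !cand_removal) better = true;
          if (better) {
            cand_best = e;
            cand_removal = removal;
            cand_i = int(i);
            cand_j = int(j);
            cand_theta = Theta;
            cand_W = Wc;
          }
        }
      }
      if (cand_i < 0 || cand_best >= best_ebic - tie_tol) break;
      bool removal = best_adj(cand_i, cand_j) == 1;
      best_adj(cand_i, cand_j) = removal ? 0 : 1;
      best_adj(cand_j, cand_i) = best_adj(cand_i, cand_j);
      best_ebic = cand_best;
      best_theta = cand_theta;
      best_W = cand_W;
      out.step_ebic.push_back(best_ebic);
    }
  }

  // tight final refit of the selected model
  {
    arma::mat Theta;
    if (cmle(S, best_adj, Theta, 1e-10, 500, &best_W)) {
      best_theta = Theta;
      best_ebic = ebic_value(Theta, S, n, gamma, edge_count(best_adj));
    }
  }

  out.adj = best_adj;
  out.theta = best_theta;
  out.pcor = pcor_from_theta(best_theta, best_adj);
  out.ebic = best_ebic;
  return out;
}

// [[Rcpp::export]]
List ggm_select_cpp(const arma::mat& S, int n, double gamma, int nlambda,
                    double lambda_min_ratio, bool stepwise) {
  GgmSelection sel =
      ggm_select_core(S, n, gamma, nlambda, lambda_min_ratio, stepwise);
  if (!sel.ok) stop("GGM estimation failed: no positive-definite model on the path (singular covariance?)");
  return List::create(
      _["pcor"] = sel.pcor, _["adj"] = sel.adj, _["theta"] = sel.theta,
      _["ebic"] = sel.ebic, _["path_ebic"] = sel.path_ebic,
      _["path_edges"] = sel.path_edges, _["step_ebic"] = sel.step_ebic);
}

// [[Rcpp::export]]
arma::mat cmle_cpp(const arma::mat& S, const arma::umat& adj) {
  arma::mat Theta;
  if (!cmle(S, adj, Theta, 1e-10, 500))
    stop("constrained MLE failed to converge");
  return Theta;
}

static double global_strength(const arma::mat& pcor) {
  const arma::uword p = pcor.n_rows;
  double s = 0.0;
  for (arma::uword j = 1; j < p; ++j)
    for (arma::uword i = 0; i < j; ++i) s += std::fabs(pcor(i, j));
  return s;
}

static double max_edge_diff(const arma::mat& a, const arma::mat& b) {
  const arma::uword p = a.n_rows;
  double m = 0.0;
  for (arma::uword j = 1; j < p; ++j)
    for (arma::uword i = 0; i < j; ++i)
      m = std::max(m, std::fabs(a(i, j) - b(i, j)));
  return m;
}

// Permutation network comparison test. Uses R's RNG (seed with set.seed
// before calling). Statistics: M = max absolute edge difference,
// S = absolute difference of global strengths.
// [[Rcpp::export]]
List nct_cpp(const arma::mat& Xa, const arma::mat& Xb, int n_perm,
             double gamma, int nlambda, double lambda_min_ratio,
             bool stepwise) {
  const arma::uword na = Xa.n_rows, nb = Xb.n_rows;
  const arma::uword p = Xa.n_cols;
  if (Xb.n_cols != p) stop("groups must have identical node rosters");

  GgmSelection fa = ggm_select_core(arma::cor(Xa), int(na), gamma, nlambda,
                                    lambda_min_ratio, stepwise);
  GgmSelection fb = ggm_select_core(arma::cor(Xb), int(nb), gamma, nlambda,
                                    lambda_min_ratio, stepwise);
  if (!fa.ok || !fb.ok) stop("NCT: observed network estimation failed");

  double m_obs = max_edge_diff(fa.pcor, fb.pcor);
  double sa = global_strength(fa.pcor);
  double sb = global_strength(fb.pcor);
  double s_obs = std::fabs(sa - sb);

  arma::mat pooled = arma::join_cols(Xa, Xb);
  const arma::uword ntot = na + nb;
  arma::vec m_perm(n_perm), s_perm(n_perm);

  RNGScope scope;
  arma::uvec idx = arma::regspace<arma::uvec>(0, ntot - 1);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates with R's RNG for reproducibility under set.seed
    for (arma::uword i = ntot - 1; i > 0; --i) {
      arma::uword j = arma::uword(unif_rand() * double(i + 1));
      if (j > i) j = i;
      std::swap(idx(i), idx(j));
    }
    arma::mat Pa = pooled.rows(idx.head(na));
    arma::mat Pb = pooled.rows(idx.tail(nb));
    GgmSelection ga = ggm_select_core(arma::cor(Pa), int(na), gamma, nlambda,
                                      lambda_min_ratio, stepwise);
    GgmSelection gb = ggm_select_core(arma::cor(Pb), int(nb), gamma, nlambda,
                                      lambda_min_ratio, stepwise);
    if (!ga.ok || !gb.ok) {
      m_perm(b) = arma::datum::nan;
      s_perm(b) = arma::datum::nan;
      continue;
    }
    m_perm(b) = max_edge_diff(ga.pcor, gb.pcor);
    s_perm(b) = std::fabs(global_strength(ga.pcor) - global_strength(gb.pcor));
  }

  return List::create(_["m_observed"] = m_obs, _["s_observed"] = s_obs,
                      _["strength_a"] = sa, _["strength_b"] = sb,
                      _["pcor_a"] = fa.pcor, _["pcor_b"] = fb.pcor,
                      _["m_perm"] = m_perm, _["s_perm"] = s_perm);
}
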