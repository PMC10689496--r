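// Likelihood engines for binary cognate data on dated trees.
//
// Three models: binary CTMC, binary covarion (4 hidden states), and
// stochastic Dollo (single birth, repeated loss). All likelihoods apply the
// per-concept observability (ascertainment) conditioning. Trees arrive as a
// postorder edge list; branch lengths arrive already converted to expected
// substitutions (years x clock rate x branch-rate multiplier), so the models
// themselves are normalized to unit expected rate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct EigenSys {
  arma::mat U;        // orthonormal eigenvectors of the symmetrized generator
  arma::vec lam;      // eigenvalues
  arma::vec pi;       // stationary distribution
  arma::vec sqrt_pi;
  int k;
};

// reversible generator -> symmetric eigen-system via the pi^{1/2} similarity
EigenSys decompose(const arma::mat& Q, const arma::vec& pi) {
  EigenSys s;
  s.k = Q.n_rows;
  s.pi = pi;
  s.sqrt_pi = arma::sqrt(pi);
  arma::mat B = Q;
  for (int i = 0; i < s.k; ++i)
    for (int j = 0; j < s.k; ++j)
      B(i, j) = Q(i, j) * s.sqrt_pi(i) / s.sqrt_pi(j);
  B = 0.5 * (B + B.t());  // clean numerical asymmetry
  arma::eig_sym(s.lam, s.U, B);
  return s;
}

// P(t) = D^{-1/2} U exp(lam t) U' D^{1/2}
void trans_mat(const EigenSys& s, double t, double* P) {
  const int k = s.k;
  double e[4];
  for (int a = 0; a < k; ++a) e[a] = std::exp(s.lam(a) * t);
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k; ++j) {
      double acc = 0.0;
      for (int a = 0; a < k; ++a) acc += s.U(i, a) * e[a] * s.U(j, a);
      double v = acc * s.sqrt_pi(j) / s.sqrt_pi(i);
      P[i * k + j] = v > 0.0 ? v : 0.0;
    }
  }
}

arma::mat ctmc_generator(double p1) {
  double p0 = 1.0 - p1;
  arma::mat Q(2, 2, arma::fill::zeros);
  Q(0, 1) = p1; Q(1, 0) = p0;
  Q(0, 0) = -p1; Q(1, 1) = -p0;
  return Q / (2.0 * p0 * p1);  // unit expected rate at stationarity
}

arma::mat covarion_generator_cpp(double p1, double s, double a) {
  double p0 = 1.0 - p1;
  arma::mat Q(4, 4, arma::fill::zeros);  // states: 0s 1s 0f 1f
  Q(0, 1) = a * p1; Q(1, 0) = a * p0;
  Q(2, 3) = p1;     Q(3, 2) = p0;
  Q(0, 2) = s; Q(2, 0) = s;
  Q(1, 3) = s; Q(3, 1) = s;
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i)) + Q(i, i);
  return Q / (p0 * p1 * (a + 1.0));
}

}  // namespace

// Pruning likelihood for CTMC / covarion with gamma categories, per-concept
// rates and per-concept ascertainment correction. `edge` is postorder,
// 1-based; `data` is n_tip x n_col with values 0, 1, -1 (missing).
// Ascertainment columns supply P(all absent) for their concept; real columns
// with no observed cell contribute nothing. Returns the total log-likelihood.
// [[Rcpp::export]]
double cognate_loglik_cpp(IntegerMatrix edge, int n_tip, int n_node,
                          NumericVector blen_subs, IntegerMatrix data,
                          IntegerVector concept_idx, LogicalVector is_asc,
                          NumericVector concept_rates, int model_kind,
                          NumericVector params, NumericVector gamma_rates) {
  const int n_edge = edge.nrow();
  const int n_col = data.ncol();
  const int n_cat = gamma_rates.size();
  const int n_concept = concept_rates.size();
  const double p1 = params[0];

  EigenSys sys;
  int k, n_vis_state = 2;
  int vis0[4], vis1[4];  // allowed-state masks per visible symbol
  if (model_kind == 0) {
    arma::vec pi = {1.0 - p1, p1};
    sys = decompose(ctmc_generator(p1), pi);
    k = 2;
    vis0[0] = 1; vis0[1] = 0;
    vis1[0] = 0; vis1[1] = 1;
  } else {
    arma::vec pi = {(1.0 - p1) / 2, p1 / 2, (1.0 - p1) / 2, p1 / 2};
    sys = decompose(covarion_generator_cpp(p1, params[1], params[2]), pi);
    k = 4;
    vis0[0] = 1; vis0[1] = 0; vis0[2] = 1; vis0[3] = 0;
    vis1[0] = 0; vis1[1] = 1; vis1[2] = 0; vis1[3] = 1;
  }
  (void)n_vis_state;

  const int root = edge(n_edge - 1, 0) - 1;
  std::vector<double> P(n_edge * n_cat * 16);
  std::vector<double> part(n_node * 4);
  // per-column mean likelihood over categories, and per-concept P0
  std::vector<double> col_loglik_sum(n_concept, 0.0);
  std::vector<int> col_count(n_concept, 0);
  std::vector<double> p0_concept(n_concept, -1.0);

  double r_prev = std::numeric_limits<double>::quiet_NaN();
  for (int col = 0; col < n_col; ++col) {
    const int ci = concept_idx[col] - 1;
    const double r = concept_rates[ci];
    if (r != r_prev) {
      // rebuild transition matrices only when the column rate changes
      for (int e = 0; e < n_edge; ++e)
        for (int g = 0; g < n_cat; ++g)
          trans_mat(sys, blen_subs[e] * r * gamma_rates[g],
                    &P[(e * n_cat + g) * 16]);
      r_prev = r;
    }
    bool any_obs = false;
    for (int t = 0; t < n_tip; ++t) if (data(t, col) >= 0) any_obs = true;
    if (!any_obs && !is_asc[col]) continue;  // all-'?' column carries no data

    double like_mean = 0.0;
    for (int g = 0; g < n_cat; ++g) {
      for (int t = 0; t < n_tip; ++t) {
        const int x = data(t, col);
        for (int s = 0; s < k; ++s) {
          part[t * 4 + s] =
            (x < 0) ? 1.0 : (x == 0 ? vis0[s] : vis1[s]);
        }
      }
      for (int v = n_tip; v < n_node; ++v)
        for (int s = 0; s < k; ++s) part[v * 4 + s] = 1.0;
      for (int e = 0; e < n_edge; ++e) {
        const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
        const double* Pe = &P[(e * n_cat + g) * 16];
        for (int s = 0; s < k; ++s) {
          double acc = 0.0;
          for (int t = 0; t < k; ++t) acc += Pe[s * k + t] * part[ch * 4 + t];
          part[par * 4 + s] *= acc;
        }
      }
      double like = 0.0;
      for (int s = 0; s < k; ++s) like += sys.pi(s) * part[root * 4 + s];
      like_mean += like / n_cat;
    }
    if (is_asc[col]) {
      p0_concept[ci] = like_mean;
    } else {
      if (like_mean <= 0.0) return -std::numeric_limits<double>::infinity();
      col_loglik_sum[ci] += std::log(like_mean);
      col_count[ci] += 1;
    }
  }

  double total = 0.0;
  for (int c = 0; c < n_concept; ++c) {
    total += col_loglik_sum[c];
    if (p0_concept[c] >= 0.0 && col_count[c] > 0) {
      const double p0 = std::min(p0_concept[c], 1.0 - 1e-12);
      total -= col_count[c] * std::log1p(-p0);
    }
  }
  return total;
}

// Stochastic Dollo likelihood: one birth (uniform in time over branches plus
// an infinite root stem on which only surviving births register) followed by
// independent loss at `death_rate` (per substitution-time unit). Each
// column's likelihood is conditioned on being observable (>= 1 presence), so
// ascertainment columns are skipped rather than corrected for. Gamma
// categories mix the process before conditioning.
// [[Rcpp::export]]
double sdollo_loglik_cpp(IntegerMatrix edge, int n_tip, int n_node,
                         NumericVector blen_subs, IntegerMatrix data,
                         IntegerVector concept_idx, LogicalVector is_asc,
                         NumericVector concept_rates, double death_rate,
                         NumericVector gamma_rates) {
  const int n_edge = edge.nrow();
  const int n_col = data.ncol();
  const int n_cat = gamma_rates.size();
  if (death_rate <= 0.0) stop("death_rate must be > 0");
  const int root = edge(n_edge - 1, 0) - 1;

  // children lookup from the postorder edge list
  std::vector<double> A(n_node), E(n_node);
  std::vector<int> ones_below(n_node), zerocomp(n_node);

  double total = 0.0;
  for (int col = 0; col < n_col; ++col) {
    if (is_asc[col]) continue;
    bool any_obs = false;
    int total_ones = 0;
    for (int t = 0; t < n_tip; ++t) {
      if (data(t, col) >= 0) any_obs = true;
      if (data(t, col) == 1) ++total_ones;
    }
    if (!any_obs) continue;
    const double r = concept_rates[concept_idx[col] - 1];

    double num_mean = 0.0, den_mean = 0.0;
    for (int g = 0; g < n_cat; ++g) {
      const double mu = death_rate * r * gamma_rates[g];
      for (int v = 0; v < n_node; ++v) {
        A[v] = 1.0; E[v] = (v < n_tip) ? 0.0 : 1.0;
        ones_below[v] = 0; zerocomp[v] = 1;
      }
      for (int t = 0; t < n_tip; ++t) {
        const int x = data(t, col);
        A[t] = (x == 0) ? 0.0 : 1.0;       // present at tip shows as 1
        zerocomp[t] = (x == 1) ? 0 : 1;    // absent compatible with 0 or ?
        ones_below[t] = (x == 1) ? 1 : 0;
      }
      double m_col = 0.0, m_zero = 0.0, m_all = 0.0;
      for (int e = 0; e < n_edge; ++e) {
        const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
        const double t_e = blen_subs[e];
        const double surv = std::exp(-mu * t_e);
        const double IA = (1.0 - surv) / mu;
        const double IB = t_e - IA;
        // B_v: data below v must be all zero-compatible
        const double Bv = zerocomp[ch] ? 1.0 : 0.0;
        const bool outside_zero = (ones_below[ch] == total_ones);
        if (outside_zero) m_col += A[ch] * IA + Bv * IB;
        m_zero += E[ch] * IA + IB;
        m_all += t_e;
        // push this child's message up to its parent
        A[par] *= surv * A[ch] + (1.0 - surv) * Bv;
        E[par] *= surv * E[ch] + (1.0 - surv);
        ones_below[par] += ones_below[ch];
        zerocomp[par] = zerocomp[par] && zerocomp[ch];
      }
      // infinite stem above the root: only births surviving to the root count
      m_col += A[root] / mu;
      m_zero += E[root] / mu;
      m_all += 1.0 / mu;
      num_mean += m_col / n_cat;
      den_mean += (m_all - m_zero) / n_cat;
    }
    if (num_mean <= 0.0 || den_mean <= 0.0)
      return -std::numeric_limits<double>::infinity();
    total += std::log(num_mean) - std::log(den_mean);
  }
  return total;
}
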