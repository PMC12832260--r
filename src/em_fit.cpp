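// Marginal maximum likelihood EM for the 2PL/3PL logistic IRT models on a
// fixed quadrature grid. The M-step is a per-item Fisher-scoring ascent with
// step halving on the expected complete-data log-likelihood, so every cycle
// is a guaranteed (generalized) EM ascent step and the marginal
// log-likelihood trace is monotone nondecreasing up to floating point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double P_EPS = 1e-10;
static const double LOG_A_MIN = -3.912023005428146; // log(0.02)
static const double LOG_A_MAX = 3.912023005428146;  // log(50)
static const double B_BOUND = 30.0;
static const double G_BOUND = 30.0;

static inline double sigmoid(double x) {
  if (x >= 0.0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

static inline double clampp(double p) {
  if (p < P_EPS) return P_EPS;
  if (p > 1.0 - P_EPS) return 1.0 - P_EPS;
  return p;
}

// expected complete-data log-likelihood contribution of one item
static double item_ell(const rowvec& r, const rowvec& nk, const vec& nodes,
                       double a, double b, double c) {
  double f = 0.0;
  for (uword k = 0; k < nodes.n_elem; ++k) {
    double p = clampp(c + (1.0 - c) * sigmoid(a * (nodes[k] - b)));
    f += r[k] * std::log(p) + (nk[k] - r[k]) * std::log1p(-p);
  }
  return f;
}

// Maximize the expected complete-data log-likelihood for one item over
// (log a, b[, logit(c/cmax)]) by Fisher scoring with step halving. Updates
// a, b, c in place; never decreases the objective.
static void mstep_item(const rowvec& r, const rowvec& nk, const vec& nodes,
                       double& a, double& b, double& c, double cmax,
                       bool est_c) {
  const int d = est_c ? 3 : 2;
  double alpha = std::log(a);
  double gamma = 0.0;
  if (est_c) {
    // clamp consistently with the gamma bound so the round trip
    // c -> gamma -> c is the identity for every reachable c
    const double u_min = sigmoid(-G_BOUND), u_max = sigmoid(G_BOUND);
    double u = std::min(std::max(c / cmax, u_min), u_max);
    gamma = std::log(u / (1.0 - u));
    c = cmax * sigmoid(gamma);
  }
  double f0 = item_ell(r, nk, nodes, a, b, c);

  for (int it = 0; it < 50; ++it) {
    vec g(d, fill::zeros);
    mat H(d, d, fill::zeros);
    double ca = std::exp(alpha);
    double cc = est_c ? cmax * sigmoid(gamma) : c;
    for (uword k = 0; k < nodes.n_elem; ++k) {
      if (nk[k] <= 0.0) continue;
      double z = ca * (nodes[k] - b);
      double psi = sigmoid(z);
      double p = clampp(cc + (1.0 - cc) * psi);
      double dpsi = psi * (1.0 - psi);
      vec dp(d);
      dp[0] = (1.0 - cc) * dpsi * z;        // d p / d log a
      dp[1] = -(1.0 - cc) * dpsi * ca;      // d p / d b
      if (est_c) dp[2] = (1.0 - psi) * cc * (1.0 - cc / cmax); // d p / d gamma
      double pq = p * (1.0 - p);
      g += ((r[k] - nk[k] * p) / pq) * dp;
      H += (nk[k] / pq) * (dp * dp.t());    // expected information (PSD)
    }
    if (norm(g, "inf") < 1e-7) break;
    H.diag() += 1e-8;
    vec step;
    if (!solve(step, H, g, solve_opts::no_approx) || !step.is_finite()) break;
    double sn = norm(step, "inf");
    if (sn > 2.0) step *= 2.0 / sn;         // trust-region style cap

    double t = 1.0;
    bool accepted = false;
    double moved = 0.0;
    for (int h = 0; h < 20; ++h) {
      double na = alpha + t * step[0];
      double nb = b + t * step[1];
      double ng = est_c ? gamma + t * step[2] : 0.0;
      na = std::min(std::max(na, LOG_A_MIN), LOG_A_MAX);
      nb = std::min(std::max(nb, -B_BOUND), B_BOUND);
      if (est_c) ng = std::min(std::max(ng, -G_BOUND), G_BOUND);
      double ta = std::exp(na);
      double tc = est_c ? cmax * sigmoid(ng) : c;
      double f1 = item_ell(r, nk, nodes, ta, nb, tc);
      if (f1 >= f0) {
        moved = std::abs(na - alpha) + std::abs(nb - b);
        if (est_c) moved += std::abs(ng - gamma);
        alpha = na; b = nb; if (est_c) gamma = ng;
        f0 = f1;
        accepted = true;
        break;
      }
      t *= 0.5;
    }
    if (!accepted || moved < 1e-9) break;
  }
  a = std::exp(alpha);
  if (est_c) c = cmax * sigmoid(gamma);
}

// [[Rcpp::export]]
Rcpp::List em_fit_cpp(const arma::mat& X, const arma::vec& nodes,
                      const arma::vec& weights, const int model,
                      arma::vec a, arma::vec b, arma::vec c,
                      const double cmax, const double tol,
                      const int max_cycles) {
  const uword I = X.n_cols, K = nodes.n_elem;
  const bool est_c = (model == 3);
  const rowvec lw = log(weights).t();

  std::vector<double> ll_trace, q_trace;
  ll_trace.reserve(max_cycles + 1);
  bool converged = false;
  int cycles = 0;
  double ll = 0.0;
  mat post;

  auto estep = [&]() {
    mat logP(I, K), log1mP(I, K);
    for (uword i = 0; i < I; ++i) {
      for (uword k = 0; k < K; ++k) {
        double p = clampp(c[i] + (1.0 - c[i]) * sigmoid(a[i] * (nodes[k] - b[i])));
        logP(i, k) = std::log(p);
        log1mP(i, k) = std::log1p(-p);
      }
    }
    rowvec s = sum(log1mP, 0);
    mat logL = X * (logP - log1mP); // N x K
    logL.each_row() += s + lw;
    vec m = max(logL, 1);
    mat e = exp(logL.each_col() - m);
    vec rs = sum(e, 1);
    post = e.each_col() / rs;
    ll = accu(log(rs) + m);
  };

  for (cycles = 0; cycles < max_cycles; ++cycles) {
    estep();
    ll_trace.push_back(ll);
    rowvec nk = sum(post, 0);
    mat rik = X.t() * post; // I x K expected correct counts
    vec a_old = a, b_old = b, c_old = c;
    double q_gain = 0.0;
    for (uword i = 0; i < I; ++i) {
      double ai = a[i], bi = b[i], ci = c[i];
      double q0 = item_ell(rik.row(i), nk, nodes, ai, bi, ci);
      mstep_item(rik.row(i), nk, nodes, ai, bi, ci, cmax, est_c);
      q_gain += item_ell(rik.row(i), nk, nodes, ai, bi, ci) - q0;
      a[i] = ai; b[i] = bi; c[i] = ci;
    }
    q_trace.push_back(q_gain);
    double delta = std::max(norm(a - a_old, "inf"), norm(b - b_old, "inf"));
    if (est_c) delta = std::max(delta, norm(c - c_old, "inf"));
    if (delta < tol) { converged = true; ++cycles; break; }
  }
  estep(); // log-likelihood at the final parameter values
  ll_trace.push_back(ll);

  return Rcpp::List::create(
    Rcpp::Named("a") = a,
    Rcpp::Named("b") = b,
    Rcpp::Named("c") = c,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("loglik_trace") = ll_trace,
    Rcpp::Named("q_gain_trace") = q_trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_cycles") = cycles);
}
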