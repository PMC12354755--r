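#include <Rcpp.h>
using namespace Rcpp;

// Stable log(1/(1+exp(-z))) and logistic.
static inline double log_plogis(double z) {
  if (z > 0) return -log1p(std::exp(-z));
  return z - log1p(std::exp(z));
}
static inline double plogis_(double z) {
  if (z > 0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// Log-likelihood of one choice sequence under the delta-rule/softmax model.
// chosen: 1/2 option indices in trial order; outcome: observed payoffs.
// [[Rcpp::export]]
double cpp_choice_loglik(IntegerVector chosen, NumericVector outcome,
                         double alpha, double beta) {
  const int n = chosen.size();
  double Q[2] = {0.0, 0.0};
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = chosen[t] - 1, o = 1 - c;
    double z = beta * (Q[c] - Q[o]);
    ll += log_plogis(z);
    Q[c] += alpha * (outcome[t] - Q[c]);
  }
  return ll;
}

// Log-likelihood plus gradient wrt (alpha, beta); dQ/dalpha carried by
// recursion G[c] <- (1-alpha) G[c] + (r - Q[c]).
static void seq_ll_grad(const int* chosen, const double* outcome, int n,
                        double alpha, double beta,
                        double& ll, double& dla, double& dlb) {
  double Q[2] = {0.0, 0.0};
  double G[2] = {0.0, 0.0};
  ll = 0.0; dla = 0.0; dlb = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = chosen[t] - 1, o = 1 - c;
    double dq = Q[c] - Q[o];
    double z = beta * dq;
    double p = plogis_(z);
    ll += log_plogis(z);
    dlb += (1.0 - p) * dq;
    dla += beta * (1.0 - p) * (G[c] - G[o]);
    double pe = outcome[t] - Q[c];
    G[c] = (1.0 - alpha) * G[c] + pe;
    Q[c] += alpha * pe;
  }
}

// Joint log-posterior and gradient of the (non-centred) hierarchical model
// on the unconstrained scale.
//
// crossover = true layout:
//   theta = [mu_a, mu_b, mu_da, mu_db, ls_a, ls_b, ls_da, ls_db,
//            nu_a(n), nu_b(n), nu_da(n), nu_db(n)]          (8 + 4n)
// crossover = false layout:
//   theta = [mu_a, mu_b, ls_a, ls_b, nu_a(n), nu_b(n)]      (4 + 2n)
//
// Sequences are ragged: seq_pid (0-based participant), seq_sess
// (0 = placebo/single, 1 = atomoxetine), seq_start (0-based offsets into
// chosen/outcome), seq_len.
// [[Rcpp::export]]
List cpp_hier_lpgrad(NumericVector theta, int n_sub, bool crossover,
                     IntegerVector seq_pid, IntegerVector seq_sess,
                     IntegerVector seq_start, IntegerVector seq_len,
                     IntegerVector chosen, NumericVector outcome) {
  const int n_mu = crossover ? 4 : 2;
  const int n_par = crossover ? (8 + 4 * n_sub) : (4 + 2 * n_sub);
  if (theta.size() != n_par) stop("theta has wrong length");
  NumericVector grad(n_par);
  double lp = 0.0;

  const double mu_a = theta[0], mu_b = theta[1];
  const double mu_da = crossover ? theta[2] : 0.0;
  const double mu_db = crossover ? theta[3] : 0.0;
  const int ls_off = n_mu;
  const double sa = std::exp(theta[ls_off + 0]);
  const double sb = std::exp(theta[ls_off + 1]);
  const double sda = crossover ? std::exp(theta[ls_off + 2]) : 0.0;
  const double sdb = crossover ? std::exp(theta[ls_off + 3]) : 0.0;
  const int nu_off = crossover ? 8 : 4;
  const int nb = n_sub; // block size for nu groups

  // Priors: mu, nu ~ N(0,1); sigma ~ half-N(0,1) with log-scale Jacobian.
  for (int k = 0; k < n_mu; ++k) {
    lp += -0.5 * theta[k] * theta[k];
    grad[k] += -theta[k];
  }
  int n_ls = crossover ? 4 : 2;
  for (int k = 0; k < n_ls; ++k) {
    double s = std::exp(theta[ls_off + k]);
    lp += -0.5 * s * s + theta[ls_off + k];
    grad[ls_off + k] += -s * s + 1.0;
  }
  for (int k = nu_off; k < n_par; ++k) {
    lp += -0.5 * theta[k] * theta[k];
    grad[k] += -theta[k];
  }

  const int n_seq = seq_pid.size();
  for (int s = 0; s < n_seq; ++s) {
    const int j = seq_pid[s];
    const bool atx = crossover && seq_sess[s] == 1;
    const double nu_a = theta[nu_off + j];
    const double nu_b = theta[nu_off + nb + j];
    double u_a = mu_a + sa * nu_a;
    double u_b = mu_b + sb * nu_b;
    double nu_da = 0.0, nu_db = 0.0;
    if (atx) {
      nu_da = theta[nu_off + 2 * nb + j];
      nu_db = theta[nu_off + 3 * nb + j];
      u_a += mu_da + sda * nu_da;
      u_b += mu_db + sdb * nu_db;
    }
    const double alpha = R::pnorm(u_a, 0.0, 1.0, 1, 0);
    const double beta = 10.0 * R::pnorm(u_b, 0.0, 1.0, 1, 0);

    double ll, dla, dlb;
    seq_ll_grad(&chosen[seq_start[s]], &outcome[seq_start[s]], seq_len[s],
                alpha, beta, ll, dla, dlb);
    lp += ll;
    const double du_a = dla * R::dnorm(u_a, 0.0, 1.0, 0);
    const double du_b = dlb * 10.0 * R::dnorm(u_b, 0.0, 1.0, 0);

    grad[0] += du_a;
    grad[1] += du_b;
    grad[ls_off + 0] += du_a * sa * nu_a;
    grad[ls_off + 1] += du_b * sb * nu_b;
    grad[nu_off + j] += du_a * sa;
    grad[nu_off + nb + j] += du_b * sb;
    if (atx) {
      grad[2] += du_a;
      grad[3] += du_b;
      grad[ls_off + 2] += du_a * sda * nu_da;
      grad[ls_off + 3] += du_b * sdb * nu_db;
      grad[nu_off + 2 * nb + j] += du_a * sda;
      grad[nu_off + 3 * nb + j] += du_b * sdb;
    }
  }
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// Simulate one agent through a schedule of one stimulus pair.
// correct_opt: 1/2 per trial; out_correct/out_incorrect: payoff the agent
// receives if it picks that option. Uses R's RNG (respects set.seed()).
// [[Rcpp::export]]
List cpp_simulate_choices(IntegerVector correct_opt,
                          NumericVector out_correct,
                          NumericVector out_incorrect,
                          double alpha, double beta) {
  const int n = correct_opt.size();
  IntegerVector action(n);
  NumericVector outcome(n);
  LogicalVector hit(n);
  double Q[2] = {0.0, 0.0};
  for (int t = 0; t < n; ++t) {
    double z = beta * (Q[0] - Q[1]);
    double p1 = plogis_(z); // P(choose option 1)
    int a = (unif_rand() < p1) ? 1 : 2;
    double r = (a == correct_opt[t]) ? out_correct[t] : out_incorrect[t];
    action[t] = a;
    outcome[t] = r;
    hit[t] = (a == correct_opt[t]);
    int c = a - 1;
    Q[c] += alpha * (r - Q[c]);
  }
  return List::create(_["action"] = action, _["outcome"] = outcome,
                      _["hit"] = hit);
}

// Mean hit rate per (alpha, beta) grid cell over n_agents freshly drawn
// schedules of n_trials. Outcomes: win if the drawn contingency favours the
// picked option, else miss payoff. Gain: good=+0.5/0; loss: good=0/-0.5.
// [[Rcpp::export]]
NumericMatrix cpp_grid_hitrate(NumericVector alphas, NumericVector betas,
                               int n_agents, int n_trials,
                               double contingency,
                               double pay_good, double pay_bad) {
  NumericMatrix surf(alphas.size(), betas.size());
  for (int ia = 0; ia < alphas.size(); ++ia) {
    for (int ib = 0; ib < betas.size(); ++ib) {
      const double alpha = alphas[ia], beta = betas[ib];
      double tot = 0.0;
      for (int g = 0; g < n_agents; ++g) {
        double Q[2] = {0.0, 0.0};
        int hits = 0;
        for (int t = 0; t < n_trials; ++t) {
          double z = beta * (Q[0] - Q[1]);
          int a = (unif_rand() < plogis_(z)) ? 0 : 1; // option 0 is correct
          double pgood = (a == 0) ? contingency : 1.0 - contingency;
          double r = (unif_rand() < pgood) ? pay_good : pay_bad;
          if (a == 0) ++hits;
          Q[a] += alpha * (r - Q[a]);
        }
        tot += (double)hits / n_trials;
      }
      surf(ia, ib) = tot / n_agents;
    }
  }
  return surf;
}

// Per-row maximum absolute cluster-mass statistic: contiguous runs of
// t > thr (summed t) or t < -thr (summed |t|), max over both signs.
// [[Rcpp::export]]
NumericVector cpp_max_cms(NumericMatrix tmat, double thr) {
  const int n = tmat.nrow(), m = tmat.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = 0.0, run = 0.0;
    int sign = 0;
    for (int j = 0; j < m; ++j) {
      double t = tmat(i, j);
      int s = (t > thr) ? 1 : (t < -thr ? -1 : 0);
      if (s != 0 && s == sign) {
        run += std::fabs(t);
      } else {
        if (run > best) best = run;
        run = (s != 0) ? std::fabs(t) : 0.0;
      }
      sign = s;
    }
    if (run > best) best = run;
    out[i] = best;
  }
  return out;
}
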