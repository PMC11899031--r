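#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sweep for the BYM Poisson log-linear model:
//   O_i ~ Poisson(E_i * exp(alpha + u_i + v_i))
//   u   ~ intrinsic CAR(tau_u), sum-to-zero within each connected component
//   v_i ~ N(0, 1/tau_v),  alpha ~ N(0, alpha_prior_var)
//   tau_u, tau_v ~ Gamma(a, b)  (conjugate Gibbs draws)
// Random-walk Metropolis on alpha, u_i, v_i against their full
// conditionals; Robbins-Monro adaptation of the proposal scales toward
// 0.44 acceptance during burn-in only.  Uses R's RNG throughout, so
// results are reproducible under set.seed().

// [[Rcpp::export]]
List bym_mcmc_cpp(NumericVector O, NumericVector E,
                  IntegerVector adj, IntegerVector adj_ptr,
                  IntegerVector comp_id, int n_comp,
                  int n_iter, int burn_in, int thin,
                  double a_u, double b_u, double a_v, double b_v,
                  double alpha_prior_var,
                  double step_alpha, NumericVector step_u_in,
                  NumericVector step_v_in, bool adapt,
                  double alpha, NumericVector u_in, NumericVector v_in,
                  double tau_u, double tau_v,
                  bool update_tau_u, bool update_tau_v,
                  bool store_uv) {
  const int n = O.size();
  NumericVector u = clone(u_in), v = clone(v_in);
  NumericVector step_u = clone(step_u_in), step_v = clone(step_v_in);
  const double target = 0.44;

  std::vector<double> mu(n);
  for (int i = 0; i < n; ++i) mu[i] = E[i] * std::exp(alpha + u[i] + v[i]);
  double sumO = 0.0;
  for (int i = 0; i < n; ++i) sumO += O[i];

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  NumericVector keep_alpha(n_keep), keep_tau_u(n_keep), keep_tau_v(n_keep);
  NumericMatrix keep_theta(n_keep, n);
  NumericMatrix keep_u(store_uv ? n_keep : 0, store_uv ? n : 0);
  NumericMatrix keep_v(store_uv ? n_keep : 0, store_uv ? n : 0);

  double acc_alpha = 0.0;
  std::vector<double> acc_u(n, 0.0), acc_v(n, 0.0);
  std::vector<int> comp_size(n_comp, 0);
  for (int i = 0; i < n; ++i) comp_size[comp_id[i]]++;
  std::vector<double> comp_mean(n_comp);

  for (int t = 1; t <= n_iter; ++t) {
    const double gam = adapt && t <= burn_in
      ? std::min(0.1, 1.0 / std::sqrt((double)t)) : 0.0;

    // --- alpha ---
    {
      double da = step_alpha * norm_rand();
      double ap = alpha + da;
      double summu = 0.0;
      for (int i = 0; i < n; ++i) summu += mu[i];
      double lr = da * sumO - (std::exp(da) - 1.0) * summu
        - (ap * ap - alpha * alpha) / (2.0 * alpha_prior_var);
      bool acc = std::log(unif_rand()) < lr;
      if (acc) {
        double f = std::exp(da);
        alpha = ap;
        for (int i = 0; i < n; ++i) mu[i] *= f;
        acc_alpha += 1.0;
      }
      if (gam > 0.0)
        step_alpha *= std::exp(gam * ((acc ? 1.0 : 0.0) - target));
    }

    // --- spatial effects u_i ---
    for (int i = 0; i < n; ++i) {
      int d = adj_ptr[i + 1] - adj_ptr[i];
      double m = 0.0;
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) m += u[adj[k]];
      m /= d;
      double du = step_u[i] * norm_rand();
      double up = u[i] + du;
      double lr = du * O[i] - mu[i] * (std::exp(du) - 1.0)
        - 0.5 * tau_u * d * ((up - m) * (up - m) - (u[i] - m) * (u[i] - m));
      bool acc = std::log(unif_rand()) < lr;
      if (acc) {
        mu[i] *= std::exp(du);
        u[i] = up;
        acc_u[i] += 1.0;
      }
      if (gam > 0.0)
        step_u[i] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target));
    }

    // --- unstructured effects v_i ---
    for (int i = 0; i < n; ++i) {
      double dv = step_v[i] * norm_rand();
      double vp = v[i] + dv;
      double lr = dv * O[i] - mu[i] * (std::exp(dv) - 1.0)
        - 0.5 * tau_v * (vp * vp - v[i] * v[i]);
      bool acc = std::log(unif_rand()) < lr;
      if (acc) {
        mu[i] *= std::exp(dv);
        v[i] = vp;
        acc_v[i] += 1.0;
      }
      if (gam > 0.0)
        step_v[i] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target));
    }

    // --- recentre u per component, absorb mean into alpha ---
    std::fill(comp_mean.begin(), comp_mean.end(), 0.0);
    for (int i = 0; i < n; ++i) comp_mean[comp_id[i]] += u[i];
    double shift = 0.0;
    for (int c = 0; c < n_comp; ++c) {
      comp_mean[c] /= comp_size[c];
      shift += comp_mean[c] * comp_size[c];
    }
    alpha += shift / n;
    for (int i = 0; i < n; ++i) {
      u[i] -= comp_mean[comp_id[i]];
      mu[i] = E[i] * std::exp(alpha + u[i] + v[i]);
    }

    // --- conjugate precision updates ---
    if (update_tau_v) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += v[i] * v[i];
      tau_v = R::rgamma(a_v + 0.5 * n, 1.0 / (b_v + 0.5 * ss));
    }
    if (update_tau_u) {
      double ssd = 0.0;  // directed pair sum: twice the unordered sum
      for (int i = 0; i < n; ++i)
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          double d = u[i] - u[adj[k]];
          ssd += d * d;
        }
      tau_u = R::rgamma(a_u + 0.5 * (n - n_comp),
                        1.0 / (b_u + 0.25 * ssd));
    }

    if (t > burn_in && (t - burn_in) % thin == 0) {
      int s = (t - burn_in) / thin - 1;
      keep_alpha[s] = alpha;
      keep_tau_u[s] = tau_u;
      keep_tau_v[s] = tau_v;
      for (int i = 0; i < n; ++i)
        keep_theta(s, i) = std::exp(alpha + u[i] + v[i]);
      if (store_uv)
        for (int i = 0; i < n; ++i) {
          keep_u(s, i) = u[i];
          keep_v(s, i) = v[i];
        }
    }
  }

  return List::create(
    _["alpha"] = keep_alpha, _["tau_u"] = keep_tau_u,
    _["tau_v"] = keep_tau_v, _["theta"] = keep_theta,
    _["u"] = keep_u, _["v"] = keep_v,
    _["acc_alpha"] = acc_alpha / n_iter,
    _["acc_u"] = NumericVector(acc_u.begin(), acc_u.end()) / n_iter,
    _["acc_v"] = NumericVector(acc_v.begin(), acc_v.end()) / n_iter,
    _["final_alpha"] = alpha, _["final_u"] = u, _["final_v"] = v,
    _["final_tau_u"] = tau_u, _["final_tau_v"] = tau_v,
    _["final_step_alpha"] = step_alpha,
    _["final_step_u"] = step_u, _["final_step_v"] = step_v);
}
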