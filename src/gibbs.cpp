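// Gibbs sampler for the regime-switching two-level dynamic factor model.
//
// Layout conventions (all 0-based internally):
//   Y1   : N1 x p x T cube of within responses (NA allowed), T = observed window
//   Y2   : N1 x q between responses (complete)
//   S    : N1 x T discrete states in {1,2}; occasion 0 fixed at 1
//   S_obs: N1 x T; 0 = latent, 1/2 = observed (dropout tail)
//
// Full conditionals are conjugate throughout except where the logistic
// transition model breaks conjugacy (eta1, eta2: Metropolis step with the
// conjugate-Gaussian part as proposal; gamma: adaptive random-walk MH).
// p12 is drawn exactly from its truncated-Beta full conditional.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// log P(stay in 1) and log P(leave 1) from the logit nu
static inline double log_p11(double nu) { return -log1pexp_(-nu); }
static inline double log_p21(double nu) { return -log1pexp_(nu); }

// N(mu, sd) truncated to (0, Inf)
static double rtnorm_pos(double mu, double sd) {
  double a = -mu / sd;
  double z;
  if (a < 0.4) {
    do { z = norm_rand(); } while (z < a);
  } else {
    double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      double e = exp_rand() / alpha + a;
      double d = e - alpha;
      if (unif_rand() <= std::exp(-0.5 * d * d)) { z = e; break; }
    }
  }
  return mu + sd * z;
}

struct Pars {
  arma::vec lambda1, sig2eps1;      // p
  arma::vec lambda2, sig2eps2;      // q
  double sig2eta2;
  arma::vec alpha21, dalpha;        // J (state-1 level, state-2 shift >= 0)
  arma::vec beta2, dbeta2;
  arma::vec b1, db1;
  arma::vec omega2, domega2;
  arma::vec s2z1, s2z2;             // J
  double gamma1, gamma2;
  arma::vec gamma3, gamma4;         // J
  double p12;
};

// [[Rcpp::export]]
List gibbs_chain_cpp(NumericVector Y1_in, NumericMatrix Y2_in,
                     IntegerVector item_map, IntegerVector scaling_items,
                     IntegerMatrix S_obs_in, LogicalVector gamma4_mask,
                     List prior, int n_iter, int n_burnin, int thin,
                     int latent_stride, double init_jitter,
                     double eta0_var) {
  IntegerVector dimY = Y1_in.attr("dim");
  const int N1 = dimY[0], p = dimY[1], T = dimY[2];
  arma::cube Y1(Y1_in.begin(), N1, p, T);  // copy with NAs
  arma::mat Y2(Y2_in.begin(), N1, Y2_in.ncol());
  const int q = Y2.n_cols;
  int J = 0;
  for (int k = 0; k < p; ++k) J = std::max(J, item_map[k]);
  arma::imat S_obs(N1, T);
  for (int i = 0; i < N1; ++i)
    for (int t = 0; t < T; ++t) S_obs(i, t) = S_obs_in(i, t);

  const double pr_load_mean = prior["loading_mean"], pr_load_sd = prior["loading_sd"];
  const double pr_coef_mean = prior["coef_mean"], pr_coef_sd = prior["coef_sd"];
  const double pr_da_mean = prior["delta_alpha_mean"], pr_da_sd = prior["delta_alpha_sd"];
  const double pr_shape = prior["prec_shape"], pr_rate = prior["prec_rate"];
  const double p12_min = prior["p12_min"], p12_max = prior["p12_max"];
  const double coef_prec = 1.0 / (pr_coef_sd * pr_coef_sd);
  const double load_prec = 1.0 / (pr_load_sd * pr_load_sd);

  // missingness mask
  arma::ucube miss(N1, p, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < p; ++k)
      for (int i = 0; i < N1; ++i)
        if (!arma::is_finite(Y1(i, k, t))) { miss(i, k, t) = 1; Y1(i, k, t) = 0.0; }

  // --- initial values: prior medians plus jitter ---------------------------
  Pars th;
  const double med_prec = R::qgamma(0.5, pr_shape, 1.0 / pr_rate, 1, 0);
  const double med_var = 1.0 / med_prec;
  const double med_tn = pr_load_mean + pr_load_sd * R::qnorm(0.75, 0.0, 1.0, 1, 0);
  th.lambda1.set_size(p); th.sig2eps1.set_size(p);
  for (int k = 0; k < p; ++k) {
    th.lambda1[k] = med_tn + init_jitter * norm_rand();
    if (th.lambda1[k] < 0.05) th.lambda1[k] = 0.05;
    th.sig2eps1[k] = med_var * std::exp(init_jitter * norm_rand());
  }
  for (int j = 0; j < J; ++j) th.lambda1[scaling_items[j] - 1] = 1.0;
  th.lambda2.set_size(q); th.sig2eps2.set_size(q);
  for (int k = 0; k < q; ++k) {
    th.lambda2[k] = med_tn + init_jitter * norm_rand();
    if (th.lambda2[k] < 0.05) th.lambda2[k] = 0.05;
    th.sig2eps2[k] = med_var * std::exp(init_jitter * norm_rand());
  }
  th.lambda2[0] = 1.0;
  th.sig2eta2 = med_var * std::exp(init_jitter * norm_rand());
  auto jn = [&](double m) { return m + init_jitter * norm_rand(); };
  th.alpha21 = arma::vec(J); th.dalpha = arma::vec(J);
  th.beta2 = arma::vec(J); th.dbeta2 = arma::vec(J);
  th.b1 = arma::vec(J); th.db1 = arma::vec(J);
  th.omega2 = arma::vec(J); th.domega2 = arma::vec(J);
  th.s2z1 = arma::vec(J); th.s2z2 = arma::vec(J);
  th.gamma3 = arma::vec(J); th.gamma4 = arma::vec(J, arma::fill::zeros);
  for (int j = 0; j < J; ++j) {
    th.alpha21[j] = jn(0.0);
    th.dalpha[j] = std::abs(jn(med_tn));
    th.beta2[j] = jn(0.0); th.dbeta2[j] = jn(0.0);
    th.b1[j] = jn(0.2); th.db1[j] = jn(0.0);
    th.omega2[j] = jn(0.0); th.domega2[j] = jn(0.0);
    th.s2z1[j] = med_var * std::exp(init_jitter * norm_rand());
    th.s2z2[j] = med_var * std::exp(init_jitter * norm_rand());
    if (gamma4_mask[j]) th.gamma4[j] = jn(0.0);
  }
  th.gamma1 = jn(1.0); th.gamma2 = jn(0.0);
  th.gamma3.transform([&](double) { return jn(0.0); });
  th.p12 = 0.5 * (p12_min + p12_max);

  arma::cube eta1(N1, J, T, arma::fill::zeros);
  arma::vec eta2(N1, arma::fill::zeros);
  arma::mat zeta2(N1, J, arma::fill::zeros);
  arma::imat S(N1, T);
  for (int i = 0; i < N1; ++i)
    for (int t = 0; t < T; ++t) S(i, t) = (S_obs(i, t) == 0) ? 1 : S_obs(i, t);

  // caches: person-resolved intercept/AR per state, transition slopes
  arma::cube alpha1c(N1, J, 2), arc(N1, J, 2);
  arma::mat gslope(N1, J);      // gamma3_j + gamma4_j * eta2_i
  auto refresh_struct_cache = [&]() {
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < N1; ++i) {
        alpha1c(i, j, 0) = th.alpha21[j] + th.beta2[j] * eta2[i] + zeta2(i, j);
        alpha1c(i, j, 1) = (th.alpha21[j] + th.dalpha[j]) +
          (th.beta2[j] + th.dbeta2[j]) * eta2[i] + zeta2(i, j);
        arc(i, j, 0) = th.b1[j] + th.omega2[j] * eta2[i];
        arc(i, j, 1) = (th.b1[j] + th.db1[j]) + (th.omega2[j] + th.domega2[j]) * eta2[i];
      }
    }
  };
  auto refresh_gslope = [&]() {
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < N1; ++i)
        gslope(i, j) = th.gamma3[j] + th.gamma4[j] * eta2[i];
  };
  auto nu_it = [&](int i, int t) {  // logit of staying, from occasion t to t+1
    double nu = th.gamma1 + th.gamma2 * eta2[i];
    for (int j = 0; j < J; ++j) nu += gslope(i, j) * eta1(i, j, t);
    return nu;
  };

  // adaptive RW-MH scales for gamma coordinates: [g1, g2, g3 (J), g4 (masked)]
  int n_gco = 2 + J;
  std::vector<int> g4_idx;
  for (int j = 0; j < J; ++j) if (gamma4_mask[j]) { g4_idx.push_back(j); ++n_gco; }
  arma::vec gstep(n_gco, arma::fill::value(0.15));

  // storage
  const int n_kept = (n_iter - n_burnin + thin - 1) / thin;
  const int n_par = 2 * p + 2 * q + 1 + 10 * J + 2 + 2 * J + 1;
  arma::mat par_draws(n_kept, n_par);
  const int n_store = (n_kept + latent_stride - 1) / latent_stride;
  arma::mat eta1_store(N1 * J * T, n_store);
  arma::mat eta2_store(N1, n_store);
  arma::mat zeta2_store(N1 * J, n_store);
  arma::imat S_store(N1 * T, n_store);
  arma::ivec store_kept_idx(n_store);
  arma::mat pstate2(N1, T, arma::fill::zeros);

  // scratch for the state FFBS
  arma::mat fwd(T, 2), lem(T, 2);
  arma::vec p11row(T);

  int kept = 0, stored = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
    const bool adapting = iter < n_burnin;

    refresh_struct_cache();
    refresh_gslope();

    // --- 1. impute missing within responses -------------------------------
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < p; ++k) {
        const int f = item_map[k] - 1;
        for (int i = 0; i < N1; ++i)
          if (miss(i, k, t))
            Y1(i, k, t) = th.lambda1[k] * eta1(i, f, t) +
              std::sqrt(th.sig2eps1[k]) * norm_rand();
      }

    // --- 2. within-factor scores eta1 (conjugate proposal + logistic MH) --
    // measurement precision per factor is shared across (i, t)
    arma::vec mprec(J, arma::fill::zeros);
    for (int k = 0; k < p; ++k)
      mprec[item_map[k] - 1] += th.lambda1[k] * th.lambda1[k] / th.sig2eps1[k];
    for (int i = 0; i < N1; ++i) {
      for (int t = 0; t < T; ++t) {
        const int s_t = S(i, t) - 1;
        const int s_n = (t + 1 < T) ? S(i, t + 1) - 1 : 0;
        const bool has_next = t + 1 < T;
        const bool logit_dep = has_next && S(i, t) == 1; // transition out of 1
        double nu_old = 0.0;
        if (logit_dep) nu_old = nu_it(i, t);
        for (int j = 0; j < J; ++j) {
          double prec = mprec[j], mz = 0.0;
          for (int k = 0; k < p; ++k)
            if (item_map[k] - 1 == j)
              mz += th.lambda1[k] * Y1(i, k, t) / th.sig2eps1[k];
          if (t == 0) {
            prec += 1.0 / eta0_var;                 // diffuse initial prior
          } else {
            const double mu = alpha1c(i, j, s_t) + arc(i, j, s_t) * eta1(i, j, t - 1);
            prec += 1.0 / th.s2z1[j];
            mz += mu / th.s2z1[j];
          }
          if (has_next) {
            const double ar_n = arc(i, j, s_n);
            const double res = eta1(i, j, t + 1) - alpha1c(i, j, s_n);
            prec += ar_n * ar_n / th.s2z1[j];
            mz += ar_n * res / th.s2z1[j];
          }
          const double v = 1.0 / prec, m = mz * v;
          const double prop = m + std::sqrt(v) * norm_rand();
          if (!logit_dep) {
            eta1(i, j, t) = prop;
          } else {
            const double nu_new = nu_old + gslope(i, j) * (prop - eta1(i, j, t));
            const bool stay = S(i, t + 1) == 1;
            const double lr = stay ? (log_p11(nu_new) - log_p11(nu_old))
                                   : (log_p21(nu_new) - log_p21(nu_old));
            if (lr >= 0.0 || exp_rand() > -lr) {  // accept
              eta1(i, j, t) = prop;
              nu_old = nu_new;
            }
          }
        }
      }
    }

    // --- 3. discrete state paths (forward filter, backward sample) --------
    const double lp12 = std::log(std::max(th.p12, 1e-300));
    const double l1mp12 = std::log1p(-th.p12);
    for (int i = 0; i < N1; ++i) {
      for (int t = 0; t < T; ++t) p11row[t] = 0.0;
      for (int t = 0; t + 1 < T; ++t) p11row[t] = nu_it(i, t);
      // log emissions of eta1_t given state and eta1_{t-1}
      for (int t = 1; t < T; ++t) {
        for (int s = 0; s < 2; ++s) {
          double le = 0.0;
          for (int j = 0; j < J; ++j) {
            const double mu = alpha1c(i, j, s) + arc(i, j, s) * eta1(i, j, t - 1);
            const double r = eta1(i, j, t) - mu;
            le += -0.5 * r * r / th.s2z1[j] - 0.5 * std::log(th.s2z1[j]);
          }
          lem(t, s) = le;
        }
        if (S_obs(i, t) == 1) lem(t, 1) = -1e300;
        if (S_obs(i, t) == 2) lem(t, 0) = -1e300;
      }
      fwd(0, 0) = 1.0; fwd(0, 1) = 0.0;  // occasion 0 fixed at state 1
      for (int t = 1; t < T; ++t) {
        const double nu = p11row[t - 1];
        const double lt11 = log_p11(nu), lt12 = log_p21(nu);
        double l0, l1;
        {
          // into state 1
          double a = (fwd(t - 1, 0) > 0 ? std::log(fwd(t - 1, 0)) + lt11 : -1e300);
          double b = (fwd(t - 1, 1) > 0 ? std::log(fwd(t - 1, 1)) + lp12 : -1e300);
          l0 = std::max(a, b) + std::log(std::exp(std::min(a, b) - std::max(a, b)) + 1.0);
          if (a < -1e290 && b < -1e290) l0 = -1e300;
          l0 += lem(t, 0);
          // into state 2
          a = (fwd(t - 1, 0) > 0 ? std::log(fwd(t - 1, 0)) + lt12 : -1e300);
          b = (fwd(t - 1, 1) > 0 ? std::log(fwd(t - 1, 1)) + l1mp12 : -1e300);
          l1 = std::max(a, b) + std::log(std::exp(std::min(a, b) - std::max(a, b)) + 1.0);
          if (a < -1e290 && b < -1e290) l1 = -1e300;
          l1 += lem(t, 1);
        }
        const double mx = std::max(l0, l1);
        const double w0 = std::exp(l0 - mx), w1 = std::exp(l1 - mx);
        fwd(t, 0) = w0 / (w0 + w1); fwd(t, 1) = w1 / (w0 + w1);
      }
      // backward sampling
      S(i, T - 1) = (unif_rand() < fwd(T - 1, 0)) ? 1 : 2;
      for (int t = T - 2; t >= 1; --t) {
        const double nu = p11row[t];
        double w0, w1;
        if (S(i, t + 1) == 1) {
          w0 = fwd(t, 0) * std::exp(log_p11(nu));
          w1 = fwd(t, 1) * th.p12;
        } else {
          w0 = fwd(t, 0) * std::exp(log_p21(nu));
          w1 = fwd(t, 1) * (1.0 - th.p12);
        }
        const double tot = w0 + w1;
        S(i, t) = (tot <= 0.0) ? S(i, t) : ((unif_rand() < w0 / tot) ? 1 : 2);
      }
      S(i, 0) = 1;
    }

    // --- 4. measurement parameters ----------------------------------------
    for (int k = 0; k < p; ++k) {
      const int f = item_map[k] - 1;
      bool is_scaling = false;
      for (int j = 0; j < J; ++j) if (scaling_items[j] - 1 == k) is_scaling = true;
      double see = 0.0, sey = 0.0, ssr = 0.0;
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < N1; ++i) {
          const double e = eta1(i, f, t);
          see += e * e; sey += e * Y1(i, k, t);
        }
      if (!is_scaling) {
        const double prec = load_prec + see / th.sig2eps1[k];
        const double m = (pr_load_mean * load_prec + sey / th.sig2eps1[k]) / prec;
        th.lambda1[k] = rtnorm_pos(m, std::sqrt(1.0 / prec));
      }
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < N1; ++i) {
          const double r = Y1(i, k, t) - th.lambda1[k] * eta1(i, f, t);
          ssr += r * r;
        }
      th.sig2eps1[k] = 1.0 / R::rgamma(pr_shape + 0.5 * N1 * T,
                                       1.0 / (pr_rate + 0.5 * ssr));
    }
    for (int k = 0; k < q; ++k) {
      double see = arma::dot(eta2, eta2);
      double sey = arma::dot(eta2, Y2.col(k));
      if (k > 0) {
        const double prec = load_prec + see / th.sig2eps2[k];
        const double m = (pr_load_mean * load_prec + sey / th.sig2eps2[k]) / prec;
        th.lambda2[k] = rtnorm_pos(m, std::sqrt(1.0 / prec));
      }
      arma::vec r = Y2.col(k) - th.lambda2[k] * eta2;
      th.sig2eps2[k] = 1.0 / R::rgamma(pr_shape + 0.5 * N1,
                                       1.0 / (pr_rate + 0.5 * arma::dot(r, r)));
    }
    th.sig2eta2 = 1.0 / R::rgamma(pr_shape + 0.5 * N1,
                                  1.0 / (pr_rate + 0.5 * arma::dot(eta2, eta2)));

    // --- 5. between-factor scores eta2 (conjugate proposal + logistic MH) -
    {
      double meas_prec = 1.0 / th.sig2eta2;
      for (int k = 0; k < q; ++k)
        meas_prec += th.lambda2[k] * th.lambda2[k] / th.sig2eps2[k];
      for (int i = 0; i < N1; ++i) {
        double prec = meas_prec, mz = 0.0;
        for (int k = 0; k < q; ++k)
          mz += th.lambda2[k] * Y2(i, k) / th.sig2eps2[k];
        for (int t = 1; t < T; ++t) {
          const int s = S(i, t) - 1;
          for (int j = 0; j < J; ++j) {
            const double eprev = eta1(i, j, t - 1);
            const double bet = (s == 0) ? th.beta2[j] : th.beta2[j] + th.dbeta2[j];
            const double om = (s == 0) ? th.omega2[j] : th.omega2[j] + th.domega2[j];
            const double al = (s == 0) ? th.alpha21[j] : th.alpha21[j] + th.dalpha[j];
            const double b = (s == 0) ? th.b1[j] : th.b1[j] + th.db1[j];
            const double c = bet + om * eprev;
            const double r = eta1(i, j, t) - al - zeta2(i, j) - b * eprev;
            prec += c * c / th.s2z1[j];
            mz += c * r / th.s2z1[j];
          }
        }
        const double v = 1.0 / prec;
        const double prop = mz * v + std::sqrt(v) * norm_rand();
        // MH correction: logistic transition terms depend on eta2
        double lr = 0.0;
        for (int t = 1; t < T; ++t) {
          if (S(i, t - 1) != 1) continue;
          double base = th.gamma1, slope = th.gamma2;
          for (int j = 0; j < J; ++j) {
            base += th.gamma3[j] * eta1(i, j, t - 1);
            slope += th.gamma4[j] * eta1(i, j, t - 1);
          }
          const double nu_o = base + slope * eta2[i];
          const double nu_n = base + slope * prop;
          lr += (S(i, t) == 1) ? (log_p11(nu_n) - log_p11(nu_o))
                               : (log_p21(nu_n) - log_p21(nu_o));
        }
        if (lr >= 0.0 || exp_rand() > -lr) eta2[i] = prop;
      }
      refresh_struct_cache();
      refresh_gslope();
    }

    // --- 6. person random intercepts zeta2 (conjugate) --------------------
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < N1; ++i) {
        double prec = 1.0 / th.s2z2[j], mz = 0.0;
        for (int t = 1; t < T; ++t) {
          const int s = S(i, t) - 1;
          const double mu_wo = (alpha1c(i, j, s) - zeta2(i, j)) +
            arc(i, j, s) * eta1(i, j, t - 1);
          prec += 1.0 / th.s2z1[j];
          mz += (eta1(i, j, t) - mu_wo) / th.s2z1[j];
        }
        const double v = 1.0 / prec;
        zeta2(i, j) = mz * v + std::sqrt(v) * norm_rand();
        for (int s = 0; s < 2; ++s)
          alpha1c(i, j, s) = ((s == 0) ? th.alpha21[j]
                                       : th.alpha21[j] + th.dalpha[j]) +
            ((s == 0) ? th.beta2[j] : th.beta2[j] + th.dbeta2[j]) * eta2[i] +
            zeta2(i, j);
      }
    }

    // --- 7. structural coefficients (scalar conjugate sweeps) -------------
    for (int j = 0; j < J; ++j) {
      const int nobs = N1 * (T - 1);
      arma::vec rfull(nobs), x_e2(nobs), x_ar(nobs), x_om(nobs);
      arma::ivec d2(nobs);
      int idx = 0;
      for (int i = 0; i < N1; ++i)
        for (int t = 1; t < T; ++t, ++idx) {
          const int s = S(i, t) - 1;
          const double eprev = eta1(i, j, t - 1);
          x_e2[idx] = eta2[i]; x_ar[idx] = eprev; x_om[idx] = eprev * eta2[i];
          d2[idx] = s;
          rfull[idx] = eta1(i, j, t) -
            (alpha1c(i, j, s) + arc(i, j, s) * eprev);
        }
      const double isz = 1.0 / th.s2z1[j];
      // parameter order: alpha21, dalpha, beta2, dbeta2, b1, db1, omega2, domega2
      for (int par = 0; par < 8; ++par) {
        const bool is_delta = (par % 2 == 1);
        double cur;
        switch (par) {
          case 0: cur = th.alpha21[j]; break;  case 1: cur = th.dalpha[j]; break;
          case 2: cur = th.beta2[j]; break;    case 3: cur = th.dbeta2[j]; break;
          case 4: cur = th.b1[j]; break;       case 5: cur = th.db1[j]; break;
          case 6: cur = th.omega2[j]; break;   default: cur = th.domega2[j]; break;
        }
        double sxx = 0.0, sxr = 0.0;
        for (int n = 0; n < nobs; ++n) {
          double x;
          switch (par / 2) {
            case 0: x = 1.0; break;
            case 1: x = x_e2[n]; break;
            case 2: x = x_ar[n]; break;
            default: x = x_om[n]; break;
          }
          if (is_delta && d2[n] == 0) continue;
          sxx += x * x;
          sxr += x * (rfull[n] + cur * x);
        }
        double prec, pm;
        if (par == 1) { prec = 1.0 / (pr_da_sd * pr_da_sd); pm = pr_da_mean; }
        else { prec = coef_prec; pm = pr_coef_mean; }
        const double post_prec = prec + sxx * isz;
        const double post_m = (pm * prec + sxr * isz) / post_prec;
        const double post_sd = std::sqrt(1.0 / post_prec);
        const double nv = (par == 1) ? rtnorm_pos(post_m, post_sd)
                                     : post_m + post_sd * norm_rand();
        const double diff = nv - cur;
        if (diff != 0.0) {
          for (int n = 0; n < nobs; ++n) {
            double x;
            switch (par / 2) {
              case 0: x = 1.0; break;
              case 1: x = x_e2[n]; break;
              case 2: x = x_ar[n]; break;
              default: x = x_om[n]; break;
            }
            if (is_delta && d2[n] == 0) continue;
            rfull[n] -= diff * x;
          }
        }
        switch (par) {
          case 0: th.alpha21[j] = nv; break;  case 1: th.dalpha[j] = nv; break;
          case 2: th.beta2[j] = nv; break;    case 3: th.dbeta2[j] = nv; break;
          case 4: th.b1[j] = nv; break;       case 5: th.db1[j] = nv; break;
          case 6: th.omega2[j] = nv; break;   default: th.domega2[j] = nv; break;
        }
      }
      // innovation variance from the final residuals
      th.s2z1[j] = 1.0 / R::rgamma(pr_shape + 0.5 * nobs,
                                   1.0 / (pr_rate + 0.5 * arma::dot(rfull, rfull)));
      // random-intercept variance
      double ssz = 0.0;
      for (int i = 0; i < N1; ++i) ssz += zeta2(i, j) * zeta2(i, j);
      th.s2z2[j] = 1.0 / R::rgamma(pr_shape + 0.5 * N1,
                                   1.0 / (pr_rate + 0.5 * ssz));
      refresh_struct_cache();
    }

    // --- 8. transition coefficients gamma (adaptive RW-MH) ----------------
    {
      // collect transition observations out of state 1
      std::vector<int> oi, ot; std::vector<char> oy;
      for (int i = 0; i < N1; ++i)
        for (int t = 1; t < T; ++t)
          if (S(i, t - 1) == 1) {
            oi.push_back(i); ot.push_back(t - 1);
            oy.push_back(S(i, t) == 1 ? 1 : 0);
          }
      const int M = oi.size();
      refresh_gslope();
      arma::vec nu(M);
      for (int n = 0; n < M; ++n) nu[n] = nu_it(oi[n], ot[n]);
      auto coord_x = [&](int co, int n) -> double {
        if (co == 0) return 1.0;
        if (co == 1) return eta2[oi[n]];
        if (co < 2 + J) return eta1(oi[n], co - 2, ot[n]);
        const int j = g4_idx[co - 2 - J];
        return eta1(oi[n], j, ot[n]) * eta2[oi[n]];
      };
      for (int co = 0; co < n_gco; ++co) {
        double *tgt;
        if (co == 0) tgt = &th.gamma1;
        else if (co == 1) tgt = &th.gamma2;
        else if (co < 2 + J) tgt = &th.gamma3[co - 2];
        else tgt = &th.gamma4[g4_idx[co - 2 - J]];
        const double cur = *tgt;
        const double prop = cur + gstep[co] * norm_rand();
        double lr = (R::dnorm(prop, pr_coef_mean, pr_coef_sd, 1) -
                     R::dnorm(cur, pr_coef_mean, pr_coef_sd, 1));
        for (int n = 0; n < M; ++n) {
          const double dnu = (prop - cur) * coord_x(co, n);
          const double nn = nu[n] + dnu;
          lr += oy[n] ? (log_p11(nn) - log_p11(nu[n]))
                      : (log_p21(nn) - log_p21(nu[n]));
        }
        const bool acc = (lr >= 0.0 || exp_rand() > -lr);
        if (acc) {
          for (int n = 0; n < M; ++n) nu[n] += (prop - cur) * coord_x(co, n);
          *tgt = prop;
        }
        if (adapting) {
          const double rate = std::min(0.05, 5.0 / std::sqrt(iter + 1.0));
          gstep[co] *= std::exp(rate * ((acc ? 1.0 : 0.0) - 0.44));
          gstep[co] = std::min(std::max(gstep[co], 1e-3), 5.0);
        }
      }
      refresh_gslope();
    }

    // --- 9. return probability p12 (exact truncated-Beta draw) ------------
    {
      int n12 = 0, n22 = 0;
      for (int i = 0; i < N1; ++i)
        for (int t = 1; t < T; ++t)
          if (S(i, t - 1) == 2) { if (S(i, t) == 1) ++n12; else ++n22; }
      const double a = 1.0 + n12, b = 1.0 + n22;
      const double lo = R::pbeta(p12_min, a, b, 1, 0);
      const double hi = R::pbeta(p12_max, a, b, 1, 0);
      double u = lo + unif_rand() * (hi - lo);
      double x = R::qbeta(u, a, b, 1, 0);
      if (!std::isfinite(x) || x < p12_min) x = p12_min;
      if (x > p12_max) x = p12_max;
      th.p12 = x;
    }

    // --- store --------------------------------------------------------------
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0) {
      int c = 0;
      arma::rowvec row(n_par);
      for (int k = 0; k < p; ++k) row[c++] = th.lambda1[k];
      for (int k = 0; k < p; ++k) row[c++] = th.sig2eps1[k];
      for (int k = 0; k < q; ++k) row[c++] = th.lambda2[k];
      for (int k = 0; k < q; ++k) row[c++] = th.sig2eps2[k];
      row[c++] = th.sig2eta2;
      for (int j = 0; j < J; ++j) row[c++] = th.alpha21[j];
      for (int j = 0; j < J; ++j) row[c++] = th.dalpha[j];
      for (int j = 0; j < J; ++j) row[c++] = th.beta2[j];
      for (int j = 0; j < J; ++j) row[c++] = th.dbeta2[j];
      for (int j = 0; j < J; ++j) row[c++] = th.b1[j];
      for (int j = 0; j < J; ++j) row[c++] = th.db1[j];
      for (int j = 0; j < J; ++j) row[c++] = th.omega2[j];
      for (int j = 0; j < J; ++j) row[c++] = th.domega2[j];
      for (int j = 0; j < J; ++j) row[c++] = th.s2z1[j];
      for (int j = 0; j < J; ++j) row[c++] = th.s2z2[j];
      row[c++] = th.gamma1; row[c++] = th.gamma2;
      for (int j = 0; j < J; ++j) row[c++] = th.gamma3[j];
      for (int j = 0; j < J; ++j) row[c++] = th.gamma4[j];
      row[c++] = th.p12;
      par_draws.row(kept) = row;
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < N1; ++i)
          if (S(i, t) == 2) pstate2(i, t) += 1.0;
      if (kept % latent_stride == 0 && stored < n_store) {
        eta1_store.col(stored) = arma::vectorise(eta1);
        eta2_store.col(stored) = eta2;
        zeta2_store.col(stored) = arma::vectorise(zeta2);
        S_store.col(stored) = arma::vectorise(S);
        store_kept_idx[stored] = kept + 1;  // 1-based kept index
        ++stored;
      }
      ++kept;
    }
  }
  pstate2 /= std::max(kept, 1);

  return List::create(
    _["par_draws"] = par_draws,
    _["pstate2"] = pstate2,
    _["eta1_store"] = eta1_store.cols(0, stored - 1),
    _["eta2_store"] = eta2_store.cols(0, stored - 1),
    _["zeta2_store"] = zeta2_store.cols(0, stored - 1),
    _["S_store"] = S_store.cols(0, stored - 1),
    _["store_kept_idx"] = store_kept_idx.head(stored),
    _["gamma_steps"] = gstep);
}
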