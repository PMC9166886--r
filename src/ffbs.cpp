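// Integrated multi-process forecaster, run once per retained posterior draw.
//
// Per factor j, the state-specific dynamic linear model has design row
// F_i = (1, eta1_j[i, t-1], eta2_i, eta1_j[i, t-1] * eta2_i, zeta2_ij),
// system vector theta_js = (alpha21_js, b1_jjs, beta2_js, omega2_jjs, 1)',
// G = I5, W = 0, V = sigma2_zeta1j * I_N1. Four regime-transition strata
// (s, s') carry independent filters; after each realized occasion the joint
// stratum probabilities are updated from the one-step forecast errors and
// collapsed over s'. Beyond the forecast origin the lagged factor values
// entering F are sampled from the previous horizon's forecast mixture.
//
// In aggregate mode (default) one stratum-probability chain is shared by
// all factors, with the likelihood terms multiplied across factors inside
// the exponent (conditional independence given the state). In per-factor
// mode each factor carries its own chain, following the per-factor
// presentation of the recursions; reported state probabilities then
// average the per-factor chains.
//
// Stratum column order everywhere: (1,1), (2,1), (1,2), (2,2)  [(s, s')].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List ffbs_forecast_cpp(const arma::mat& eta1_store,   // (N1*J*T) x K
                       const arma::mat& eta2_store,   // N1 x K
                       const arma::mat& zeta2_store,  // (N1*J) x K
                       const arma::imat& S_store,     // (N1*T) x K
                       const arma::mat& s2z1_draws,   // K x J
                       const arma::vec& gamma1_draws,
                       const arma::vec& gamma2_draws,
                       const arma::mat& gamma3_draws, // K x J
                       const arma::mat& gamma4_draws, // K x J
                       const arma::vec& p12_draws,
                       int N1, int J, int T, int H,
                       const arma::vec& m0, const arma::mat& C0,
                       bool aggregate_factors) {
  const int K = eta1_store.n_cols;
  const int nch = aggregate_factors ? 1 : J;  // probability chains
  arma::cube sum_mu(N1, J, H, arma::fill::zeros);
  arma::cube sum_mu2(N1, J, H, arma::fill::zeros);
  arma::cube sum_var(N1, J, H, arma::fill::zeros);
  arma::mat sum_p2_fore(N1, H, arma::fill::zeros);
  arma::mat sum_p2_obs(N1, T, arma::fill::zeros);
  const arma::mat I5r = 1e-12 * arma::eye(5, 5);

  for (int k = 0; k < K; ++k) {
    const arma::cube eta1(const_cast<double*>(eta1_store.colptr(k)),
                          N1, J, T, false, true);
    const arma::vec eta2 = eta2_store.col(k);
    const arma::mat zeta2(const_cast<double*>(zeta2_store.colptr(k)),
                          N1, J, false, true);
    const double g1 = gamma1_draws[k], g2 = gamma2_draws[k], p12 = p12_draws[k];
    const arma::rowvec g3 = gamma3_draws.row(k), g4 = gamma4_draws.row(k);
    const arma::rowvec s2z1 = s2z1_draws.row(k);

    std::vector<std::vector<arma::vec>> m(J, std::vector<arma::vec>(4, m0));
    std::vector<std::vector<arma::mat>> C(J, std::vector<arma::mat>(4, C0));
    // p_prev(i, s, chain): probability of being in state s given data so far
    arma::cube p_prev(N1, 2, nch, arma::fill::zeros);
    for (int ch = 0; ch < nch; ++ch) p_prev.slice(ch).col(0).ones();

    arma::cube llik(N1, 4, J);
    arma::mat Fd(N1, 5);
    arma::vec p11(N1);

    auto fill_p11 = [&](const arma::mat& eprev) {
      for (int i = 0; i < N1; ++i) {
        double nu = g1 + g2 * eta2[i];
        for (int j = 0; j < J; ++j)
          nu += (g3[j] + g4[j] * eta2[i]) * eprev(i, j);
        p11[i] = 1.0 / (1.0 + std::exp(-std::max(std::min(nu, 35.0), -35.0)));
      }
    };
    auto pi_str = [&](int i, int str) {
      switch (str) {
        case 0: return p11[i];
        case 1: return 1.0 - p11[i];
        case 2: return p12;
        default: return 1.0 - p12;
      }
    };

    // ---------- forward filtering over the observed window ----------------
    for (int t = 1; t < T; ++t) {
      arma::mat eprev(N1, J);
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < N1; ++i) eprev(i, j) = eta1(i, j, t - 1);
      fill_p11(eprev);
      for (int j = 0; j < J; ++j) {
        for (int i = 0; i < N1; ++i) {
          Fd(i, 0) = 1.0; Fd(i, 1) = eprev(i, j); Fd(i, 2) = eta2[i];
          Fd(i, 3) = eprev(i, j) * eta2[i]; Fd(i, 4) = zeta2(i, j);
        }
        arma::vec y(N1);
        for (int i = 0; i < N1; ++i) y[i] = eta1(i, j, t);
        for (int str = 0; str < 4; ++str) {
          const arma::vec a = m[j][str];
          const arma::mat R = C[j][str];
          const arma::vec f = Fd * a;
          const arma::mat RF = R * Fd.t();
          for (int i = 0; i < N1; ++i) {
            const double qd = arma::dot(Fd.row(i), RF.col(i)) + s2z1[j];
            const double e = y[i] - f[i];
            llik(i, str, j) = -0.5 * std::log(qd) - 0.5 * e * e / qd;
          }
          // information-form update of (m, C), equivalent to the gain form
          const arma::mat Rinv = arma::inv_sympd(R + I5r);
          const arma::mat Cn = arma::inv_sympd(Rinv + (Fd.t() * Fd) / s2z1[j] + I5r);
          const arma::vec mn = Cn * (Rinv * a + (Fd.t() * y) / s2z1[j]);
          m[j][str] = mn;
          C[j][str] = 0.5 * (Cn + Cn.t());
        }
      }
      // joint stratum probabilities, collapsed over the previous state
      for (int i = 0; i < N1; ++i) {
        double p2acc = 0.0;
        for (int ch = 0; ch < nch; ++ch) {
          double lw[4], mx = -1e300;
          for (int str = 0; str < 4; ++str) {
            const int sp = str / 2;
            const double pp = p_prev(i, sp, ch);
            const double pi_ = pi_str(i, str);
            double lv = (pp > 0 && pi_ > 0) ? std::log(pi_) + std::log(pp)
                                            : -1e300;
            if (aggregate_factors) {
              for (int j = 0; j < J; ++j) lv += llik(i, str, j);
            } else {
              lv += llik(i, str, ch);
            }
            lw[str] = lv;
            if (lv > mx) mx = lv;
          }
          double tot = 0.0, w[4];
          for (int str = 0; str < 4; ++str) {
            w[str] = std::exp(lw[str] - mx); tot += w[str];
          }
          if (tot <= 0.0) { for (int str = 0; str < 4; ++str) w[str] = 0.25; tot = 1.0; }
          const double p1 = (w[0] + w[2]) / tot;
          p_prev(i, 0, ch) = p1; p_prev(i, 1, ch) = 1.0 - p1;
          p2acc += 1.0 - p1;
        }
        sum_p2_obs(i, t) += p2acc / nch;
      }
    }

    // ---------- H-steps-ahead forecast ------------------------------------
    arma::mat eprev(N1, J);
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < N1; ++i) eprev(i, j) = eta1(i, j, T - 1);
    arma::ivec s_prev(N1);
    for (int i = 0; i < N1; ++i) s_prev[i] = S_store(i + N1 * (T - 1), k);
    arma::cube fstr(N1, J, 4), qstr(N1, J, 4);
    for (int h = 0; h < H; ++h) {
      fill_p11(eprev);
      for (int j = 0; j < J; ++j) {
        for (int i = 0; i < N1; ++i) {
          Fd(i, 0) = 1.0; Fd(i, 1) = eprev(i, j); Fd(i, 2) = eta2[i];
          Fd(i, 3) = eprev(i, j) * eta2[i]; Fd(i, 4) = zeta2(i, j);
        }
        for (int str = 0; str < 4; ++str) {
          const arma::vec f = Fd * m[j][str];
          const arma::mat RF = C[j][str] * Fd.t();
          for (int i = 0; i < N1; ++i) {
            fstr(i, j, str) = f[i];
            qstr(i, j, str) = arma::dot(Fd.row(i), RF.col(i)) + s2z1[j];
          }
        }
      }
      for (int i = 0; i < N1; ++i) {
        double p2acc = 0.0;
        for (int ch = 0; ch < nch; ++ch) {
          double w[4], tot = 0.0;
          for (int str = 0; str < 4; ++str) {
            w[str] = pi_str(i, str) * p_prev(i, str / 2, ch);
            tot += w[str];
          }
          for (int str = 0; str < 4; ++str) w[str] /= tot;
          // mixture moments: in per-factor mode chain ch weights factor ch
          if (aggregate_factors) {
            for (int j = 0; j < J; ++j) {
              double mu = 0.0, m2 = 0.0;
              for (int str = 0; str < 4; ++str) {
                mu += w[str] * fstr(i, j, str);
                m2 += w[str] * (qstr(i, j, str) + fstr(i, j, str) * fstr(i, j, str));
              }
              sum_mu(i, j, h) += mu;
              sum_mu2(i, j, h) += mu * mu;
              sum_var(i, j, h) += m2 - mu * mu;
            }
          } else {
            const int j = ch;
            double mu = 0.0, m2 = 0.0;
            for (int str = 0; str < 4; ++str) {
              mu += w[str] * fstr(i, j, str);
              m2 += w[str] * (qstr(i, j, str) + fstr(i, j, str) * fstr(i, j, str));
            }
            sum_mu(i, j, h) += mu;
            sum_mu2(i, j, h) += mu * mu;
            sum_var(i, j, h) += m2 - mu * mu;
          }
          const double p2n = w[1] + w[3];
          p_prev(i, 0, ch) = 1.0 - p2n; p_prev(i, 1, ch) = p2n;
          p2acc += p2n;
        }
        sum_p2_fore(i, h) += p2acc / nch;
        // sample the trajectory used to build F at the next horizon
        const double pstay1 = (s_prev[i] == 1) ? p11[i] : p12;
        const int s_new = (unif_rand() < pstay1) ? 1 : 2;
        const int str_i = (s_new - 1) + 2 * (s_prev[i] - 1);
        for (int j = 0; j < J; ++j)
          eprev(i, j) = fstr(i, j, str_i) +
            std::sqrt(qstr(i, j, str_i)) * norm_rand();
        s_prev[i] = s_new;
      }
    }
  }

  return List::create(
    _["sum_mu"] = sum_mu, _["sum_mu2"] = sum_mu2, _["sum_var"] = sum_var,
    _["sum_p2_fore"] = sum_p2_fore, _["sum_p2_obs"] = sum_p2_obs,
    _["K"] = K);
}
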