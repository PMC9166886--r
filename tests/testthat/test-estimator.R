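test_that("posterior draws respect supports and observed dropout constraints", {
  fx <- small_fit_fixture()
  fit <- fx$fit
  # support constraints hold in every kept draw
  expect_true(all(fit$draws[, grep("^delta_alpha21", colnames(fit$draws))] >= 0))
  expect_true(all(fit$draws[, "p12"] >= 0 & fit$draws[, "p12"] <= 0.1))
  expect_true(all(fit$draws[, grep("^sigma2", colnames(fit$draws))] > 0))
  free <- setdiff(grep("^lambda1", colnames(fit$draws)),
                  grep("^lambda1", colnames(fit$draws))[fx$dims$scaling_items])
  expect_true(all(fit$draws[, free] > 0))
  # stored state paths honor the dropout tail and the first occasion
  S <- fit$latent$S
  d <- fx$dims
  for (k in seq_len(ncol(S))) {
    Sm <- matrix(S[, k], d$N1, d$Nt)
    expect_true(all(Sm[, 1] == 1L))
    for (r in seq_len(nrow(fx$sim$dropout))) {
      i <- fx$sim$dropout$person[r]
      t0 <- fx$sim$dropout$dropout_occasion[r]
      if (t0 <= d$Nt) expect_true(all(Sm[i, t0:d$Nt] == 2L))
    }
  }
  # posterior state probabilities are probabilities
  expect_true(all(fit$pstate2 >= 0 & fit$pstate2 <= 1))
  expect_true(all(fit$pstate2[, 1] == 0))
})

test_that("the fit is deterministic given the seed and rejects bad inputs", {
  fx <- small_fit_fixture()
  d <- fx$dims
  cfg <- mcmc_config(n_chains = 2, n_iter = 120, n_burnin = 60, seed = 77)
  f1 <- rsdfm_fit(fx$sim$panel, fx$sim$between, d, config = cfg)
  f2 <- rsdfm_fit(fx$sim$panel, fx$sim$between, d, config = cfg)
  expect_identical(f1$draws, f2$draws)
  bad <- fx$sim$panel
  bad$item[3] <- 99
  expect_error(rsdfm_fit(bad, fx$sim$between, d, config = cfg),
               "malformed panel row")
  expect_error(rsdfm_fit(fx$sim$panel, fx$sim$between[-1, ], d, config = cfg),
               "incomplete")
  expect_error(rsdfm_fit(fx$sim$panel, fx$sim$between, d, config = cfg,
                         dropout = tibble::tibble(person = 1L,
                                                  dropout_occasion = 1L)),
               ">= 2")
})

test_that("the joint model log density is finite at stored draws", {
  fx <- small_fit_fixture()
  fit <- fx$fit
  d <- fx$dims
  idx <- fit$latent$kept_idx +
    (fit$latent$chain - 1L) * (nrow(fit$draws) / fit$config$n_chains)
  for (k in sample(seq_len(ncol(fit$latent$eta2)), 3)) {
    row <- fit$draws[idx[k], ]
    g <- function(nm, n) unname(row[paste0(nm, "[", seq_len(n), "]")])
    gs <- function(nm, n) unname(row[paste0(nm, "[1,", seq_len(n), "]")])
    p <- rsdfm_params(
      d, lambda1 = g("lambda1", d$p), sigma2_eps1 = g("sigma2_eps1", d$p),
      lambda2 = g("lambda2", d$q), sigma2_eps2 = g("sigma2_eps2", d$q),
      sigma2_eta2 = unname(row["sigma2_eta2"]),
      alpha21 = gs("alpha21", d$J), delta_alpha21 = g("delta_alpha21", d$J),
      beta2 = gs("beta2", d$J), delta_beta2 = g("delta_beta2", d$J),
      b1 = gs("b1", d$J), delta_b1 = g("delta_b1", d$J),
      omega2 = gs("omega2", d$J), delta_omega2 = g("delta_omega2", d$J),
      sigma2_zeta1 = g("sigma2_zeta1", d$J), sigma2_zeta2 = g("sigma2_zeta2", d$J),
      gamma1 = unname(row["gamma1"]), gamma2 = unname(row["gamma2"]),
      gamma3 = g("gamma3", d$J), gamma4 = g("gamma4", d$J),
      gamma4_mask = fit$gamma4_mask, p12 = unname(row["p12"]))
    lp <- log_prior_density(p)
    expect_true(is.finite(lp))
    # structural density of the stored trajectories is finite too
    eta1 <- array(fit$latent$eta1[, k], c(d$N1, d$J, d$Nt))
    eta2 <- fit$latent$eta2[, k]
    zeta2 <- matrix(fit$latent$zeta2[, k], d$N1, d$J)
    S <- matrix(fit$latent$S[, k], d$N1, d$Nt)
    ll <- 0
    for (i in 1:2) {
      for (t in 2:d$Nt) {
        mu <- structural_step(p, eta1[i, , t - 1], eta2[i], zeta2[i, ], S[i, t])
        ll <- ll + sum(dnorm(eta1[i, , t], mu, sqrt(p$sigma2_zeta1), log = TRUE))
      }
    }
    expect_true(is.finite(ll))
  }
})

test_that("conditional state draws match brute-force path enumeration", {
  d <- rsdfm_dims(N1 = 4, Nt = 4, H = 0, J = 2, q = 2,
                  item_map = c(1L, 1L, 2L, 2L))
  p <- draw_replication_params(d, seed = 55)
  p$gamma1 <- 0; p$gamma3 <- rep(0, 2); p$gamma4 <- rep(0, 2)  # flat chain prior
  set.seed(56)
  eta1 <- matrix(rnorm(2 * 4), 2, 4)
  e2 <- 0.3; z2 <- c(0.1, -0.2)
  # place occasions 3 and 4 exactly at their state-2 structural means
  eta1[, 3] <- structural_step(p, eta1[, 2], e2, z2, 2)
  eta1[, 4] <- structural_step(p, eta1[, 3], e2, z2, 2)
  truth_p2 <- enumerate_state_posterior(p, eta1, e2, z2)
  set.seed(57)
  draws <- replicate(4000, conditional_state_draw(p, eta1, e2, z2))
  mc_p2 <- rowMeans(draws == 2L)
  expect_lt(max(abs(mc_p2 - truth_p2)), 0.04)
  expect_gt(truth_p2[3], 0.5)  # elevated scores pull toward state 2
  # masked occasions are returned as the observed state
  S_obs <- c(0L, 0L, 2L, 2L)
  draws2 <- replicate(200, conditional_state_draw(p, eta1, e2, z2, S_obs))
  expect_true(all(draws2[3:4, ] == 2L))
  expect_true(all(draws2[1, ] == 1L))
  # flat likelihood: the conditional reduces to the prior Markov chain
  p_flat <- p
  p_flat$delta_alpha21 <- rep(0, 2); p_flat$delta_beta2 <- rep(0, 2)
  p_flat$delta_b1 <- rep(0, 2); p_flat$delta_omega2 <- rep(0, 2)
  truth_flat <- enumerate_state_posterior(p_flat, eta1, e2, z2)
  # under identical structural densities the posterior equals the chain prior
  p11 <- transition_stay_prob(p_flat, t(eta1), rep(e2, 4))
  prior_p2 <- numeric(4)
  pr <- c(1, 0)
  for (t in 2:4) {
    trans <- rbind(c(p11[t - 1], 1 - p11[t - 1]), c(p_flat$p12, 1 - p_flat$p12))
    pr <- drop(pr %*% trans)
    prior_p2[t] <- pr[2]
  }
  expect_equal(truth_flat, prior_p2, tolerance = 1e-10)
})

test_that("split Rhat flags separated chains and passes identical ones", {
  set.seed(60)
  x <- matrix(rnorm(2000), ncol = 1)
  colnames(x) <- "theta"
  chain <- rep(1:2, each = 1000)
  r_same <- rsdfm_rhat(x, chain = chain)
  expect_lt(abs(r_same$rhat - 1), 0.02)
  x2 <- x; x2[chain == 2, 1] <- x2[chain == 2, 1] + 5
  r_diff <- rsdfm_rhat(x2, chain = chain)
  expect_gt(r_diff$rhat, 1.5)
  expect_true(r_diff$flagged)
  # agreement with an independent implementation
  if (requireNamespace("coda", quietly = TRUE)) {
    half <- function(v) list(coda::mcmc(v[1:500]), coda::mcmc(v[501:1000]))
    ml <- coda::mcmc.list(c(half(x2[chain == 1, 1]), half(x2[chain == 2, 1])))
    ref <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1]
    expect_gt(ref, 1.5)  # the independent implementation flags it too
    expect_lt(abs(r_diff$rhat - ref) / ref, 0.4)  # same order (df corrections differ)
  }
  # constant parameter yields NA, single chain errors
  xc <- cbind(x, const = 1)
  expect_true(is.na(rsdfm_rhat(xc, chain = chain)$rhat[2]))
  expect_error(rsdfm_rhat(x, chain = rep(1, 2000)), "2 chains")
})

test_that("tidy and glance summarise the posterior", {
  fx <- small_fit_fixture()
  td <- tidy(fx$fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high",
                    "rhat") %in% names(td)))
  expect_equal(nrow(td), ncol(fx$fit$draws))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fx$fit)
  expect_equal(gl$n_kept, nrow(fx$fit$draws))
  expect_identical(gl$converged, gl$n_flagged == 0L)
})
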