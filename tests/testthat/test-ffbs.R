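test_that("filter initialization replicates the prior across the four strata", {
  f <- ffbs_init_filter()
  expect_length(f$strata, 4)
  for (s in names(f$strata)) {
    expect_equal(f$strata[[s]]$m, rep(0, 5))
    expect_equal(f$strata[[s]]$C, diag(5))
  }
  C_bad <- diag(5); C_bad[1, 1] <- -1
  expect_error(ffbs_init_filter(C0 = C_bad), "positive semidefinite")
  expect_error(ffbs_init_filter(C0 = matrix(rnorm(25), 5)), "symmetric")
})

test_that("the gain-form update matches an information-form oracle", {
  set.seed(31)
  N <- 3
  Fl <- replicate(4, cbind(1, rnorm(N), rnorm(N), rnorm(N), rnorm(N)),
                  simplify = FALSE)
  yl <- replicate(4, rnorm(N, 0, 1.5), simplify = FALSE)
  sigma2 <- 0.7
  f <- ffbs_init_filter()
  oracle <- dlm_oracle(rep(0, 5), diag(5), Fl, yl, sigma2)
  for (t in 1:4) {
    f <- ffbs_update_step(f, yl[[t]], Fl[[t]], sigma2)
    for (s in names(f$strata)) {
      expect_equal(f$strata[[s]]$m, oracle[[t]]$m, tolerance = 1e-10)
      expect_equal(f$strata[[s]]$C, oracle[[t]]$C, tolerance = 1e-10)
      expect_equal(f$strata[[s]]$f, oracle[[t]]$f, tolerance = 1e-10)
      expect_equal(f$strata[[s]]$Q, oracle[[t]]$Q, tolerance = 1e-10)
    }
  }
})

test_that("huge observation variance yields a zero-gain update", {
  set.seed(32)
  F <- cbind(1, rnorm(3), rnorm(3), rnorm(3), rnorm(3))
  f <- ffbs_init_filter(m0 = rnorm(5), C0 = diag(5))
  f2 <- ffbs_update_step(f, rnorm(3, 0, 10), F, V = 1e12)
  for (s in names(f$strata)) {
    expect_equal(f2$strata[[s]]$m, f$strata[[s]]$m, tolerance = 1e-6)
    expect_equal(f2$strata[[s]]$C, f$strata[[s]]$C, tolerance = 1e-6)
  }
})

test_that("scalar recursions equal the hand-computed Kalman filter", {
  # N = 1, scalar theta: F = 1, G = 1, W = 0 reduces to the textbook
  # scalar filter m <- m + C/(C + v) * (y - m), C <- C v / (C + v)
  ys <- c(0.8, -0.4, 1.1)
  v <- 0.5
  m_or <- 0; C_or <- 1
  f <- ffbs_init_filter(m0 = c(0, rep(0, 4)),
                        C0 = diag(c(1, rep(1e-12, 4))))
  for (t in 1:3) {
    Q_or <- C_or + v
    m_or <- m_or + C_or / Q_or * (ys[t] - m_or)
    C_or <- C_or * v / Q_or
    f <- ffbs_update_step(f, ys[t], matrix(c(1, 0, 0, 0, 0), 1), v)
    expect_equal(f$strata[["(1,1)"]]$m[1], m_or, tolerance = 1e-9)
    expect_equal(f$strata[["(1,1)"]]$C[1, 1], C_or, tolerance = 1e-9)
  }
})

test_that("posterior covariance stays symmetric PSD along random updates", {
  set.seed(33)
  f <- ffbs_init_filter()
  for (k in 1:50) {
    F <- cbind(1, rnorm(4), rnorm(4), rnorm(4), rnorm(4))
    f <- ffbs_update_step(f, rnorm(4), F, runif(1, 0.2, 2))
  }
  for (s in names(f$strata)) {
    C <- f$strata[[s]]$C
    expect_lt(max(abs(C - t(C))), 1e-10)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("H-step forecasts keep the system prior fixed under identity dynamics", {
  set.seed(34)
  F <- cbind(1, rnorm(3), rnorm(3), rnorm(3), rnorm(3))
  f <- ffbs_init_filter()
  f <- ffbs_update_step(f, rnorm(3), F, 0.5)
  fc <- ffbs_h_step_forecast(f, F, 0.5, H = 4)
  expect_error(ffbs_h_step_forecast(f, F, 0.5, H = 0), ">= 1")
  one <- fc[fc$stratum == "(1,1)", ]
  # constant mean and variance across horizons when F is reused
  for (i in 1:3) {
    sub <- one[one$person == i, ]
    expect_equal(diff(range(sub$mean)), 0)
    expect_equal(diff(range(sub$variance)), 0)
  }
  # one-step mean equals F m
  expect_equal(one$mean[one$horizon == 1],
               drop(F %*% f$strata[["(1,1)"]]$m))
})

test_that("joint stratum probabilities normalize and degenerate cases collapse", {
  # equal likelihood terms: posterior proportional to pi * p_prev
  pi_m <- matrix(c(0.7, 0.05, 0.3, 0.95), 2, 2)  # pi[s, s']
  pp <- c(0.6, 0.4)
  out <- ffbs_joint_probs(pi_m, pp, e = rep(1, 4), q_diag = rep(2, 4))
  w_expect <- c(pi_m[1, 1] * pp[1], pi_m[2, 1] * pp[1],
                pi_m[1, 2] * pp[2], pi_m[2, 2] * pp[2])
  expect_equal(drop(out$p_joint), w_expect / sum(w_expect),
               ignore_attr = TRUE)
  # identity transition with all prior mass on state 1
  out2 <- ffbs_joint_probs(diag(2), c(1, 0), e = rep(0, 4), q_diag = rep(1, 4))
  expect_equal(drop(out2$p_joint), c(1, 0, 0, 0), ignore_attr = TRUE)
  # direct normalization of four arbitrary positive weights
  pi_u <- matrix(1, 1, 4); pp_u <- c(1, 1)
  qd <- rep(1, 4)
  e <- sqrt(-2 * log(c(0.2, 0.1, 0.4, 0.3)))  # weights 0.2/0.1/0.4/0.3 sum to 1
  out3 <- ffbs_joint_probs(pi_u, pp_u, e = e, q_diag = qd)
  expect_equal(drop(out3$p_joint), c(0.2, 0.1, 0.4, 0.3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(out3$p_joint), 1, tolerance = 1e-12)
})

test_that("stratum probability objects stay normalized on random inputs", {
  set.seed(35)
  for (k in 1:200) {
    pi_m <- matrix(runif(4), 2)
    pi_m <- pi_m / rep(colSums(pi_m), each = 2)  # columns sum to 1 over s
    pp <- runif(2); pp <- pp / sum(pp)
    out <- ffbs_joint_probs(pi_m, pp, e = rnorm(4, 0, 2), q_diag = runif(4, 0.1, 3))
    expect_equal(sum(out$p_joint), 1, tolerance = 1e-8)
    expect_equal(drop(out$p_state[, 1] + out$p_state[, 2]), 1, tolerance = 1e-8)
    expect_equal(out$p_joint[1] + out$p_joint[3], drop(out$p_state[, 1]),
                 tolerance = 1e-12)
  }
})

test_that("the marginal predictive mixture has closed-form moments and quantiles", {
  # identical components reduce to the component
  out <- ffbs_marginal_predictive(rep(1.5, 4), rep(0.8, 4), rep(0.25, 4))
  expect_equal(out$mean, 1.5)
  expect_equal(out$variance, 0.8)
  expect_equal(out$lower, 1.5 - qnorm(0.975) * sqrt(0.8), tolerance = 1e-6)
  # two-component closed form: means 0 and 2, unit variances, equal weight
  out2 <- ffbs_marginal_predictive(c(0, 2, 0, 0), c(1, 1, 1, 1),
                                   c(0.5, 0.5, 0, 0))
  expect_equal(out2$mean, 1)
  expect_equal(out2$variance, 2)
  # the CDF at the median is one half
  med <- out2$quantile(0.5)
  expect_equal(out2$cdf(med), 0.5, tolerance = 1e-6)
  expect_error(ffbs_marginal_predictive(1:4, rep(1, 4), c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("collapsing onto the current state moment-matches the stratum mixture", {
  m <- c(0.4, -1, 2, 0.3)
  ml <- lapply(m, function(x) rep(x, 2))
  Cl <- replicate(4, diag(2) * 0.5, simplify = FALSE)
  # all mass on one stratum returns that stratum's moments
  out <- ffbs_collapse(c(1, 0, 0, 0), ml, Cl)
  expect_equal(out$p_state, c(`1` = 1, `2` = 0))
  expect_equal(out$m[["1"]], ml[[1]])
  expect_equal(out$C[["1"]], Cl[[1]])
  expect_null(out$m[["2"]])
  # two equal-weight strata at +/- m: mean 0, covariance C + m m'
  mv <- c(1, -2)
  out2 <- ffbs_collapse(c(0.3, 0.2, 0.3, 0.2),
                        list(mv, rep(9, 2), -mv, rep(9, 2)),
                        list(diag(2), diag(2), diag(2), diag(2)))
  expect_equal(out2$m[["1"]], c(0, 0))
  expect_equal(out2$C[["1"]], diag(2) + outer(mv, mv))
  expect_equal(sum(out2$p_state), 1)
})

test_that("state classification uses a strict threshold and is monotone", {
  expect_identical(classify_states(c(1, 0.5, 0.500001, 0.2)), c(2L, 1L, 2L, 1L))
  expect_error(classify_states(0.5, threshold = 1), "inside")
  set.seed(36)
  p <- runif(50)
  n2 <- vapply(c(0.2, 0.4, 0.6, 0.8),
               function(th) sum(classify_states(p, th) == 2L), 0L)
  expect_true(all(diff(n2) <= 0))
})

test_that("the integrated forecaster agrees with the exposed recursions", {
  # one retained draw, transition model pinned to the (1,1) stratum:
  # the integrated filter must match the plain DLM recursion, and the
  # filtered state probabilities must stay at state 1
  set.seed(37)
  N1 <- 3; J <- 1; T <- 5; H <- 2
  eta1 <- array(rnorm(N1 * J * T), c(N1, J, T))
  eta2 <- rnorm(N1); zeta2 <- matrix(rnorm(N1), N1, J)
  s2 <- 0.6
  res <- rsdfm:::ffbs_forecast_cpp(
    matrix(as.vector(eta1), ncol = 1), matrix(eta2, ncol = 1),
    matrix(as.vector(zeta2), ncol = 1),
    matrix(1L, N1 * T, 1),
    matrix(s2, 1, 1), 50, 0, matrix(0, 1, 1), matrix(0, 1, 1), 0,
    N1, J, T, H, rep(0, 5), diag(5), TRUE)
  # gamma1 = 50 saturates the stay probability; p12 = 0
  expect_equal(as.vector(res$sum_p2_obs), rep(0, N1 * T), tolerance = 1e-10)
  f <- ffbs_init_filter()
  for (t in 2:T) {
    F <- cbind(1, eta1[, 1, t - 1], eta2, eta1[, 1, t - 1] * eta2, zeta2[, 1])
    f <- ffbs_update_step(f, eta1[, 1, t], F, s2)
  }
  Fh <- cbind(1, eta1[, 1, T], eta2, eta1[, 1, T] * eta2, zeta2[, 1])
  fc <- ffbs_h_step_forecast(f, Fh, s2, H = 1)
  one <- fc[fc$stratum == "(1,1)" & fc$horizon == 1, ]
  expect_equal(res$sum_mu[, 1, 1], one$mean, tolerance = 1e-8)
  expect_equal(res$sum_var[, 1, 1], one$variance, tolerance = 1e-8)
})
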