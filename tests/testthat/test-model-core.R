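test_that("stay probability is the logistic of the transition logit", {
  d <- rsdfm_dims(N1 = 5, Nt = 5)
  p <- example_params(d)
  p$gamma1 <- 0; p$gamma2 <- 0; p$gamma3 <- rep(0, 3); p$gamma4 <- rep(0, 3)
  expect_equal(transition_stay_prob(p, rep(0, 3), 0), 0.5)
  # logit log(9) gives probability 0.9
  p$gamma1 <- 2.1972246
  expect_equal(transition_stay_prob(p, rep(0, 3), 0), 0.9, tolerance = 1e-7)
  # complement identity for arbitrary covariates
  p2 <- example_params(d)
  set.seed(1)
  for (k in 1:10) {
    eta <- rnorm(3); e2 <- rnorm(1)
    P <- transition_matrix(p2, eta, e2)
    expect_equal(P[1, 2], 1 - transition_stay_prob(p2, eta, e2))
  }
  # numerically safe in the saturated regime
  p$gamma1 <- 500
  expect_equal(transition_stay_prob(p, rep(0, 3), 0), 1)
  p$gamma1 <- -500
  expect_equal(transition_stay_prob(p, rep(0, 3), 0), 0)
  expect_error(transition_stay_prob(p, c(0, NA, 0), 0), "person 1, factor 2")
})

test_that("transition matrix is row stochastic with the constant return row", {
  d <- rsdfm_dims(N1 = 5, Nt = 5)
  p <- example_params(d)
  set.seed(2)
  for (k in 1:20) {
    P <- transition_matrix(p, rnorm(3), rnorm(1))
    expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(P[2, ]), c(p$p12, 1 - p$p12))
  }
  # absorbing second state at p12 = 0
  p$p12 <- 0
  expect_equal(unname(transition_matrix(p, rep(0, 3), 0)[2, ]), c(0, 1))
  # return probability printed for the empirical fit: row 2 = (0.097, 0.903)
  p$p12 <- 0.097
  p$gamma1 <- 0; p$gamma2 <- 0; p$gamma3 <- rep(0, 3); p$gamma4 <- rep(0, 3)
  expect_equal(unname(transition_matrix(p, rep(0, 3), 0)),
               matrix(c(0.5, 0.5, 0.097, 0.903), 2, byrow = TRUE))
})

test_that("structural step resolves person-specific intercept and AR slope", {
  d <- rsdfm_dims(N1 = 5, Nt = 5)
  p <- example_params(d)
  # with no dynamics the mean is the state intercept
  p$b1 <- rep(0, 3); p$delta_b1 <- rep(0, 3)
  p$omega2 <- rep(0, 3); p$delta_omega2 <- rep(0, 3)
  p$beta2 <- rep(0, 3); p$delta_beta2 <- rep(0, 3)
  expect_equal(structural_step(p, rnorm(3), 1.3, rep(0, 3), 1), p$alpha21)
  expect_equal(structural_step(p, rnorm(3), 1.3, rep(0, 3), 2),
               p$alpha21 + p$delta_alpha21)
  # hand-computed single-factor arithmetic
  d1 <- rsdfm_dims(N1 = 2, Nt = 5, J = 1, q = 2, item_map = c(1L, 1L))
  p1 <- rsdfm_params(d1, lambda1 = c(1, 0.9), sigma2_eps1 = c(0.3, 0.3),
                     lambda2 = c(1, 0.9), sigma2_eps2 = c(0.3, 0.3),
                     sigma2_eta2 = 1,
                     alpha21 = 0.2, delta_alpha21 = 0.5,
                     beta2 = -0.3, delta_beta2 = 0,
                     b1 = 0.5, delta_b1 = 0,
                     omega2 = 0.1, delta_omega2 = 0,
                     sigma2_zeta1 = 0.4, sigma2_zeta2 = 0.4,
                     gamma1 = 0, gamma2 = 0, gamma3 = 0, gamma4 = 0,
                     gamma4_mask = TRUE, p12 = 0.05)
  # 0.2 - 0.3 + 0.1 + (0.5 + 0.1) * 2 = 1.2
  expect_equal(structural_step(p1, eta1_prev = 2, eta2 = 1,
                               zeta2_i = 0.1, s = 1), 1.2)
  # affine in the lagged score with slope b1 + omega2 * eta2
  p <- example_params(d)
  e2 <- 0.7
  slope <- p$b1 + p$omega2 * e2
  base <- structural_step(p, rep(0, 3), e2, rep(0, 3), 1)
  eps <- 1e-6
  fd <- (structural_step(p, rep(eps, 3), e2, rep(0, 3), 1) - base) / eps
  expect_equal(fd, slope, tolerance = 1e-5)
  # centered moderator removes the interaction from the AR coefficient
  fd0 <- (structural_step(p, rep(eps, 3), 0, rep(0, 3), 1) -
            structural_step(p, rep(0, 3), 0, rep(0, 3), 1)) / eps
  expect_equal(fd0, p$b1, tolerance = 1e-5)
  expect_error(structural_step(p, rep(0, 2), 0, rep(0, 3), 1), "length J")
})

test_that("state labels are identified by the nonnegative level shift", {
  d <- rsdfm_dims(N1 = 5, Nt = 5)
  set.seed(3)
  for (k in 1:10) {
    p <- draw_replication_params(d, seed = k)
    s1 <- state_coefs(p, 1); s2 <- state_coefs(p, 2)
    expect_true(all(s2$alpha21 >= s1$alpha21))
  }
  ok <- example_params(d)
  expect_error(
    rsdfm_params(d, lambda1 = ok$lambda1, sigma2_eps1 = ok$sigma2_eps1,
                 lambda2 = ok$lambda2, sigma2_eps2 = ok$sigma2_eps2,
                 sigma2_eta2 = ok$sigma2_eta2,
                 alpha21 = ok$alpha21, delta_alpha21 = c(-0.1, 1, 1),
                 beta2 = ok$beta2, delta_beta2 = ok$delta_beta2,
                 b1 = ok$b1, delta_b1 = ok$delta_b1,
                 omega2 = ok$omega2, delta_omega2 = ok$delta_omega2,
                 sigma2_zeta1 = ok$sigma2_zeta1, sigma2_zeta2 = ok$sigma2_zeta2,
                 gamma1 = ok$gamma1, gamma2 = ok$gamma2, gamma3 = ok$gamma3,
                 gamma4 = ok$gamma4, gamma4_mask = ok$gamma4_mask,
                 p12 = ok$p12),
    "nonnegative")
})

test_that("log prior density matches a term-by-term oracle and support rules", {
  d <- rsdfm_dims(N1 = 5, Nt = 5)
  p <- example_params(d)
  pr <- rsdfm_priors()
  # independent recomputation, term by term
  tn <- function(x) dnorm(x, log = TRUE) - pnorm(0, lower.tail = FALSE, log.p = TRUE)
  free_l1 <- p$lambda1[-d$scaling_items]
  oracle <- sum(tn(free_l1)) + sum(tn(p$lambda2[-1])) + sum(tn(p$delta_alpha21)) +
    sum(dgamma(1 / c(p$sigma2_eps1, p$sigma2_eps2, p$sigma2_eta2,
                     p$sigma2_zeta1, p$sigma2_zeta2), 9, rate = 4, log = TRUE)) +
    sum(dnorm(c(p$alpha21, p$beta2, p$b1, p$omega2, p$delta_beta2,
                p$delta_b1, p$delta_omega2, p$gamma1, p$gamma2, p$gamma3,
                p$gamma4[p$gamma4_mask]), log = TRUE)) +
    log(1 / 0.1)
  expect_equal(log_prior_density(p, pr), oracle, tolerance = 1e-12)
  # uniform support on the return probability contributes log(1 / 0.1)
  p2 <- p; p2$p12 <- 0.05
  expect_equal(log_prior_density(p2, pr), oracle, tolerance = 1e-12)
  p2$p12 <- 0.11
  expect_identical(log_prior_density(p2, pr), -Inf)
  # negative level shift is outside the censored prior support
  p3 <- p; p3$delta_alpha21[1] <- -0.01
  expect_identical(log_prior_density(p3, pr), -Inf)
  # precision 2 under Gamma(9, 4): 9 log 4 - log Gamma(9) + 8 log 2 - 8
  p4 <- p; p4$sigma2_eta2 <- 0.5
  expect_equal(log_prior_density(p4, pr) - log_prior_density(p, pr),
               (9 * log(4) - lgamma(9) + 8 * log(2) - 8) -
                 dgamma(1 / p$sigma2_eta2, 9, rate = 4, log = TRUE),
               tolerance = 1e-12)
})

test_that("parameter serialization round-trips exactly", {
  d <- rsdfm_dims(N1 = 7, Nt = 9, H = 3)
  p <- draw_replication_params(d, seed = 99)
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, path)
  p2 <- params_from_json(path)
  expect_identical(params_flatten(p), params_flatten(p2))
  expect_identical(p2$dims$item_map, d$item_map)
  expect_identical(p2$gamma4_mask, p$gamma4_mask)
})
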