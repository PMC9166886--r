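# Independent oracles and shared fixtures for the test suite.

# Information-form Bayesian linear recursion: an independent route to the
# same posterior as the gain-form dynamic-linear-model update (G = I,
# W = 0). Returns filtered moments and one-step forecast quantities.
dlm_oracle <- function(m0, C0, F_list, y_list, sigma2) {
  m <- m0; C <- C0
  steps <- list()
  for (t in seq_along(F_list)) {
    F <- as.matrix(F_list[[t]]); y <- y_list[[t]]
    f <- drop(F %*% m)
    Q <- F %*% C %*% t(F) + diag(sigma2, nrow(F))
    Cn <- solve(solve(C) + t(F) %*% F / sigma2)
    mn <- drop(Cn %*% (solve(C) %*% m + t(F) %*% y / sigma2))
    m <- unname(mn); C <- unname((Cn + t(Cn)) / 2)
    steps[[t]] <- list(m = m, C = C, f = unname(f), Q = unname(Q))
  }
  steps
}

# Brute-force posterior of a single person's state path by enumeration of
# all 2^(T-1) paths (occasion 1 fixed at state 1).
enumerate_state_posterior <- function(params, eta1_i, eta2_i, zeta2_i,
                                      S_obs_i = NULL) {
  eta1_i <- as.matrix(eta1_i)
  Tt <- ncol(eta1_i)
  if (is.null(S_obs_i)) S_obs_i <- rep(0L, Tt)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tt - 1)))
  lp <- apply(paths, 1, function(tail) {
    S <- c(1L, tail)
    if (any(S_obs_i > 0 & S != S_obs_i)) return(-Inf)
    ll <- 0
    for (t in 2:Tt) {
      P <- transition_matrix(params, eta1_i[, t - 1], eta2_i)
      ll <- ll + log(P[S[t - 1], S[t]])
      mu <- structural_step(params, eta1_i[, t - 1], eta2_i, zeta2_i, S[t])
      ll <- ll + sum(dnorm(eta1_i[, t], mu, sqrt(params$sigma2_zeta1), log = TRUE))
    }
    ll
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  p2 <- c(0, vapply(seq_len(Tt - 1), function(k) sum(w[paths[, k] == 2]), 0))
  p2
}

# tiny fitted replication shared across test files (built once per run)
.fixture_env <- new.env(parent = emptyenv())

small_fit_fixture <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  dims <- rsdfm_dims(N1 = 12, Nt = 12, H = 4)
  params <- draw_replication_params(dims, seed = 11)
  sim <- simulate_panel(params, dims, missing_rate = 0.1, seed = 12)
  sim <- inject_dropout(sim, fraction = 1, seed = 13)
  fit <- rsdfm_fit(sim$panel, sim$between, dims, dropout = sim$dropout,
                   config = mcmc_config(n_chains = 2, n_iter = 400,
                                        n_burnin = 200, seed = 14))
  fc <- rsdfm_forecast(fit, seed = 15)
  .fixture_env$small <- list(dims = dims, params = params, sim = sim,
                             fit = fit, forecast = fc)
  .fixture_env$small
}
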