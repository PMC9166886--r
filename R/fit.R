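#' MCMC configuration
#'
#' Defaults match the package's simulation-study configuration: 2 chains of
#' 10,000 iterations with 5,000 burn-in. For full empirical analyses a
#' heavier setting such as 4 chains of 30,000 iterations with 25,000
#' burn-in is recommended. Convergence is flagged with the split potential
#' scale reduction factor against `rhat_threshold` (default 1.12).
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param thin Thinning interval for stored parameter draws.
#' @param seed Integer seed; chain `c` uses `seed + 1000 * c`.
#' @param rhat_threshold Convergence flag threshold.
#' @param store_latent Maximum number of retained latent-variable draws per
#'   chain kept for the forecaster (subsampled evenly from the kept draws).
#' @param init_jitter Standard deviation of the jitter added to the
#'   prior-median starting values (chains differ by seed).
#' @param eta0_var Variance of the diffuse normal prior on the initial
#'   factor scores.
#' @return An object of class `rsdfm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 10000L, n_burnin = 5000L,
                        thin = 1L, seed = 1L, rhat_threshold = 1.12,
                        store_latent = 250L, init_jitter = 0.2,
                        eta0_var = 4) {
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= 0, thin >= 1,
            rhat_threshold > 1, store_latent >= 1, eta0_var > 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold,
                 store_latent = as.integer(store_latent),
                 init_jitter = init_jitter, eta0_var = eta0_var),
            class = "rsdfm_mcmc_config")
}

par_names <- function(dims) {
  J <- dims$J
  idx <- function(nm, n) paste0(nm, "[", seq_len(n), "]")
  jdx <- function(nm, s) paste0(nm, "[", s, ",", seq_len(J), "]")
  c(idx("lambda1", dims$p), idx("sigma2_eps1", dims$p),
    idx("lambda2", dims$q), idx("sigma2_eps2", dims$q),
    "sigma2_eta2",
    jdx("alpha21", 1), idx("delta_alpha21", J),
    jdx("beta2", 1), idx("delta_beta2", J),
    jdx("b1", 1), idx("delta_b1", J),
    jdx("omega2", 1), idx("delta_omega2", J),
    idx("sigma2_zeta1", J), idx("sigma2_zeta2", J),
    "gamma1", "gamma2", idx("gamma3", J), idx("gamma4", J), "p12")
}

# long panel -> N1 x p x T array over the observation window
panel_to_array <- function(panel, dims) {
  req <- c("person", "occasion", "item", "value")
  if (!all(req %in% names(panel))) {
    stop("panel must have columns person, occasion, item, value", call. = FALSE)
  }
  bad <- which(!is.finite(panel$value) | panel$person < 1 | panel$person > dims$N1 |
                 panel$item < 1 | panel$item > dims$p | panel$occasion < 1)
  if (length(bad)) {
    stop(sprintf("malformed panel row %d (person=%s, occasion=%s, item=%s)",
                 bad[1], panel$person[bad[1]], panel$occasion[bad[1]],
                 panel$item[bad[1]]), call. = FALSE)
  }
  Y1 <- array(NA_real_, c(dims$N1, dims$p, dims$Nt))
  keep <- panel$occasion <= dims$Nt
  Y1[cbind(panel$person[keep], panel$item[keep], panel$occasion[keep])] <-
    panel$value[keep]
  Y1
}

between_to_matrix <- function(between, dims) {
  req <- c("person", "item", "value")
  if (!all(req %in% names(between))) {
    stop("between table must have columns person, item, value", call. = FALSE)
  }
  Y2 <- matrix(NA_real_, dims$N1, dims$q)
  Y2[cbind(between$person, between$item)] <- between$value
  if (anyNA(Y2)) stop("between-level table is incomplete", call. = FALSE)
  Y2
}

#' Fit the regime-switching dynamic factor model
#'
#' Runs the Gibbs sampler over the observation window (occasions
#' `1..dims$Nt`): within- and between-level factor scores, person random
#' intercepts, the partly observed discrete state paths, and all
#' measurement, structural and switching parameters are drawn from their
#' full conditionals under the priors of [rsdfm_priors()]. Missing within
#' responses are imputed each sweep. Persons with a recorded dropout have
#' their state fixed to 2 from the dropout occasion onward; every person
#' starts in state 1 at the first occasion.
#'
#' @param panel Long within-level panel: columns `person`, `occasion`,
#'   `item`, `value` (missing responses are absent rows).
#' @param between Between-level table: columns `person`, `item`, `value`.
#' @param dims An [rsdfm_dims()] object.
#' @param dropout Optional tibble of observed dropouts (`person`,
#'   `dropout_occasion` with occasions >= 2); states from that occasion on
#'   are treated as observed state-2 entries.
#' @param priors An [rsdfm_priors()] object.
#' @param config An [mcmc_config()] object.
#' @param gamma4_mask Logical length-`J` mask of factors whose interaction
#'   with the between factor enters the transition model; default marks the
#'   last factor.
#' @param verbose Print per-chain progress.
#' @return An object of class `rsdfm_fit`. Key components: `draws` (kept
#'   parameter draws, one column per scalar parameter), `chain`/`iteration`
#'   labels, `pstate2` (posterior probability of state 2 per person and
#'   occasion), `latent` (subsampled latent-variable draws used by
#'   [rsdfm_forecast()]), and `rhat` (split potential-scale-reduction
#'   table). Use [generics::tidy()] / [generics::glance()] for summaries.
#' @export
rsdfm_fit <- function(panel, between, dims, dropout = NULL,
                      priors = rsdfm_priors(), config = mcmc_config(),
                      gamma4_mask = c(rep(FALSE, dims$J - 1), TRUE),
                      verbose = FALSE) {
  stopifnot(inherits(dims, "rsdfm_dims"), inherits(priors, "rsdfm_priors"),
            inherits(config, "rsdfm_mcmc_config"))
  if (length(gamma4_mask) != dims$J) {
    stop("`gamma4_mask` must have length J", call. = FALSE)
  }
  # identification: every factor needs its scaling item
  if (anyNA(dims$scaling_items)) {
    stop("non-identified configuration: a factor has no scaling item", call. = FALSE)
  }
  Y1 <- panel_to_array(panel, dims)
  Y2 <- between_to_matrix(between, dims)
  S_obs <- matrix(0L, dims$N1, dims$Nt)
  S_obs[, 1] <- 1L
  if (!is.null(dropout) && nrow(dropout) > 0) {
    stopifnot(all(c("person", "dropout_occasion") %in% names(dropout)))
    if (any(dropout$dropout_occasion < 2)) {
      stop("dropout occasions must be >= 2 (everyone starts in state 1)",
           call. = FALSE)
    }
    for (r in seq_len(nrow(dropout))) {
      d <- dropout$dropout_occasion[r]
      if (d <= dims$Nt) S_obs[dropout$person[r], d:dims$Nt] <- 2L
    }
  }
  n_kept <- (config$n_iter - config$n_burnin) %/% config$thin +
    as.integer((config$n_iter - config$n_burnin) %% config$thin > 0)
  latent_stride <- max(1L, ceiling(n_kept / config$store_latent))

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    if (verbose) message(sprintf("chain %d/%d ...", ch, config$n_chains))
    set.seed(config$seed + 1000L * ch)
    chains[[ch]] <- gibbs_chain_cpp(
      Y1, Y2, dims$item_map, dims$scaling_items, S_obs, gamma4_mask,
      unclass(priors), config$n_iter, config$n_burnin, config$thin,
      latent_stride, config$init_jitter, config$eta0_var)
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "par_draws"))
  colnames(draws) <- par_names(dims)
  n_per <- nrow(chains[[1]]$par_draws)
  chain_id <- rep(seq_len(config$n_chains), each = n_per)
  iteration <- rep(seq_len(n_per), times = config$n_chains)
  pstate2 <- Reduce(`+`, lapply(chains, `[[`, "pstate2")) / config$n_chains
  latent <- list(
    eta1 = do.call(cbind, lapply(chains, `[[`, "eta1_store")),
    eta2 = do.call(cbind, lapply(chains, `[[`, "eta2_store")),
    zeta2 = do.call(cbind, lapply(chains, `[[`, "zeta2_store")),
    S = do.call(cbind, lapply(chains, `[[`, "S_store")),
    chain = rep(seq_len(config$n_chains),
                times = vapply(chains, function(x) ncol(x$eta1_store), 1L)),
    kept_idx = unlist(lapply(chains, `[[`, "store_kept_idx")))

  fit <- structure(
    list(draws = draws, chain = chain_id, iteration = iteration,
         pstate2 = pstate2, latent = latent,
         dims = dims, priors = priors, config = config,
         gamma4_mask = gamma4_mask,
         data = list(Y1 = Y1, Y2 = Y2, S_obs = S_obs, dropout = dropout)),
    class = "rsdfm_fit")
  fit$rhat <- rsdfm_rhat(fit, threshold = config$rhat_threshold)
  fit
}

#' Split potential scale reduction factor
#'
#' Computes the split-chain PSRF per scalar parameter (each chain is split
#' in half, then the classical between/within variance ratio is formed)
#' and flags parameters at or above the threshold. Parameters that are
#' constant across all draws yield `NA`.
#'
#' @param fit An [rsdfm_fit()] object (or a numeric draws matrix with a
#'   `chain` attribute-style vector passed via `chain`).
#' @param threshold Flagging threshold (default 1.12).
#' @param chain Optional chain labels when `fit` is a plain matrix.
#' @return A tibble with columns `parameter`, `rhat`, `flagged`.
#' @export
rsdfm_rhat <- function(fit, threshold = 1.12, chain = NULL) {
  if (inherits(fit, "rsdfm_fit")) {
    draws <- fit$draws; chain <- fit$chain
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain)) stop("supply `chain` labels with a draws matrix", call. = FALSE)
  }
  if (length(unique(chain)) < 2) {
    stop("at least 2 chains are required for the PSRF", call. = FALSE)
  }
  split_ids <- integer(length(chain))
  k <- 0L
  for (ch in unique(chain)) {
    rows <- which(chain == ch)
    half <- length(rows) %/% 2
    split_ids[rows[seq_len(half)]] <- k + 1L
    split_ids[rows[(half + 1):length(rows)]] <- k + 2L
    k <- k + 2L
  }
  rhat_one <- function(x) {
    means <- tapply(x, split_ids, mean)
    vars <- tapply(x, split_ids, stats::var)
    n <- min(tapply(x, split_ids, length))
    W <- mean(vars)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    B_over_n <- stats::var(means)
    sqrt((n - 1) / n + B_over_n / W)
  }
  rh <- apply(draws, 2, rhat_one)
  tibble::tibble(parameter = colnames(draws), rhat = unname(rh),
                 flagged = !is.na(rh) & rh >= threshold)
}

#' @export
print.rsdfm_fit <- function(x, ...) {
  d <- x$dims
  cat("<rsdfm_fit>", d$N1, "persons x", d$Nt, "occasions |", d$J, "factors\n")
  cat("  chains:", x$config$n_chains, "| kept draws:", nrow(x$draws), "\n")
  mr <- suppressWarnings(max(x$rhat$rhat, na.rm = TRUE))
  cat("  max Rhat:", round(mr, 3), "|", sum(x$rhat$flagged), "flagged (threshold",
      x$config$rhat_threshold, ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries
#'
#' @param x An `rsdfm_fit` object.
#' @param conf.level Credible-interval level (central quantiles).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior mean),
#'   `std.error` (posterior SD), `conf.low`, `conf.high`, `rhat`.
#' @method tidy rsdfm_fit
#' @export
tidy.rsdfm_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  qs <- apply(x$draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  tibble::tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, stats::sd),
    conf.low = qs[1, ], conf.high = qs[2, ],
    rhat = x$rhat$rhat)
}

#' One-row fit summary
#'
#' @param x An `rsdfm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: chain/iteration counts, maximum PSRF, number
#'   of flagged parameters, and the convergence verdict at the configured
#'   threshold.
#' @method glance rsdfm_fit
#' @export
glance.rsdfm_fit <- function(x, ...) {
  mr <- suppressWarnings(max(x$rhat$rhat, na.rm = TRUE))
  tibble::tibble(
    n_chains = x$config$n_chains, n_iter = x$config$n_iter,
    n_burnin = x$config$n_burnin, n_kept = nrow(x$draws),
    n_parameters = ncol(x$draws),
    max_rhat = mr, n_flagged = sum(x$rhat$flagged),
    converged = sum(x$rhat$flagged) == 0)
}

#' Posterior state estimates over the observation window
#'
#' @param fit An `rsdfm_fit` object.
#' @param threshold Classify state 2 where the posterior probability
#'   strictly exceeds this value.
#' @return A tibble: `person`, `occasion`, `p_state2`, `S_hat`.
#' @export
state_estimates <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "rsdfm_fit"))
  d <- fit$dims
  tibble::tibble(
    person = rep(seq_len(d$N1), times = d$Nt),
    occasion = rep(seq_len(d$Nt), each = d$N1),
    p_state2 = as.vector(fit$pstate2),
    S_hat = classify_states(as.vector(fit$pstate2), threshold))
}

#' Write posterior draws as delimited text
#'
#' Parameter draws go to `path` in long format (`chain`, `iteration`,
#' `parameter`, `value`); if `states_path` is given, the subsampled latent
#' state paths are written as `person`, `occasion`, `draw`, `S`.
#'
#' @param fit An `rsdfm_fit` object.
#' @param path Output path for parameter draws.
#' @param states_path Optional output path for state paths.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path, states_path = NULL) {
  long <- tibble::tibble(
    chain = rep(fit$chain, times = ncol(fit$draws)),
    iteration = rep(fit$iteration, times = ncol(fit$draws)),
    parameter = rep(colnames(fit$draws), each = nrow(fit$draws)),
    value = as.vector(fit$draws))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(states_path)) {
    d <- fit$dims
    n_draw <- ncol(fit$latent$S)
    st <- tibble::tibble(
      person = rep(rep(seq_len(d$N1), times = d$Nt), times = n_draw),
      occasion = rep(rep(seq_len(d$Nt), each = d$N1), times = n_draw),
      draw = rep(seq_len(n_draw), each = d$N1 * d$Nt),
      S = as.vector(fit$latent$S))
    utils::write.table(st, states_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Draw one person's state path from its full conditional
#'
#' Samples the discrete state path of a single person given that person's
#' factor trajectories, between-level score, random intercepts, and the
#' model parameters, by a discrete forward filter / backward sampler: the
#' "emission" at occasion `t` is the state-specific structural density of
#' the factor scores at `t` given those at `t - 1`, and the chain part uses
#' the covariate-dependent transition matrix. The first occasion is fixed
#' at state 1; occasions with an observed state (dropout tail) are fixed to
#' it.
#'
#' @param params An [rsdfm_params()] object.
#' @param eta1_i `J x T` matrix of the person's factor scores.
#' @param eta2_i Scalar between-factor score.
#' @param zeta2_i Length-`J` random intercepts.
#' @param S_obs_i Length-`T` integer vector: 0 where the state is latent,
#'   otherwise the observed state (1 or 2).
#' @return Integer state path of length `T`.
#' @export
conditional_state_draw <- function(params, eta1_i, eta2_i, zeta2_i,
                                   S_obs_i = NULL) {
  stopifnot(inherits(params, "rsdfm_params"))
  eta1_i <- as.matrix(eta1_i)
  J <- nrow(eta1_i); Tt <- ncol(eta1_i)
  stopifnot(J == params$dims$J, length(zeta2_i) == J)
  if (is.null(S_obs_i)) S_obs_i <- rep(0L, Tt)
  lem <- matrix(0, Tt, 2)
  for (t in 2:Tt) {
    for (s in 1:2) {
      mu <- structural_step(params, eta1_i[, t - 1], eta2_i, zeta2_i, s)
      lem[t, s] <- sum(stats::dnorm(eta1_i[, t], mu,
                                    sqrt(params$sigma2_zeta1), log = TRUE))
    }
    if (S_obs_i[t] == 1L) lem[t, 2] <- -Inf
    if (S_obs_i[t] == 2L) lem[t, 1] <- -Inf
  }
  p11 <- transition_stay_prob(params, t(eta1_i), rep(eta2_i, Tt))
  fwd <- matrix(0, Tt, 2)
  fwd[1, ] <- c(1, 0)
  for (t in 2:Tt) {
    trans <- rbind(c(p11[t - 1], 1 - p11[t - 1]),
                   c(params$p12, 1 - params$p12))
    lw <- log(drop(fwd[t - 1, ] %*% trans)) + lem[t, ]
    w <- exp(lw - max(lw))
    fwd[t, ] <- w / sum(w)
  }
  S <- integer(Tt)
  S[Tt] <- sample(1:2, 1, prob = fwd[Tt, ])
  if (Tt > 2) {
    for (t in (Tt - 1):2) {
      trans_next <- rbind(c(p11[t], 1 - p11[t]),
                          c(params$p12, 1 - params$p12))
      w <- fwd[t, ] * trans_next[, S[t + 1]]
      S[t] <- if (sum(w) <= 0) S[t + 1] else sample(1:2, 1, prob = w)
    }
  }
  S[1] <- 1L
  S
}
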