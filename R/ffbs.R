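#' @useDynLib rsdfm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# stratum order used throughout: (s, s') = (1,1), (2,1), (1,2), (2,2)
STRATA <- c("(1,1)", "(2,1)", "(1,2)", "(2,2)")

stratum_index <- function(s, s_prev) (s - 1L) + 2L * (s_prev - 1L) + 1L

#' Initialize the four-stratum filter
#'
#' Each regime-transition stratum `(s, s')` starts from the same normal
#' prior on the 5-dimensional system vector (intercept, AR coefficient,
#' between-factor effect, cross-level interaction, and the unit random
#' effect loading). The default is weakly informative: zero mean, identity
#' covariance.
#'
#' @param m0 Prior mean (length 5).
#' @param C0 Prior covariance (5 x 5, symmetric positive semidefinite).
#' @return An object of class `rsdfm_filter`: list of 4 strata, each with
#'   elements `m` and `C`, plus a step counter.
#' @export
ffbs_init_filter <- function(m0 = rep(0, 5), C0 = diag(5)) {
  stopifnot(length(m0) == 5, all(dim(C0) == c(5, 5)))
  if (max(abs(C0 - t(C0))) > 1e-8) stop("prior covariance must be symmetric", call. = FALSE)
  ev <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("prior covariance must be positive semidefinite", call. = FALSE)
  }
  strata <- lapply(STRATA, function(s) list(m = as.numeric(m0), C = unname(C0)))
  names(strata) <- STRATA
  structure(list(strata = strata, t = 0L), class = "rsdfm_filter")
}

#' One filtering update at a realized occasion
#'
#' Applies the conjugate dynamic-linear-model recursion within every
#' stratum: with `G = I` and `W = 0`, prior `a = m`, `R = C`; forecast
#' `f = F a`, `Q = F R F' + V`; error `e = y - f`; gain `A = R F' Q^{-1}`;
#' posterior `m = a + A e`, `C = R - A Q A'`.
#'
#' @param filter An [ffbs_init_filter()] object (state at `t - 1`).
#' @param eta1_jt Realized factor scores at `t` (length `N`).
#' @param F Design matrix (`N x 5`): columns 1, lagged factor, between
#'   factor, their product, and the person random intercept.
#' @param V Observation-error variance: a scalar innovation variance
#'   (expanded to `V * I`) or an `N x N` covariance matrix.
#' @return The updated filter; each stratum additionally carries the
#'   step's `a`, `R`, `f`, `Q`, `e`, `A`.
#' @export
ffbs_update_step <- function(filter, eta1_jt, F, V) {
  stopifnot(inherits(filter, "rsdfm_filter"))
  F <- as.matrix(F)
  N <- nrow(F)
  stopifnot(length(eta1_jt) == N, ncol(F) == 5)
  Vm <- if (is.matrix(V)) V else diag(as.numeric(V), N)
  for (s in STRATA) {
    st <- filter$strata[[s]]
    a <- st$m
    R <- st$C
    f <- drop(F %*% a)
    Q <- F %*% R %*% t(F) + Vm
    kap <- kappa(Q, exact = FALSE)
    if (!is.finite(kap) || kap > 1e12) {
      stop(sprintf("forecast covariance Q numerically singular (condition number %.3g)",
                   kap), call. = FALSE)
    }
    e <- eta1_jt - f
    A <- R %*% t(F) %*% solve(Q)
    m <- a + drop(A %*% e)
    C <- R - A %*% Q %*% t(A)
    C <- (C + t(C)) / 2
    filter$strata[[s]] <- list(m = m, C = C, a = a, R = R, f = f, Q = Q,
                               e = e, A = A)
  }
  filter$t <- filter$t + 1L
  filter
}

#' H-steps-ahead forecast distributions per stratum
#'
#' With identity system evolution and zero evolution noise, the system
#' prior stays at the last filtered `(m, C)` for every horizon; the
#' forecast distribution at horizon `h` is `N(F_h m, F_h C F_h' + V)`.
#' `F` may be a single design matrix (reused at every horizon, as when the
#' lagged values are plugged in) or a list of length `H` with one design
#' per horizon (as when lagged values are sampled forward).
#'
#' @param filter Filter updated through the forecast origin.
#' @param F Design matrix or list of design matrices.
#' @param V Scalar innovation variance or `N x N` covariance.
#' @param H Number of horizons (>= 1).
#' @return A tibble with columns `horizon`, `stratum`, `person`, `mean`,
#'   `variance`.
#' @export
ffbs_h_step_forecast <- function(filter, F, V, H = 1L) {
  stopifnot(inherits(filter, "rsdfm_filter"))
  if (H < 1) stop("forecast horizon must be >= 1", call. = FALSE)
  Fl <- if (is.list(F)) F else rep(list(as.matrix(F)), H)
  stopifnot(length(Fl) == H)
  out <- vector("list", H * 4L)
  k <- 0L
  for (h in seq_len(H)) {
    Fh <- as.matrix(Fl[[h]])
    N <- nrow(Fh)
    Vm <- if (is.matrix(V)) V else diag(as.numeric(V), N)
    for (s in STRATA) {
      st <- filter$strata[[s]]
      f <- drop(Fh %*% st$m)
      Q <- Fh %*% st$C %*% t(Fh) + Vm
      k <- k + 1L
      out[[k]] <- tibble::tibble(horizon = h, stratum = s,
                                 person = seq_len(N),
                                 mean = f, variance = diag(Q))
    }
  }
  dplyr::bind_rows(out)
}

#' Joint posterior stratum probabilities at one occasion
#'
#' Combines the transition probabilities, the previous state
#' probabilities, and the one-step forecast errors into the normalized
#' joint probabilities of the four regime-transition strata, computed in
#' log space. Inputs are per person: rows index persons, the four columns
#' follow the stratum order `(1,1), (2,1), (1,2), (2,2)`.
#'
#' @param pi 2 x 2 transition matrix `pi[s, s']` (single person) or an
#'   `N x 4` matrix in stratum order.
#' @param p_prev Length-2 previous-state probabilities (or `N x 2`).
#' @param e Forecast errors, `N x 4` (or length 4).
#' @param q_diag Forecast variances (diagonal elements of Q), same shape
#'   as `e`.
#' @return A list with `p_joint` (`N x 4`, rows summing to 1), `p_state`
#'   (`N x 2`, collapsed over the previous state), and the normalization
#'   constant `c` per person.
#' @export
ffbs_joint_probs <- function(pi, p_prev, e, q_diag) {
  if (is.matrix(pi) && all(dim(pi) == c(2, 2))) {
    pi <- matrix(c(pi[1, 1], pi[2, 1], pi[1, 2], pi[2, 2]), nrow = 1)
  }
  pi <- as.matrix(pi)
  if (is.null(dim(p_prev)) || length(dim(p_prev)) < 2) {
    p_prev <- matrix(p_prev, nrow = nrow(pi), ncol = 2, byrow = TRUE)
  }
  e <- matrix(e, ncol = 4); q_diag <- matrix(q_diag, ncol = 4)
  if (any(q_diag <= 0)) stop("forecast variances must be positive", call. = FALSE)
  sp <- c(1L, 1L, 2L, 2L)  # previous state per stratum column
  lw <- log(pi) + log(p_prev[, sp, drop = FALSE]) -
    0.5 * log(q_diag) - 0.5 * e^2 / q_diag
  mx <- apply(lw, 1, max)
  if (any(!is.finite(mx))) {
    stop("all stratum weights vanish (degenerate likelihood)", call. = FALSE)
  }
  w <- exp(lw - mx)
  tot <- rowSums(w)
  p_joint <- w / tot
  colnames(p_joint) <- STRATA
  p_state <- cbind(p_joint[, 1] + p_joint[, 3], p_joint[, 2] + p_joint[, 4])
  colnames(p_state) <- c("1", "2")
  list(p_joint = p_joint, p_state = p_state, c = exp(-mx) / tot)
}

#' Marginal predictive mixture of the four strata
#'
#' Moments and central interval of the four-component normal mixture that
#' forms the marginal forecast density of a factor score.
#'
#' @param means,variances Component means and variances (length 4, or any
#'   equal length).
#' @param weights Mixture weights; must sum to 1 within 1e-8.
#' @param level Central-interval level.
#' @return A list: `mean`, `variance`, `lower`, `upper`, and functions
#'   `cdf(x)` and `quantile(p)`.
#' @export
ffbs_marginal_predictive <- function(means, variances, weights, level = 0.95) {
  stopifnot(length(means) == length(variances),
            length(means) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  if (any(variances <= 0)) stop("component variances must be positive", call. = FALSE)
  mu <- sum(weights * means)
  v <- sum(weights * (variances + means^2)) - mu^2
  sds <- sqrt(variances)
  cdf <- function(x) {
    vapply(x, function(xx) sum(weights * stats::pnorm(xx, means, sds)), 0)
  }
  qf <- function(p) {
    vapply(p, function(pp) {
      lo <- min(means - 10 * sds); hi <- max(means + 10 * sds)
      stats::uniroot(function(x) cdf(x) - pp, c(lo, hi), tol = 1e-9)$root
    }, 0)
  }
  a <- (1 - level) / 2
  list(mean = mu, variance = v, lower = qf(a), upper = qf(1 - a),
       cdf = cdf, quantile = qf)
}

#' Collapse stratum posteriors onto the current state
#'
#' Moment-matches, for each current state `s`, the mixture of the two
#' strata `(s, 1)` and `(s, 2)` weighted by their joint probabilities:
#' `p(s) = sum_{s'} p(s, s')`, `m(s) = sum m(s,s') p(s,s') / p(s)`, and
#' `C(s) = sum {C(s,s') + (m(s)-m(s,s'))(m(s)-m(s,s'))'} p(s,s')/p(s)`.
#' This step is provided for completeness; the default forecasting
#' pipeline keeps the four strata separate.
#'
#' @param p_joint Length-4 joint probabilities in stratum order.
#' @param m_list List of 4 stratum means (stratum order).
#' @param C_list List of 4 stratum covariances.
#' @return A list: `p_state` (length 2) and per-state `m` and `C` (NULL
#'   where the state probability is 0).
#' @export
ffbs_collapse <- function(p_joint, m_list, C_list) {
  stopifnot(length(p_joint) == 4, length(m_list) == 4, length(C_list) == 4)
  p_state <- c(p_joint[1] + p_joint[3], p_joint[2] + p_joint[4])
  names(p_state) <- c("1", "2")
  m_out <- list(`1` = NULL, `2` = NULL)
  C_out <- list(`1` = NULL, `2` = NULL)
  for (s in 1:2) {
    cols <- c(s, s + 2L)  # strata with current state s
    if (p_state[s] <= 0) next
    wts <- p_joint[cols] / p_state[s]
    m_s <- wts[1] * m_list[[cols[1]]] + wts[2] * m_list[[cols[2]]]
    C_s <- matrix(0, length(m_s), length(m_s))
    for (k in 1:2) {
      dm <- m_s - m_list[[cols[k]]]
      C_s <- C_s + wts[k] * (C_list[[cols[k]]] + outer(dm, dm))
    }
    m_out[[s]] <- m_s
    C_out[[s]] <- C_s
  }
  list(p_state = p_state, m = m_out, C = C_out)
}

#' Classify discrete states from posterior probabilities
#'
#' State 2 is assigned where the probability strictly exceeds the
#' threshold (ties go to state 1).
#'
#' @param p_state2 Probabilities of state 2.
#' @param threshold Classification threshold in (0, 1).
#' @return Integer states (1 or 2).
#' @export
classify_states <- function(p_state2, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  }
  ifelse(p_state2 > threshold, 2L, 1L)
}

#' Forecast latent factors and discrete states
#'
#' Runs the four-stratum forecaster once per retained posterior draw,
#' fully integrated with the sampled latent variables: the filter is run
#' forward over the observation window on the draw's factor trajectories,
#' then propagated `H` occasions ahead, with the lagged factor values of
#' the design sampled from the previous horizon's forecast mixture.
#' Per-draw mixture means and variances are pooled across draws (law of
#' total variance); forecast intervals are central normal intervals on the
#' pooled moments.
#'
#' @param fit An [rsdfm_fit()] object.
#' @param H Forecast horizon; defaults to `fit$dims$H`.
#' @param level Forecast-interval level.
#' @param m0,C0 Filter prior (see [ffbs_init_filter()]).
#' @param aggregate_factors Combine the per-factor likelihood terms across
#'   factors when updating the stratum probabilities (default). With
#'   `FALSE`, each factor keeps its own stratum-probability chain and the
#'   reported state probabilities average the per-factor chains.
#' @param seed Seed for the per-draw forecast sampling.
#' @return An object of class `rsdfm_forecast`: a tibble with columns
#'   `person`, `factor`, `horizon`, `mean`, `variance`, `lower`, `upper`,
#'   `p_state2` (exactly `N1 * J * H` rows). Attributes carry the
#'   observation-window filtered state probabilities (`p2_observed`) and
#'   the interval level.
#' @export
rsdfm_forecast <- function(fit, H = NULL, level = 0.95,
                           m0 = rep(0, 5), C0 = diag(5),
                           aggregate_factors = TRUE, seed = 1L) {
  stopifnot(inherits(fit, "rsdfm_fit"))
  if (is.null(H)) H <- fit$dims$H
  if (H < 1) stop("forecast horizon must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  ffbs_init_filter(m0, C0)  # validates the prior
  d <- fit$dims
  J <- d$J
  cols <- function(nm, n) paste0(nm, "[", seq_len(n), "]")
  idx <- fit$latent$kept_idx +
    (fit$latent$chain - 1L) * (nrow(fit$draws) / fit$config$n_chains)
  dm <- fit$draws[idx, , drop = FALSE]
  set.seed(seed)
  res <- ffbs_forecast_cpp(
    fit$latent$eta1, fit$latent$eta2, fit$latent$zeta2, fit$latent$S,
    dm[, cols("sigma2_zeta1", J), drop = FALSE],
    dm[, "gamma1"], dm[, "gamma2"],
    dm[, cols("gamma3", J), drop = FALSE],
    dm[, cols("gamma4", J), drop = FALSE],
    dm[, "p12"],
    d$N1, J, d$Nt, as.integer(H),
    as.numeric(m0), as.matrix(C0), isTRUE(aggregate_factors))
  K <- res$K
  mu <- res$sum_mu / K
  var_within <- res$sum_var / K
  var_between <- pmax(res$sum_mu2 / K - mu^2, 0)
  vtot <- var_within + var_between
  z <- stats::qnorm((1 + level) / 2)
  p2 <- res$sum_p2_fore / K
  out <- tibble::tibble(
    person = rep(seq_len(d$N1), times = J * H),
    factor = rep(rep(seq_len(J), each = d$N1), times = H),
    horizon = rep(seq_len(H), each = d$N1 * J),
    mean = as.vector(mu),
    variance = as.vector(vtot),
    lower = as.vector(mu - z * sqrt(vtot)),
    upper = as.vector(mu + z * sqrt(vtot)),
    p_state2 = p2[cbind(rep(seq_len(d$N1), times = J * H),
                        rep(seq_len(H), each = d$N1 * J))])
  class(out) <- c("rsdfm_forecast", class(out))
  attr(out, "p2_observed") <- res$sum_p2_obs / K
  attr(out, "level") <- level
  attr(out, "H") <- as.integer(H)
  attr(out, "dims") <- d
  out
}

#' Discrete state forecasts
#'
#' @param forecast An [rsdfm_forecast()] result.
#' @param threshold Classification threshold (strict inequality).
#' @return A tibble: `person`, `horizon`, `p_state2`, `S_hat`.
#' @export
forecast_states <- function(forecast, threshold = 0.5) {
  stopifnot(inherits(forecast, "rsdfm_forecast"))
  out <- dplyr::distinct(tibble::as_tibble(forecast)[, c("person", "horizon", "p_state2")])
  out$S_hat <- classify_states(out$p_state2, threshold)
  out
}

#' Write a forecast table as delimited text
#'
#' Fixed column order: `person`, `factor`, `horizon`, `mean`, `variance`,
#' `lower`, `upper`, `p_state2`.
#'
#' @param forecast An [rsdfm_forecast()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(forecast, path) {
  utils::write.table(
    tibble::as_tibble(forecast)[, c("person", "factor", "horizon", "mean",
                                    "variance", "lower", "upper", "p_state2")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
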