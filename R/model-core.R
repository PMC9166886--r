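#' Probability of staying in state 1
#'
#' Evaluates `P(S_t = 1 | S_{t-1} = 1)` for one or more persons: the
#' logistic transform of the linear predictor
#' `nu = gamma1 + gamma2 * eta2 + gamma3' eta1_prev + gamma4' (eta1_prev * eta2)`,
#' computed in a numerically safe way for large `|nu|`.
#'
#' @param params An [rsdfm_params()] object (only the transition-model
#'   coefficients are used).
#' @param eta1_prev Lagged within-factor scores: a length-`J` vector, or an
#'   `N x J` matrix for several persons.
#' @param eta2 Between-factor score(s): scalar or length-`N`.
#' @return A probability (or vector of probabilities).
#' @export
#' @examples
#' d <- rsdfm_dims(N1 = 5, Nt = 5)
#' p <- example_params(d)
#' transition_stay_prob(p, rep(0, 3), 0)
transition_stay_prob <- function(params, eta1_prev, eta2) {
  stopifnot(inherits(params, "rsdfm_params"))
  J <- params$dims$J
  if (is.null(dim(eta1_prev))) eta1_prev <- matrix(eta1_prev, nrow = 1)
  if (ncol(eta1_prev) != J) stop("`eta1_prev` must have J columns", call. = FALSE)
  if (!all(is.finite(eta1_prev))) {
    bad <- which(!is.finite(eta1_prev), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite `eta1_prev` for person %d, factor %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (!all(is.finite(eta2))) {
    stop(sprintf("non-finite `eta2` for person %d",
                 which(!is.finite(eta2))[1]), call. = FALSE)
  }
  nu <- params$gamma1 + params$gamma2 * eta2 +
    drop(eta1_prev %*% params$gamma3) +
    drop(eta1_prev %*% params$gamma4) * eta2
  # plogis evaluates exp(nu)/(1 + exp(nu)) without overflow
  stats::plogis(nu)
}

#' Transition matrix of the discrete state process
#'
#' Row 1 holds the transition probabilities out of state 1 (covariate
#' dependent through the lagged factor scores); row 2 is
#' `(p12, 1 - p12)` with the person- and time-constant return probability.
#'
#' @inheritParams transition_stay_prob
#' @return A 2 x 2 row-stochastic matrix (single person input).
#' @export
transition_matrix <- function(params, eta1_prev, eta2) {
  if (params$p12 < 0 || params$p12 > 1) stop("`p12` outside [0, 1]", call. = FALSE)
  p11 <- transition_stay_prob(params, eta1_prev, eta2)
  stopifnot(length(p11) == 1)
  matrix(c(p11, 1 - p11, params$p12, 1 - params$p12),
         nrow = 2, byrow = TRUE,
         dimnames = list(from = c("1", "2"), to = c("1", "2")))
}

#' Conditional mean of the within-factor AR(1) step
#'
#' Computes the structural mean
#' `alpha1_is + B1_is eta1_{t-1}` where the person-specific intercept is
#' `alpha21_s + beta2_s * eta2 + zeta2_i` and the person-specific AR
#' coefficient is `b1_s + omega2_s * eta2` (diagonal dynamics).
#'
#' @inheritParams transition_stay_prob
#' @param eta1_prev Length-`J` lagged factor scores.
#' @param zeta2_i Length-`J` person-level random-intercept residuals.
#' @param s Discrete state, 1 or 2.
#' @return Length-`J` conditional mean.
#' @export
structural_step <- function(params, eta1_prev, eta2, zeta2_i, s) {
  stopifnot(inherits(params, "rsdfm_params"), s %in% c(1, 2),
            length(eta2) == 1)
  J <- params$dims$J
  if (length(eta1_prev) != J || length(zeta2_i) != J) {
    stop("`eta1_prev` and `zeta2_i` must have length J", call. = FALSE)
  }
  co <- state_coefs(params, s)
  alpha1 <- co$alpha21 + co$beta2 * eta2 + zeta2_i
  ar <- co$b1 + co$omega2 * eta2
  alpha1 + ar * eta1_prev
}

#' Example parameter set
#'
#' A fixed, valid parameter set used in documentation and tests: moderate
#' positive AR(1) coefficients, unit level shift for state 2, negative
#' between-factor main effects, and a transition model with a strong
#' tendency to stay in state 1.
#'
#' @param dims An [rsdfm_dims()] object.
#' @return An [rsdfm_params()] object.
#' @export
example_params <- function(dims = rsdfm_dims(N1 = 25, Nt = 25)) {
  J <- dims$J
  lambda1 <- rep(0.9, dims$p); lambda1[dims$scaling_items] <- 1
  lambda2 <- rep(0.9, dims$q); lambda2[1] <- 1
  mask <- rep(FALSE, J); mask[J] <- TRUE
  rsdfm_params(
    dims,
    lambda1 = lambda1, sigma2_eps1 = rep(0.3, dims$p),
    lambda2 = lambda2, sigma2_eps2 = rep(0.3, dims$q), sigma2_eta2 = 1,
    alpha21 = rep(0, J), delta_alpha21 = rep(1, J),
    beta2 = rep(-0.2, J), delta_beta2 = rep(0, J),
    b1 = rep(0.4, J), delta_b1 = rep(0.15, J),
    omega2 = rep(0.1, J), delta_omega2 = rep(0, J),
    sigma2_zeta1 = rep(0.45, J), sigma2_zeta2 = rep(0.5, J),
    gamma1 = 3.5, gamma2 = 0.2, gamma3 = rep(-0.5, J),
    gamma4 = c(rep(0, J - 1), 0.05), gamma4_mask = mask,
    p12 = 0.097
  )
}
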