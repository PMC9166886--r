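#' Model dimensions
#'
#' Describes the size of a regime-switching dynamic factor model: number of
#' persons, observed occasions, forecast horizon, latent within-person
#' factors, within- and between-level indicators, and the map from within
#' indicators to factors (simple structure).
#'
#' @param N1 Number of persons.
#' @param Nt Number of observed measurement occasions (the forecast origin).
#' @param H Forecast horizon: additional occasions beyond `Nt`.
#' @param J Number of latent within-person factors.
#' @param q Number of between-level indicators (all load on the single
#'   between factor).
#' @param item_map Integer vector of length `p` assigning each within
#'   indicator to a factor (values in `1:J`). Must partition the indicators
#'   so every factor has at least one indicator; the first indicator of each
#'   factor is its scaling item (loading fixed to 1). Defaults to three
#'   indicators per factor.
#'
#' @return An object of class `rsdfm_dims`.
#' @export
#' @examples
#' rsdfm_dims(N1 = 25, Nt = 25)
rsdfm_dims <- function(N1, Nt, H = 10L, J = 3L, q = 3L,
                       item_map = rep(seq_len(J), each = 3L)) {
  N1 <- as.integer(N1); Nt <- as.integer(Nt); H <- as.integer(H)
  J <- as.integer(J); q <- as.integer(q)
  item_map <- as.integer(item_map)
  p <- length(item_map)
  stopifnot(N1 > 0, Nt > 0, H >= 0, J > 0, q > 0, p >= J)
  if (!setequal(unique(item_map), seq_len(J))) {
    stop("`item_map` must use every factor index 1..J at least once", call. = FALSE)
  }
  structure(
    list(N1 = N1, Nt = Nt, H = H, J = J, p = p, q = q,
         item_map = item_map, nS = 2L,
         scaling_items = vapply(seq_len(J), function(j) which(item_map == j)[1], 1L)),
    class = "rsdfm_dims"
  )
}

#' @export
print.rsdfm_dims <- function(x, ...) {
  cat("<rsdfm_dims> N1 =", x$N1, "| Nt =", x$Nt, "| H =", x$H,
      "| J =", x$J, "| p =", x$p, "| q =", x$q, "\n")
  invisible(x)
}

#' Model parameters
#'
#' Container for every parameter of the regime-switching dynamic factor
#' model. State-2 structural coefficients are stored as state-1 values plus
#' shifts; the level shift `delta_alpha21` is constrained nonnegative, which
#' identifies the state labels (state 2 has elevated factor levels).
#'
#' @param dims An [rsdfm_dims()] object.
#' @param lambda1 Length-`p` loadings of within indicators on their factor;
#'   scaling items must be exactly 1.
#' @param sigma2_eps1 Length-`p` within measurement-error variances.
#' @param lambda2 Length-`q` between loadings; first fixed to 1.
#' @param sigma2_eps2 Length-`q` between measurement-error variances.
#' @param sigma2_eta2 Variance of the between factor.
#' @param alpha21 Length-`J` state-1 structural intercepts.
#' @param delta_alpha21 Length-`J` nonnegative state-2 intercept shifts.
#' @param beta2,delta_beta2 Length-`J` main effects of the between factor
#'   (state 1) and their state-2 shifts.
#' @param b1,delta_b1 Length-`J` diagonal AR(1) coefficients (state 1) and
#'   state-2 shifts.
#' @param omega2,delta_omega2 Length-`J` diagonal cross-level interaction
#'   coefficients (state 1) and state-2 shifts.
#' @param sigma2_zeta1 Length-`J` within innovation variances (state
#'   invariant).
#' @param sigma2_zeta2 Length-`J` between residual variances of the random
#'   intercepts.
#' @param gamma1,gamma2 Intercept and between-factor effect in the
#'   stay-in-state-1 logit.
#' @param gamma3 Length-`J` lagged-factor effects in the logit.
#' @param gamma4 Length-`J` interaction effects (lagged factor x between
#'   factor); entries where `gamma4_mask` is `FALSE` must be exactly 0.
#' @param gamma4_mask Logical length-`J`; which factors carry an interaction
#'   term in the transition model.
#' @param p12 Probability of returning from state 2 to state 1; must lie in
#'   `[0, 0.1]`.
#' @param validate If `FALSE`, skip support checks (used to evaluate the
#'   prior density of out-of-support values, where it is `-Inf`).
#'
#' @return An object of class `rsdfm_params`.
#' @export
rsdfm_params <- function(dims,
                         lambda1, sigma2_eps1,
                         lambda2, sigma2_eps2, sigma2_eta2,
                         alpha21, delta_alpha21,
                         beta2, delta_beta2,
                         b1, delta_b1,
                         omega2, delta_omega2,
                         sigma2_zeta1, sigma2_zeta2,
                         gamma1, gamma2, gamma3, gamma4, gamma4_mask,
                         p12, validate = TRUE) {
  stopifnot(inherits(dims, "rsdfm_dims"))
  x <- list(
    dims = dims,
    lambda1 = as.numeric(lambda1), sigma2_eps1 = as.numeric(sigma2_eps1),
    lambda2 = as.numeric(lambda2), sigma2_eps2 = as.numeric(sigma2_eps2),
    sigma2_eta2 = as.numeric(sigma2_eta2),
    alpha21 = as.numeric(alpha21), delta_alpha21 = as.numeric(delta_alpha21),
    beta2 = as.numeric(beta2), delta_beta2 = as.numeric(delta_beta2),
    b1 = as.numeric(b1), delta_b1 = as.numeric(delta_b1),
    omega2 = as.numeric(omega2), delta_omega2 = as.numeric(delta_omega2),
    sigma2_zeta1 = as.numeric(sigma2_zeta1), sigma2_zeta2 = as.numeric(sigma2_zeta2),
    gamma1 = as.numeric(gamma1), gamma2 = as.numeric(gamma2),
    gamma3 = as.numeric(gamma3), gamma4 = as.numeric(gamma4),
    gamma4_mask = as.logical(gamma4_mask),
    p12 = as.numeric(p12)
  )
  class(x) <- "rsdfm_params"
  if (validate) validate_params(x)
  x
}

validate_params <- function(x) {
  d <- x$dims
  chk_len <- function(v, n, nm) {
    if (length(x[[v]]) != n) stop(sprintf("`%s` must have length %d", nm, n), call. = FALSE)
  }
  chk_len("lambda1", d$p, "lambda1"); chk_len("sigma2_eps1", d$p, "sigma2_eps1")
  chk_len("lambda2", d$q, "lambda2"); chk_len("sigma2_eps2", d$q, "sigma2_eps2")
  for (v in c("alpha21", "delta_alpha21", "beta2", "delta_beta2", "b1",
              "delta_b1", "omega2", "delta_omega2", "sigma2_zeta1",
              "sigma2_zeta2", "gamma3", "gamma4")) chk_len(v, d$J, v)
  chk_len("gamma4_mask", d$J, "gamma4_mask")
  if (any(abs(x$lambda1[d$scaling_items] - 1) > 1e-12)) {
    stop("scaling-item loadings must be fixed to 1", call. = FALSE)
  }
  if (abs(x$lambda2[1] - 1) > 1e-12) {
    stop("first between loading must be fixed to 1", call. = FALSE)
  }
  if (any(x$delta_alpha21 < 0)) {
    stop("`delta_alpha21` must be nonnegative (state-label identification)", call. = FALSE)
  }
  if (any(x$gamma4[!x$gamma4_mask] != 0)) {
    stop("masked entries of `gamma4` must be exactly 0", call. = FALSE)
  }
  vars <- c(x$sigma2_eps1, x$sigma2_eps2, x$sigma2_eta2,
            x$sigma2_zeta1, x$sigma2_zeta2)
  if (any(vars <= 0)) stop("all variances must be positive", call. = FALSE)
  if (x$p12 < 0 || x$p12 > 0.1) {
    stop("`p12` must lie in [0, 0.1]", call. = FALSE)
  }
  invisible(x)
}

#' State-specific structural coefficients
#'
#' Resolves the stored state-1 coefficients plus state-2 shifts into the
#' coefficient set that applies in discrete state `s`.
#'
#' @param params An [rsdfm_params()] object.
#' @param s Discrete state, 1 or 2.
#' @return A list with elements `alpha21`, `beta2`, `b1`, `omega2`, each of
#'   length `J`.
#' @export
state_coefs <- function(params, s) {
  stopifnot(inherits(params, "rsdfm_params"), s %in% c(1, 2))
  if (s == 1) {
    list(alpha21 = params$alpha21, beta2 = params$beta2,
         b1 = params$b1, omega2 = params$omega2)
  } else {
    list(alpha21 = params$alpha21 + params$delta_alpha21,
         beta2 = params$beta2 + params$delta_beta2,
         b1 = params$b1 + params$delta_b1,
         omega2 = params$omega2 + params$delta_omega2)
  }
}

#' @export
print.rsdfm_params <- function(x, ...) {
  d <- x$dims
  cat("<rsdfm_params>", d$J, "factors,", d$p, "within items,", d$q, "between items\n")
  cat("  AR(1) state 1:", signif(x$b1, 3), "\n")
  cat("  level shift (state 2):", signif(x$delta_alpha21, 3), "\n")
  cat("  p12:", signif(x$p12, 3), "\n")
  invisible(x)
}

#' Flatten parameters to a named numeric vector
#'
#' Keys use bracketed indices (`lambda1[4]`, `alpha21[2,1]`, ...). State-2
#' rows of `alpha21`, `beta2`, `b1` and `omega2` are the resolved values
#' (state 1 plus shift).
#'
#' @param params An [rsdfm_params()] object.
#' @return A named numeric vector.
#' @export
params_flatten <- function(params) {
  p <- params; d <- p$dims
  idx <- function(nm, n) paste0(nm, "[", seq_len(n), "]")
  s2 <- state_coefs(p, 2)
  out <- c(
    stats::setNames(p$lambda1, idx("lambda1", d$p)),
    stats::setNames(p$sigma2_eps1, idx("sigma2_eps1", d$p)),
    stats::setNames(p$lambda2, idx("lambda2", d$q)),
    stats::setNames(p$sigma2_eps2, idx("sigma2_eps2", d$q)),
    stats::setNames(p$sigma2_eta2, "sigma2_eta2"),
    stats::setNames(p$alpha21, paste0("alpha21[1,", seq_len(d$J), "]")),
    stats::setNames(s2$alpha21, paste0("alpha21[2,", seq_len(d$J), "]")),
    stats::setNames(p$delta_alpha21, idx("delta_alpha21", d$J)),
    stats::setNames(p$beta2, paste0("beta2[1,", seq_len(d$J), "]")),
    stats::setNames(s2$beta2, paste0("beta2[2,", seq_len(d$J), "]")),
    stats::setNames(p$b1, paste0("b1[1,", seq_len(d$J), "]")),
    stats::setNames(s2$b1, paste0("b1[2,", seq_len(d$J), "]")),
    stats::setNames(p$omega2, paste0("omega2[1,", seq_len(d$J), "]")),
    stats::setNames(s2$omega2, paste0("omega2[2,", seq_len(d$J), "]")),
    stats::setNames(p$sigma2_zeta1, idx("sigma2_zeta1", d$J)),
    stats::setNames(p$sigma2_zeta2, idx("sigma2_zeta2", d$J)),
    stats::setNames(p$gamma1, "gamma1"),
    stats::setNames(p$gamma2, "gamma2"),
    stats::setNames(p$gamma3, idx("gamma3", d$J)),
    stats::setNames(p$gamma4, idx("gamma4", d$J)),
    stats::setNames(p$p12, "p12")
  )
  out
}

#' Serialize parameters to JSON
#'
#' Writes a flat key-value document (full double precision) that
#' round-trips exactly through [params_from_json()]. Dimension metadata and
#' the interaction mask are stored alongside the numeric entries.
#'
#' @param params An [rsdfm_params()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
params_to_json <- function(params, path = NULL) {
  d <- params$dims
  doc <- list(
    dims = list(N1 = d$N1, Nt = d$Nt, H = d$H, J = d$J, q = d$q,
                item_map = d$item_map),
    gamma4_mask = params$gamma4_mask,
    values = as.list(params_flatten(params))
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Deserialize parameters from JSON
#'
#' @param input A path to, or the string of, a document written by
#'   [params_to_json()].
#' @return An [rsdfm_params()] object.
#' @export
params_from_json <- function(input) {
  doc <- jsonlite::fromJSON(input)
  dd <- doc$dims
  dims <- rsdfm_dims(N1 = dd$N1, Nt = dd$Nt, H = dd$H, J = dd$J, q = dd$q,
                     item_map = dd$item_map)
  v <- unlist(doc$values)
  g <- function(nm, n) unname(v[paste0(nm, "[", seq_len(n), "]")])
  gs <- function(nm, s, n) unname(v[paste0(nm, "[", s, ",", seq_len(n), "]")])
  J <- dims$J
  rsdfm_params(
    dims,
    lambda1 = g("lambda1", dims$p), sigma2_eps1 = g("sigma2_eps1", dims$p),
    lambda2 = g("lambda2", dims$q), sigma2_eps2 = g("sigma2_eps2", dims$q),
    sigma2_eta2 = unname(v["sigma2_eta2"]),
    alpha21 = gs("alpha21", 1, J),
    delta_alpha21 = g("delta_alpha21", J),
    beta2 = gs("beta2", 1, J), delta_beta2 = gs("beta2", 2, J) - gs("beta2", 1, J),
    b1 = gs("b1", 1, J), delta_b1 = gs("b1", 2, J) - gs("b1", 1, J),
    omega2 = gs("omega2", 1, J), delta_omega2 = gs("omega2", 2, J) - gs("omega2", 1, J),
    sigma2_zeta1 = g("sigma2_zeta1", J), sigma2_zeta2 = g("sigma2_zeta2", J),
    gamma1 = unname(v["gamma1"]), gamma2 = unname(v["gamma2"]),
    gamma3 = g("gamma3", J), gamma4 = g("gamma4", J),
    gamma4_mask = as.logical(doc$gamma4_mask),
    p12 = unname(v["p12"])
  )
}

#' Prior specification
#'
#' Defaults follow the model's baseline priors: truncated-normal
#' TN(0, 1, 0, Inf) for free loadings and for the nonnegative state-2 level
#' shifts, N(0, 1) for all other coefficients and shifts, Gamma(9, 4) for
#' every precision (inverse variance), and Uniform(0, 0.1) for the return
#' probability `p12`. Every hyperparameter can be overridden.
#'
#' @param loading_mean,loading_sd Truncated-normal hyperparameters for free
#'   loadings (truncation at 0 from below).
#' @param coef_mean,coef_sd Normal hyperparameters for structural, shift and
#'   transition coefficients.
#' @param delta_alpha_mean,delta_alpha_sd Truncated-normal hyperparameters
#'   for the nonnegative state-2 level shifts.
#' @param prec_shape,prec_rate Gamma hyperparameters for precisions.
#' @param p12_min,p12_max Support of the uniform prior on `p12`.
#' @return An object of class `rsdfm_priors`.
#' @export
rsdfm_priors <- function(loading_mean = 0, loading_sd = 1,
                         coef_mean = 0, coef_sd = 1,
                         delta_alpha_mean = 0, delta_alpha_sd = 1,
                         prec_shape = 9, prec_rate = 4,
                         p12_min = 0, p12_max = 0.1) {
  stopifnot(loading_sd > 0, coef_sd > 0, delta_alpha_sd > 0,
            prec_shape > 0, prec_rate > 0,
            p12_min >= 0, p12_max <= 1, p12_min < p12_max)
  structure(
    list(loading_mean = loading_mean, loading_sd = loading_sd,
         coef_mean = coef_mean, coef_sd = coef_sd,
         delta_alpha_mean = delta_alpha_mean, delta_alpha_sd = delta_alpha_sd,
         prec_shape = prec_shape, prec_rate = prec_rate,
         p12_min = p12_min, p12_max = p12_max),
    class = "rsdfm_priors"
  )
}

# log density helpers used by log_prior_density and tests
ldnorm <- function(x, mean, sd) stats::dnorm(x, mean, sd, log = TRUE)

ldtnorm_pos <- function(x, mean, sd) {
  # N(mean, sd) truncated to (0, Inf)
  ifelse(x < 0, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

ldgamma <- function(x, shape, rate) stats::dgamma(x, shape, rate = rate, log = TRUE)

#' Log prior density of a full parameter set
#'
#' Sums the log prior densities of every free parameter, including
#' truncation normalizers. Variance parameters carry a Gamma prior on the
#' precision scale, and the density is evaluated on that scale (the
#' precision is the parameter). Returns `-Inf` outside the prior support
#' (negative level shift, `p12` outside its uniform support, nonpositive
#' variance, negative free loading, nonzero masked interaction).
#'
#' @param params An [rsdfm_params()] object.
#' @param priors An [rsdfm_priors()] object.
#' @return A scalar log density.
#' @export
log_prior_density <- function(params, priors = rsdfm_priors()) {
  stopifnot(inherits(params, "rsdfm_params"), inherits(priors, "rsdfm_priors"))
  p <- params; d <- p$dims; pr <- priors
  free_l1 <- p$lambda1[-d$scaling_items]
  free_l2 <- if (d$q > 1) p$lambda2[-1] else numeric(0)
  vars <- c(p$sigma2_eps1, p$sigma2_eps2, p$sigma2_eta2,
            p$sigma2_zeta1, p$sigma2_zeta2)
  if (any(vars <= 0)) return(-Inf)
  if (p$p12 < pr$p12_min || p$p12 > pr$p12_max) return(-Inf)
  if (any(p$delta_alpha21 < 0) || any(free_l1 < 0) || any(free_l2 < 0)) return(-Inf)
  if (any(p$gamma4[!p$gamma4_mask] != 0)) return(-Inf)
  ld_var <- function(s2) ldgamma(1 / s2, pr$prec_shape, pr$prec_rate)
  out <- sum(ldtnorm_pos(free_l1, pr$loading_mean, pr$loading_sd)) +
    sum(ldtnorm_pos(free_l2, pr$loading_mean, pr$loading_sd)) +
    sum(ld_var(vars)) +
    sum(ldnorm(c(p$alpha21, p$beta2, p$b1, p$omega2,
                 p$delta_beta2, p$delta_b1, p$delta_omega2,
                 p$gamma1, p$gamma2, p$gamma3, p$gamma4[p$gamma4_mask]),
               pr$coef_mean, pr$coef_sd)) +
    sum(ldtnorm_pos(p$delta_alpha21, pr$delta_alpha_mean, pr$delta_alpha_sd)) -
    log(pr$p12_max - pr$p12_min)
  out
}
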