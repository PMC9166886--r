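#' Simulation design
#'
#' Describes a full synthetic study: the crossed (N1, Nt) conditions, the
#' forecast holdout horizon, the number of replications, the population
#' table from which each replication's generating parameters are drawn, and
#' the missing-data rate for the within-level responses.
#'
#' The defaults reproduce the package's reference study: persons
#' `N1 in {25, 50}` crossed with occasions `Nt in {25, 50}`, a holdout of
#' `H = 10` further occasions, and 100 replications per condition.
#'
#' @param conditions Data frame with columns `N1` and `Nt`.
#' @param H Holdout horizon (occasions generated beyond `Nt`).
#' @param R Replications per condition.
#' @param population Population table, see [default_population()]: one row
#'   per parameter family with columns `parameter`, `mean`, `sd`.
#' @param missing_rate Fraction of within-level responses masked completely
#'   at random, in `[0, 1)`.
#' @param J,q,item_map Model size passed to [rsdfm_dims()].
#' @param seed Master seed; per-replication seeds are derived from it.
#' @return An object of class `rsdfm_design`.
#' @export
sim_design <- function(conditions = tidyr::crossing(N1 = c(25L, 50L), Nt = c(25L, 50L)),
                       H = 10L, R = 100L,
                       population = default_population(),
                       missing_rate = 0,
                       J = 3L, q = 3L, item_map = rep(seq_len(J), each = 3L),
                       seed = 1L) {
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("N1", "Nt") %in% names(conditions)),
            nrow(conditions) >= 1, R >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(conditions = conditions, H = as.integer(H), R = as.integer(R),
         population = population, missing_rate = missing_rate,
         J = as.integer(J), q = as.integer(q), item_map = as.integer(item_map),
         seed = as.integer(seed)),
    class = "rsdfm_design"
  )
}

#' Default population table for replication-level parameter draws
#'
#' Reads the shipped population table (`inst/extdata/population-defaults.json`):
#' one normal (mean, sd) hyperparameter pair per parameter family, applied
#' independently to every element of that family. The shipped values encode
#' positive AR(1) coefficients, clearly elevated state-2 levels, negative
#' between-factor main effects, interaction effects near zero, a return
#' probability near 0.1, and within/between variances giving intraclass
#' correlations near one half.
#'
#' @param path Optional path to an alternative JSON table.
#' @return A tibble with columns `parameter`, `mean`, `sd`.
#' @export
default_population <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "population-defaults.json", package = "rsdfm")
  }
  doc <- jsonlite::fromJSON(path)
  tibble::tibble(parameter = names(doc),
                 mean = unname(vapply(doc, function(x) x$mean, 0)),
                 sd = unname(vapply(doc, function(x) x$sd, 0)))
}

# one rejection-sampled draw per element; support constraints per family
draw_family <- function(n, mean, sd, lower = -Inf, upper = Inf, family = "") {
  out <- numeric(n)
  for (k in seq_len(n)) {
    val <- stats::rnorm(1, mean, sd)
    tries <- 0L
    while (val < lower || val > upper) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop(sprintf(
          "more than 1000 consecutive rejections drawing `%s` from N(%g, %g) on [%g, %g]",
          family, mean, sd, lower, upper), call. = FALSE)
      }
      val <- stats::rnorm(1, mean, sd)
    }
    out[k] <- val
  }
  out
}

#' Draw one replication's generating parameters
#'
#' Samples every free parameter independently from the population normal
#' hyperparameters, redrawing (rejection) any value outside its support:
#' loadings and variances positive, state-2 level shifts nonnegative, and
#' the return probability inside `[0, 0.1]`. The dynamics block is
#' additionally constrained to the mean-reverting region: the
#' person-specific AR coefficient `b1_s + omega2_s * eta2` must stay inside
#' `(-0.97, 0.97)` in both states for persons within 2.5 SD of the
#' between-factor distribution, since an explosive latent affect process is
#' not a meaningful data-generating condition (draws violating the bound
#' are rejected and redrawn as a block).
#'
#' @param dims An [rsdfm_dims()] object.
#' @param population Population table as in [default_population()].
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @param gamma4_mask Logical length-`J` mask of interacting factors;
#'   default marks the last factor only.
#' @return An [rsdfm_params()] object.
#' @export
draw_replication_params <- function(dims, population = default_population(),
                                    seed = 1L,
                                    gamma4_mask = c(rep(FALSE, dims$J - 1), TRUE)) {
  stopifnot(inherits(dims, "rsdfm_dims"))
  set.seed(seed)
  pop <- function(nm) {
    row <- population[population$parameter == nm, ]
    if (nrow(row) != 1) stop(sprintf("population table lacks `%s`", nm), call. = FALSE)
    row
  }
  dr <- function(nm, n, lower = -Inf, upper = Inf) {
    r <- pop(nm)
    draw_family(n, r$mean, r$sd, lower, upper, family = nm)
  }
  J <- dims$J
  lambda1 <- rep(1, dims$p)
  free1 <- setdiff(seq_len(dims$p), dims$scaling_items)
  lambda1[free1] <- dr("lambda1", length(free1), lower = 0)
  lambda2 <- rep(1, dims$q)
  if (dims$q > 1) lambda2[-1] <- dr("lambda2", dims$q - 1, lower = 0)
  gamma4 <- rep(0, J)
  gamma4[gamma4_mask] <- dr("gamma4", sum(gamma4_mask))
  sigma2_eta2 <- dr("sigma2_eta2", 1, lower = 1e-8)
  # dynamics block: reject draws whose person-specific AR coefficient
  # b1_s + omega2_s * eta2 can leave (-0.97, 0.97) within 2.5 SD of the
  # between-factor distribution (explosive latent dynamics are not a
  # meaningful generating condition for mean-reverting affect processes)
  eta2_span <- 2.5 * sqrt(sigma2_eta2)
  tries <- 0L
  repeat {
    b1 <- dr("b1", J); delta_b1 <- dr("delta_b1", J)
    omega2 <- dr("omega2", J); delta_omega2 <- dr("delta_omega2", J)
    m1 <- max(abs(b1) + abs(omega2) * eta2_span)
    m2 <- max(abs(b1 + delta_b1) + abs(omega2 + delta_omega2) * eta2_span)
    if (max(m1, m2) < 0.97) break
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("more than 1000 consecutive rejections drawing a mean-reverting ",
           "dynamics block; population hyperparameters for `b1`/`omega2` ",
           "put too much mass on explosive dynamics", call. = FALSE)
    }
  }
  rsdfm_params(
    dims,
    lambda1 = lambda1,
    sigma2_eps1 = dr("sigma2_eps1", dims$p, lower = 1e-8),
    lambda2 = lambda2,
    sigma2_eps2 = dr("sigma2_eps2", dims$q, lower = 1e-8),
    sigma2_eta2 = sigma2_eta2,
    alpha21 = dr("alpha21", J),
    delta_alpha21 = dr("delta_alpha21", J, lower = 0),
    beta2 = dr("beta2", J), delta_beta2 = dr("delta_beta2", J),
    b1 = b1, delta_b1 = delta_b1,
    omega2 = omega2, delta_omega2 = delta_omega2,
    sigma2_zeta1 = dr("sigma2_zeta1", J, lower = 1e-8),
    sigma2_zeta2 = dr("sigma2_zeta2", J, lower = 1e-8),
    gamma1 = dr("gamma1", 1), gamma2 = dr("gamma2", 1),
    gamma3 = dr("gamma3", J),
    gamma4 = gamma4, gamma4_mask = gamma4_mask,
    p12 = dr("p12", 1, lower = 0, upper = 0.1)
  )
}

#' Simulate a synthetic panel from the generative model
#'
#' Draws the between factor and random intercepts, forward-simulates the
#' discrete state path and within-factor trajectories jointly over
#' `Nt + H` occasions (the state at occasion `t` is sampled from the
#' covariate-dependent transition matrix driven by the lagged factors; the
#' factors then follow the state-specific AR(1) step), and generates the
#' within- and between-level item responses from the measurement models.
#' Every person starts in state 1; the initial factor scores are drawn from
#' the person's stationary state-1 distribution. Missingness is applied to
#' the within responses completely at random.
#'
#' @param params An [rsdfm_params()] object.
#' @param dims An [rsdfm_dims()] object (defaults to `params$dims`).
#' @param missing_rate MCAR missingness fraction for within responses.
#' @param seed Integer seed.
#' @return An object of class `rsdfm_sim`: a list with tibbles `panel`
#'   (`person`, `occasion`, `item`, `value`), `between` (`person`, `item`,
#'   `value`), `truth` (`person`, `occasion`, `factor`, `eta1`, `S`),
#'   `dropout` (empty until [inject_dropout()] is applied), and a `latent`
#'   list of arrays (`eta1` `N1 x J x T`, `eta2`, `zeta2`, `S`,
#'   `S_observed`). Occasions are labelled 1..`Nt + H`; the first `Nt` are
#'   the observation window.
#' @export
simulate_panel <- function(params, dims = params$dims, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(params, "rsdfm_params"), inherits(dims, "rsdfm_dims"))
  validate_params(params)
  set.seed(seed)
  N1 <- dims$N1; J <- dims$J; Tt <- dims$Nt + dims$H
  eta2 <- stats::rnorm(N1, 0, sqrt(params$sigma2_eta2))
  zeta2 <- matrix(stats::rnorm(N1 * J, 0, rep(sqrt(params$sigma2_zeta2), each = N1)),
                  N1, J)
  eta1 <- array(NA_real_, c(N1, J, Tt))
  S <- matrix(NA_integer_, N1, Tt)
  co1 <- state_coefs(params, 1)
  for (i in seq_len(N1)) {
    S[i, 1] <- 1L
    ar0 <- co1$b1 + co1$omega2 * eta2[i]
    mu_a <- co1$alpha21 + co1$beta2 * eta2[i] + zeta2[i, ]
    stat_ok <- abs(ar0) < 0.999
    m0 <- ifelse(stat_ok, mu_a / (1 - ar0), mu_a)
    v0 <- ifelse(stat_ok, params$sigma2_zeta1 / (1 - ar0^2), params$sigma2_zeta1)
    eta1[i, , 1] <- stats::rnorm(J, m0, sqrt(v0))
    for (t in 2:Tt) {
      P <- transition_matrix(params, eta1[i, , t - 1], eta2[i])
      S[i, t] <- sample(1:2, 1, prob = P[S[i, t - 1], ])
      mu <- structural_step(params, eta1[i, , t - 1], eta2[i], zeta2[i, ], S[i, t])
      eta1[i, , t] <- stats::rnorm(J, mu, sqrt(params$sigma2_zeta1))
    }
  }
  # measurement
  fac <- dims$item_map
  Y1 <- array(NA_real_, c(N1, dims$p, Tt))
  for (j in seq_len(dims$p)) {
    mu <- params$lambda1[j] * eta1[, fac[j], , drop = FALSE]
    Y1[, j, ] <- mu[, 1, ] + stats::rnorm(N1 * Tt, 0, sqrt(params$sigma2_eps1[j]))
  }
  if (missing_rate > 0) {
    drop_mask <- array(stats::runif(length(Y1)) < missing_rate, dim(Y1))
    Y1[drop_mask] <- NA_real_
  }
  Y2 <- sapply(seq_len(dims$q), function(j) {
    params$lambda2[j] * eta2 + stats::rnorm(N1, 0, sqrt(params$sigma2_eps2[j]))
  })
  Y2 <- matrix(Y2, N1, dims$q)

  panel <- tibble::tibble(
    person = rep(seq_len(N1), times = dims$p * Tt),
    item = rep(rep(seq_len(dims$p), each = N1), times = Tt),
    occasion = rep(seq_len(Tt), each = N1 * dims$p),
    value = as.vector(Y1)
  )
  panel <- dplyr::arrange(panel[!is.na(panel$value), c("person", "occasion", "item", "value")],
                          .data$person, .data$occasion, .data$item)
  between <- tibble::tibble(person = rep(seq_len(N1), dims$q),
                            item = rep(seq_len(dims$q), each = N1),
                            value = as.vector(Y2))
  truth <- tidyr::expand_grid(person = seq_len(N1), factor = seq_len(J),
                              occasion = seq_len(Tt))
  truth$eta1 <- eta1[cbind(truth$person, truth$factor, truth$occasion)]
  truth$S <- S[cbind(truth$person, truth$occasion)]
  truth <- dplyr::arrange(truth[, c("person", "occasion", "factor", "eta1", "S")],
                          .data$person, .data$occasion, .data$factor)
  structure(
    list(panel = panel, between = dplyr::arrange(between, .data$person, .data$item),
         truth = truth,
         dropout = tibble::tibble(person = integer(), dropout_occasion = integer()),
         latent = list(eta1 = eta1, eta2 = eta2, zeta2 = zeta2, S = S,
                       S_observed = matrix(FALSE, N1, Tt)),
         dims = dims, params = params, missing_rate = missing_rate, seed = seed),
    class = "rsdfm_sim"
  )
}

#' @export
print.rsdfm_sim <- function(x, ...) {
  d <- x$dims
  cat("<rsdfm_sim>", d$N1, "persons x", d$Nt + d$H, "occasions (",
      d$Nt, "observed +", d$H, "holdout ),", d$p, "items\n")
  cat("  state-2 share:", round(mean(x$latent$S == 2), 3),
      "| missing rate:", round(x$missing_rate, 3), "\n")
  invisible(x)
}

#' Mark manifest dropouts as observed state entries
#'
#' For persons whose simulated state path switches to state 2 and never
#' returns, marks the tail of the path -- from the start of that terminal
#' state-2 run (or a later designated occasion) onward -- as observed. The
#' fit then treats those entries as known rather than latent, mirroring a
#' recorded dropout event.
#'
#' @param sim An [simulate_panel()] result.
#' @param fraction Fraction of eligible persons (terminal state-2 run
#'   starting at occasion 2 or later inside the observation window) whose
#'   dropout is recorded; sampled without replacement.
#' @param delay Occasions between the start of the terminal state-2 run and
#'   the recorded manifest dropout.
#' @param seed Integer seed for the eligibility sample.
#' @return The `rsdfm_sim` object with `dropout` filled in and
#'   `latent$S_observed` set from each dropout occasion onward.
#' @export
inject_dropout <- function(sim, fraction = 1, delay = 0L, seed = 1L) {
  stopifnot(inherits(sim, "rsdfm_sim"), fraction >= 0, fraction <= 1)
  S <- sim$latent$S
  N1 <- nrow(S); Tt <- ncol(S); Nt <- sim$dims$Nt
  run_start <- rep(NA_integer_, N1)
  for (i in seq_len(N1)) {
    if (S[i, Tt] == 2L) {
      last1 <- max(which(S[i, ] == 1L))
      st <- last1 + 1L + as.integer(delay)
      if (st >= 2L && st <= Nt) run_start[i] <- st
    }
  }
  eligible <- which(!is.na(run_start))
  set.seed(seed)
  chosen <- sort(sample(eligible, size = round(fraction * length(eligible))))
  mask <- matrix(FALSE, N1, Tt)
  for (i in chosen) mask[i, run_start[i]:Tt] <- TRUE
  stopifnot(all(S[mask] == 2L))
  sim$dropout <- tibble::tibble(person = chosen,
                                dropout_occasion = run_start[chosen])
  sim$latent$S_observed <- mask
  sim
}

rep_seed <- function(master, k) {
  as.integer((as.numeric(master) + 7919 * as.numeric(k)) %% 2147483629)
}

#' Run a full simulation design to disk
#'
#' Generates one panel (plus truth) per condition and replication, with
#' per-replication parameter draws and seeds derived reproducibly from the
#' design's master seed, and writes everything as delimited text.
#'
#' @param design An [sim_design()] object.
#' @param out_dir Output directory (created if needed).
#' @param dropout_fraction Fraction of eligible dropouts recorded as
#'   observed state entries (see [inject_dropout()]); default 0.
#' @return The manifest tibble (also written to `manifest.tsv`): one row
#'   per replication with condition, seeds and file paths.
#' @export
run_design <- function(design, out_dir, dropout_fraction = 0) {
  stopifnot(inherits(design, "rsdfm_design"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0L
  for (ci in seq_len(nrow(design$conditions))) {
    N1 <- design$conditions$N1[ci]; Nt <- design$conditions$Nt[ci]
    dims <- rsdfm_dims(N1 = N1, Nt = Nt, H = design$H, J = design$J,
                       q = design$q, item_map = design$item_map)
    for (r in seq_len(design$R)) {
      k <- k + 1L
      seed_k <- rep_seed(design$seed, k)
      params <- draw_replication_params(dims, design$population, seed = seed_k)
      sim <- simulate_panel(params, dims, missing_rate = design$missing_rate,
                            seed = seed_k + 1L)
      if (dropout_fraction > 0) {
        sim <- inject_dropout(sim, fraction = dropout_fraction, seed = seed_k + 2L)
      }
      stub <- sprintf("c%02d_r%03d", ci, r)
      paths <- c(panel = file.path(out_dir, paste0(stub, "_panel.tsv")),
                 between = file.path(out_dir, paste0(stub, "_between.tsv")),
                 truth = file.path(out_dir, paste0(stub, "_truth.tsv")),
                 params = file.path(out_dir, paste0(stub, "_params.json")))
      write_panel(sim, paths["panel"], paths["between"])
      write_truth(sim, paths["truth"])
      params_to_json(params, paths["params"])
      rows[[k]] <- tibble::tibble(
        condition = ci, N1 = N1, Nt = Nt, H = design$H, replication = r,
        seed = seed_k,
        panel = unname(paths["panel"]), between = unname(paths["between"]),
        truth = unname(paths["truth"]), params = unname(paths["params"]))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Read and write long-format panels
#'
#' Panels are tab-separated text with header `person, occasion, item,
#' value`; missing responses are simply absent rows. The between-level
#' table has `person, item, value`; the truth file has `person, occasion,
#' factor, eta1, S`.
#'
#' @param sim An `rsdfm_sim` object.
#' @param panel_path,between_path,path Output file paths.
#' @return The input path(s), invisibly.
#' @export
write_panel <- function(sim, panel_path, between_path) {
  utils::write.table(sim$panel, panel_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$between, between_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(panel_path, between_path))
}

#' @rdname write_panel
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
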