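#' State-extraction sensitivity and specificity
#'
#' Cell-level confusion rates over person-occasion entries:
#' sensitivity is the fraction of true state-2 cells predicted as state 2,
#' specificity the fraction of true state-1 cells predicted as state 1.
#' The window restricts the occasions counted: `"observed"` uses occasions
#' `1..Nt`, `"forecast"` the occasions beyond `Nt`, `"overall"` all.
#'
#' @param true_S,pred_S Integer matrices (`N1 x T`, states in 1/2) on the
#'   same occasion grid.
#' @param window One of `"overall"`, `"observed"`, `"forecast"`.
#' @param Nt Number of observed occasions (forecast origin); required for
#'   the windowed variants.
#' @return A one-row tibble with `sensitivity` and `specificity` (`NA`
#'   where a window contains no cells of the corresponding true state).
#' @export
confusion_rates <- function(true_S, pred_S,
                            window = c("overall", "observed", "forecast"),
                            Nt = NULL) {
  window <- match.arg(window)
  true_S <- as.matrix(true_S); pred_S <- as.matrix(pred_S)
  if (!all(dim(true_S) == dim(pred_S))) {
    stop("`true_S` and `pred_S` must have identical dimensions", call. = FALSE)
  }
  if (window != "overall") {
    if (is.null(Nt)) stop("`Nt` is required for windowed rates", call. = FALSE)
    cols <- if (window == "observed") seq_len(Nt) else setdiff(seq_len(ncol(true_S)), seq_len(Nt))
    true_S <- true_S[, cols, drop = FALSE]
    pred_S <- pred_S[, cols, drop = FALSE]
  }
  pos <- true_S == 2L
  sens <- if (any(pos)) mean(pred_S[pos] == 2L) else NA_real_
  spec <- if (any(!pos)) mean(pred_S[!pos] == 1L) else NA_real_
  tibble::tibble(sensitivity = sens, specificity = spec)
}

#' Quadratic forecast score
#'
#' The sum of squared differences between forecast and true factor scores
#' across persons and factors at one forecast horizon.
#'
#' @param eta_hat,eta_true `N1 x J` matrices of forecast and true factor
#'   scores at the horizon.
#' @return A nonnegative scalar.
#' @export
score_function <- function(eta_hat, eta_true) {
  eta_hat <- as.matrix(eta_hat); eta_true <- as.matrix(eta_true)
  if (!all(dim(eta_hat) == dim(eta_true))) {
    stop("`eta_hat` and `eta_true` must have identical dimensions", call. = FALSE)
  }
  sum((eta_hat - eta_true)^2)
}

#' Forecast-interval coverage
#'
#' Fraction of cells whose true value lies inside its interval. Zero-width
#' intervals are counted as non-covering (with a warning).
#'
#' @param lower,upper,truth Equal-length numeric vectors.
#' @return Coverage rate in `[0, 1]`.
#' @export
interval_coverage <- function(lower, upper, truth) {
  stopifnot(length(lower) == length(upper), length(lower) == length(truth))
  zw <- upper <= lower
  if (any(zw)) warning(sum(zw), " zero-width interval(s) counted as non-covering")
  mean(!zw & truth >= lower & truth <= upper)
}

#' Evaluate one fitted replication against simulation truth
#'
#' Computes the full metric battery for a synthetic panel with known
#' latent truth: state-extraction sensitivity and specificity (overall,
#' observation window, forecast window), forecast-interval coverage at the
#' forecast's level, and the per-horizon quadratic score and mean
#' forecast-interval width.
#'
#' State predictions use the posterior state probabilities from the fit
#' over the observation window and the forecast state probabilities beyond
#' it, both thresholded at `threshold`.
#'
#' @param sim The [simulate_panel()] object that generated the data.
#' @param fit The [rsdfm_fit()] result on the observation window.
#' @param forecast The [rsdfm_forecast()] result (`H` horizons).
#' @param threshold State-2 classification threshold.
#' @return A one-row tibble with the rates, `coverage`, condition labels,
#'   and a nested `curves` tibble (`horizon`, `delta_h`, `fi_width`).
#' @export
evaluate_replication <- function(sim, fit, forecast, threshold = 0.5) {
  stopifnot(inherits(sim, "rsdfm_sim"), inherits(fit, "rsdfm_fit"),
            inherits(forecast, "rsdfm_forecast"))
  d <- fit$dims
  H <- attr(forecast, "H")
  Tt <- d$Nt + H
  true_S <- sim$latent$S[, seq_len(Tt), drop = FALSE]
  fs <- forecast_states(forecast, threshold)
  pred_fore <- matrix(1L, d$N1, H)
  pred_fore[cbind(fs$person, fs$horizon)] <- fs$S_hat
  pred_obs <- matrix(classify_states(as.vector(fit$pstate2), threshold),
                     d$N1, d$Nt)
  pred_S <- cbind(pred_obs, pred_fore)
  rates <- dplyr::bind_cols(
    dplyr::rename_with(confusion_rates(true_S, pred_S, "overall"),
                       ~ paste0(.x, "_overall")),
    dplyr::rename_with(confusion_rates(true_S, pred_S, "observed", Nt = d$Nt),
                       ~ paste0(.x, "_observed")),
    dplyr::rename_with(confusion_rates(true_S, pred_S, "forecast", Nt = d$Nt),
                       ~ paste0(.x, "_forecast")))
  # truth at forecast horizons, aligned with the forecast tibble
  fc <- tibble::as_tibble(forecast)
  truth_cells <- sim$latent$eta1[cbind(fc$person, fc$factor, d$Nt + fc$horizon)]
  coverage <- interval_coverage(fc$lower, fc$upper, truth_cells)
  curves <- fc |>
    dplyr::mutate(truth = truth_cells, width = .data$upper - .data$lower,
                  sqerr = (.data$mean - .data$truth)^2) |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(delta_h = sum(.data$sqerr),
                     fi_width = mean(.data$width), .groups = "drop")
  dplyr::bind_cols(
    tibble::tibble(N1 = d$N1, Nt = d$Nt),
    rates,
    tibble::tibble(coverage = coverage, curves = list(curves)))
}

#' Aggregate replication reports into a condition summary
#'
#' Means of every metric by condition, in the layout of a
#' sensitivity/specificity/coverage table, plus the per-horizon score and
#' interval-width series for megaphone-style plots.
#'
#' @param reports Row-bound [evaluate_replication()] results.
#' @return A list: `table` (one row per condition) and `curves`
#'   (per-condition, per-horizon means of `delta_h` and `fi_width`).
#' @export
aggregate_table <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  tab <- reports |>
    dplyr::group_by(.data$N1, .data$Nt) |>
    dplyr::summarise(dplyr::across(
      c(dplyr::starts_with("sensitivity"), dplyr::starts_with("specificity"),
        "coverage"),
      ~ mean(.x, na.rm = TRUE)), n_replications = dplyr::n(),
      .groups = "drop")
  curves <- reports |>
    dplyr::select("N1", "Nt", "curves") |>
    tidyr::unnest("curves") |>
    dplyr::group_by(.data$N1, .data$Nt, .data$horizon) |>
    dplyr::summarise(delta_h = mean(.data$delta_h),
                     fi_width = mean(.data$fi_width), .groups = "drop")
  list(table = tab, curves = curves)
}

#' Run a full simulation study
#'
#' For every condition and replication: draw generating parameters from
#' the population table, simulate a panel, fit the model on the
#' observation window, forecast the holdout horizons, and evaluate. All
#' seeds derive reproducibly from the design's master seed.
#'
#' @param design An [sim_design()] object.
#' @param config An [mcmc_config()] template; the per-replication seed is
#'   derived from the design seed.
#' @param dropout_fraction Fraction of eligible simulated dropouts recorded
#'   as observed state entries (see [inject_dropout()]).
#' @param threshold State-2 classification threshold.
#' @param level Forecast-interval level.
#' @param aggregate_factors Passed to [rsdfm_forecast()].
#' @param out_dir Optional directory: per-replication reports are written
#'   as delimited text and finished replications are skipped on re-run.
#' @param verbose Print progress lines.
#' @return A list with `reports` (one row per replication) and `summary`
#'   (the [aggregate_table()] of the reports).
#' @export
run_simulation_study <- function(design, config = mcmc_config(),
                                 dropout_fraction = 0, threshold = 0.5,
                                 level = 0.95, aggregate_factors = TRUE,
                                 out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "rsdfm_design"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  k <- 0L
  for (ci in seq_len(nrow(design$conditions))) {
    N1 <- design$conditions$N1[ci]; Nt <- design$conditions$Nt[ci]
    dims <- rsdfm_dims(N1 = N1, Nt = Nt, H = design$H, J = design$J,
                       q = design$q, item_map = design$item_map)
    for (r in seq_len(design$R)) {
      k <- k + 1L
      stub <- sprintf("c%02d_r%03d", ci, r)
      cache <- if (is.null(out_dir)) NULL else file.path(out_dir, paste0(stub, "_report.tsv"))
      if (!is.null(cache) && file.exists(cache)) {
        reports[[k]] <- read_report(cache)
        next
      }
      seed_k <- rep_seed(design$seed, k)
      rep_result <- tryCatch({
        params <- draw_replication_params(dims, design$population, seed = seed_k)
        sim <- simulate_panel(params, dims, missing_rate = design$missing_rate,
                              seed = seed_k + 1L)
        if (dropout_fraction > 0) {
          sim <- inject_dropout(sim, fraction = dropout_fraction, seed = seed_k + 2L)
        }
        cfg <- config
        cfg$seed <- seed_k + 3L
        fit <- rsdfm_fit(sim$panel, sim$between, dims, dropout = sim$dropout,
                         config = cfg)
        fc <- rsdfm_forecast(fit, H = design$H, level = level,
                             aggregate_factors = aggregate_factors,
                             seed = seed_k + 4L)
        rep <- evaluate_replication(sim, fit, fc, threshold = threshold)
        rep$replication <- r
        rep$seed <- seed_k
        rep$max_rhat <- suppressWarnings(max(fit$rhat$rhat, na.rm = TRUE))
        rep
      }, error = function(e) {
        warning(sprintf("replication %s failed: %s", stub, conditionMessage(e)))
        NULL
      })
      if (is.null(rep_result)) next
      reports[[k]] <- rep_result
      if (!is.null(cache)) write_report(rep_result, cache)
      if (verbose) {
        message(sprintf("[%s] N1=%d Nt=%d rep=%d sens=%.3f spec_obs=%.3f cov=%.3f",
                        stub, N1, Nt, r, rep_result$sensitivity_overall,
                        rep_result$specificity_observed, rep_result$coverage))
      }
    }
  }
  reports <- dplyr::bind_rows(reports)
  if (nrow(reports) == 0) stop("every replication failed", call. = FALSE)
  list(reports = reports, summary = aggregate_table(reports))
}

write_report <- function(report, path) {
  flat <- report |> dplyr::select(-"curves")
  utils::write.table(flat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(tidyr::unnest(report[, c("N1", "Nt", "curves")], "curves"),
                     sub("_report\\.tsv$", "_curves.tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_report <- function(path) {
  flat <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  cur <- tibble::as_tibble(utils::read.table(sub("_report\\.tsv$", "_curves.tsv", path),
                                             header = TRUE, sep = "\t"))
  flat$curves <- list(cur[, c("horizon", "delta_h", "fi_width")])
  flat
}
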