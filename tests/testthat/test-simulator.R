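test_that("replication parameter draws respect the population and support", {
  d <- rsdfm_dims(N1 = 10, Nt = 10)
  pop <- default_population()
  # zero population spread returns the means exactly
  pop0 <- pop; pop0$sd <- 0
  p <- draw_replication_params(d, pop0, seed = 1)
  expect_equal(unname(p$b1), rep(pop$mean[pop$parameter == "b1"], 3),
               ignore_attr = TRUE)
  expect_equal(unname(p$delta_alpha21),
               rep(pop$mean[pop$parameter == "delta_alpha21"], 3),
               ignore_attr = TRUE)
  expect_equal(p$lambda1[d$scaling_items], rep(1, 3))
  # determinism
  expect_identical(params_flatten(draw_replication_params(d, seed = 5)),
                   params_flatten(draw_replication_params(d, seed = 5)))
  # support constraints always hold
  for (k in 1:25) {
    pk <- draw_replication_params(d, seed = 100 + k)
    expect_true(all(pk$delta_alpha21 >= 0))
    expect_true(pk$p12 >= 0 && pk$p12 <= 0.1)
    expect_true(all(pk$lambda1 > 0) && all(pk$sigma2_zeta1 > 0))
  }
  # Monte-Carlo check on an unconstrained parameter over 500 draws
  b1s <- vapply(1:500, function(k) draw_replication_params(d, seed = k)$b1[1], 0)
  mu <- pop$mean[pop$parameter == "b1"]; s <- pop$sd[pop$parameter == "b1"]
  expect_lt(abs(mean(b1s) - mu), 3 * s / sqrt(500))
  # impossible support triggers the rejection-cap error
  pop_bad <- pop
  pop_bad$mean[pop_bad$parameter == "p12"] <- 10
  pop_bad$sd[pop_bad$parameter == "p12"] <- 1e-6
  expect_error(draw_replication_params(d, pop_bad, seed = 1), "1000 consecutive")
})

test_that("simulated panels follow the generative model", {
  d <- rsdfm_dims(N1 = 30, Nt = 20, H = 5)
  p <- example_params(d)
  # near-noiseless identity measurement reproduces the factor scores
  d1 <- rsdfm_dims(N1 = 10, Nt = 10, H = 2, J = 3, item_map = 1:3)
  p1 <- example_params(d1)
  p1$lambda1 <- rep(1, 3)
  p1$sigma2_eps1 <- rep(1e-12, 3)
  sim1 <- simulate_panel(p1, d1, seed = 4)
  wide <- tidyr::pivot_wider(sim1$panel, names_from = "item", values_from = "value")
  tr <- tidyr::pivot_wider(sim1$truth[, c("person", "occasion", "factor", "eta1")],
                           names_from = "factor", values_from = "eta1")
  expect_equal(as.matrix(wide[, c("1", "2", "3")]),
               as.matrix(tr[, c("1", "2", "3")]), tolerance = 1e-5,
               ignore_attr = TRUE)
  # saturated stay logit keeps every person in state 1
  p2 <- example_params(d)
  p2$gamma1 <- 20; p2$gamma3 <- rep(0, 3); p2$gamma4 <- rep(0, 3); p2$p12 <- 0
  sim2 <- simulate_panel(p2, d, seed = 5)
  expect_true(all(sim2$latent$S == 1L))
  # states start at 1 and missingness is absent by default
  sim <- simulate_panel(p, d, seed = 6)
  expect_true(all(sim$latent$S[, 1] == 1L))
  expect_equal(nrow(sim$panel), d$N1 * d$p * (d$Nt + d$H))
})

test_that("factor dynamics match AR(1) theory when no switching occurs", {
  d <- rsdfm_dims(N1 = 200, Nt = 50, H = 0, J = 3)
  p <- example_params(d)
  p$gamma1 <- 20; p$gamma3 <- rep(0, 3); p$gamma4 <- rep(0, 3); p$p12 <- 0
  p$b1 <- rep(0.5, 3); p$delta_b1 <- rep(0, 3)
  p$omega2 <- rep(0, 3); p$delta_omega2 <- rep(0, 3)
  p$beta2 <- rep(0, 3); p$delta_beta2 <- rep(0, 3)
  p$sigma2_zeta2 <- rep(1e-12, 3)  # no person-level offsets
  sim <- simulate_panel(p, d, seed = 8)
  e <- sim$latent$eta1
  # lag-1 autocorrelation near the AR coefficient
  x <- as.vector(e[, , -dim(e)[3]]); y <- as.vector(e[, , -1])
  expect_lt(abs(stats::cor(x, y) - 0.5), 0.05)
  # long-run variance near sigma2_zeta1 / (1 - b^2) = 0.6 (Monte-Carlo
  # tolerance sized for ~200 effectively independent person trajectories)
  expect_lt(abs(stats::var(as.vector(e[, 1, ])) - 0.45 / (1 - 0.25)), 0.1)
})

test_that("missingness is MCAR at the requested rate", {
  d <- rsdfm_dims(N1 = 40, Nt = 30, H = 0)
  p <- example_params(d)
  sim <- simulate_panel(p, d, missing_rate = 0.3, seed = 9)
  n_total <- d$N1 * d$p * d$Nt
  n_obs <- nrow(sim$panel)
  rate <- 1 - n_obs / n_total
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / n_total))
})

test_that("dropout injection marks exactly the terminal elevated-state tail", {
  d <- rsdfm_dims(N1 = 40, Nt = 25, H = 5)
  p <- example_params(d)
  p$gamma1 <- 1.5  # frequent switching
  sim <- simulate_panel(p, d, seed = 10)
  out <- inject_dropout(sim, fraction = 1, seed = 11)
  mask <- out$latent$S_observed
  # masked entries are all state 2 and contiguous to the end
  expect_true(all(out$latent$S[mask] == 2L))
  for (r in seq_len(nrow(out$dropout))) {
    i <- out$dropout$person[r]; t0 <- out$dropout$dropout_occasion[r]
    expect_true(all(mask[i, t0:ncol(mask)]))
    expect_false(any(mask[i, seq_len(t0 - 1)]))
    expect_gte(t0, 2)
  }
  # persons never in state 2 are never masked
  never <- which(rowSums(out$latent$S == 2L) == 0)
  expect_true(all(!mask[never, ]))
  # fraction 0 marks nobody
  out0 <- inject_dropout(sim, fraction = 0, seed = 11)
  expect_identical(nrow(out0$dropout), 0L)
})

test_that("a written design is reproducible and carries the holdout block", {
  design <- sim_design(conditions = data.frame(N1 = 6, Nt = 8), H = 3, R = 2,
                       seed = 21)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  man1 <- run_design(design, dir1)
  man2 <- run_design(design, dir2)
  expect_equal(nrow(man1), 2)
  expect_true(all(file.exists(man1$panel, man1$truth, man1$between, man1$params)))
  # byte-identical regeneration from the same master seed
  for (f in c("panel", "truth", "between", "params")) {
    expect_identical(readLines(man1[[f]][1]), readLines(man2[[f]][1]))
  }
  # panels span Nt + H occasions; the fit window is the first Nt
  panel <- read_panel(man1$panel[1])
  expect_equal(max(panel$occasion), 8 + 3)
  expect_equal(man1$Nt[1], 8)
  expect_equal(man1$H[1], 3)
})
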