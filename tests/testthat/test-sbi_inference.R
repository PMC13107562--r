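# Neural posterior estimation: prior sampling, training-set construction,
# flow training, posterior sampling, collective posteriors and predictive
# checks. The trained estimator is shared across blocks (helper-npe.R).

test_that("log-uniform prior sampling matches its closed-form median", {
  pr <- prior_spec(s = c(1e-5, 1e-1), delta = c(1e-5, 1e-1),
                   phi = c(1e-5, 1e-1), n_loci = 1)
  th <- sample_prior(pr, 1e5, seed = 1)
  expect_true(all(th >= 1e-5 & th <= 1e-1))
  # median of a log-uniform is the geometric mean of the bounds
  expect_equal(unname(apply(th, 2, median)), rep(1e-3, 3),
               tolerance = 0.05)
  expect_error(prior_spec(s = c(0, 1)), "0 < lo < hi")
  expect_error(prior_spec(delta = c(1e-2, 1e-3)), "0 < lo < hi")
  # near-degenerate prior collapses to its bounds
  tiny <- prior_spec(s = c(0.1, 0.1 * (1 + 1e-12)),
                     delta = c(1e-4, 1e-4 * (1 + 1e-12)),
                     phi = c(1e-3, 1e-3 * (1 + 1e-12)), n_loci = 1)
  thd <- sample_prior(tiny, 100, seed = 2)
  expect_equal(unname(colMeans(thd)), c(0.1, 1e-4, 1e-3), tolerance = 1e-9)
})

test_that("training sets record simulations with the stated noise model", {
  pr <- prior_spec(n_loci = 2)
  cfg <- pop_config(N = Inf, T_gen = 220)
  # zero noise: noisy equals clean
  ts0 <- build_training_set(pr, cfg, n = 50, noise_sigma = 0, seed = 3)
  expect_identical(ts0$x_noisy, ts0$x)
  expect_equal(nrow(ts0$theta), 50L)
  expect_equal(ncol(ts0$x), 2L * length(cfg$sample_gens))
  # the added noise is N(0, 0.02): SD within 5%, normality not rejected
  ts <- build_training_set(pr, cfg, n = 10000, noise_sigma = 0.02, seed = 4)
  eps <- as.numeric(ts$x_noisy - ts$x)
  expect_equal(sd(eps), 0.02, tolerance = 0.05)
  expect_gt(shapiro.test(sample(eps, 5000))$p.value, 0.01)
  # all prior draws inside the box
  expect_true(all(ts$theta >= matrix(pr$lo, 10000, 6, byrow = TRUE) &
                    ts$theta <= matrix(pr$hi, 10000, 6, byrow = TRUE)))
})

test_that("fitness transforms follow w = 1/(1+s) and multiplicative combination", {
  expect_equal(fitness_transforms(0)$w_G, 1)
  expect_equal(fitness_transforms(0.0846)$w_G, 0.922, tolerance = 1e-3)
  ft <- fitness_transforms(0.02, 0.05)
  expect_equal(ft$s_GM, 0.071, tolerance = 1e-6 / 0.071)
  expect_equal(ft$w_strain, 1 / 1.071)
  expect_error(fitness_transforms(-1.2), "-1")
})

test_that("flow training reduces held-out loss and is deterministic", {
  est <- shared_npe()
  expect_true(all(est$training$best_val_nll < est$training$init_val_nll))
  # determinism contract on a miniature run
  ts <- shared_training_set()
  small <- list(n_ensemble = 1L, max_epochs = 5L, patience = 5L,
                hidden = 10L, n_transforms = 2L)
  e1 <- train_npe(ts, flow_config = small, seed = 99)
  e2 <- train_npe(ts, flow_config = small, seed = 99)
  expect_identical(e1$training$best_val_nll, e2$training$best_val_nll)
  # too-small training sets are refused with a minimum-n message
  pr <- prior_spec(n_loci = 2)
  cfg <- pop_config(N = Inf, T_gen = 220)
  tiny <- build_training_set(pr, cfg, n = 30, seed = 5)
  expect_error(train_npe(tiny), "at least")
})

test_that("posterior samples stay in the prior box and recover known truths", {
  est <- shared_npe()
  truth <- c(sG = 0.08, deltaG = 1e-4, phiG = 1e-5,
             sM = 0.08, deltaM = 1e-4, phiM = 1e-5)
  set.seed(7)
  obs <- simulate_observation(truth, est$config, est$noise_sigma)
  ps <- posterior_sample(est, obs, m = 2000, seed = 7)
  expect_true(all(ps$theta >= matrix(est$lo, 2000, 6, byrow = TRUE) &
                    ps$theta <= matrix(est$hi, 2000, 6, byrow = TRUE)))
  # selection coefficient within +/- 0.04; reversion rate within one
  # order of magnitude
  expect_lt(abs(ps$point[["sG"]] - 0.08), 0.04)
  expect_lt(abs(ps$point[["sM"]] - 0.08), 0.04)
  expect_lt(abs(log10(ps$point[["deltaG"]]) - log10(1e-4)), 1)
  expect_lt(abs(log10(ps$point[["deltaM"]]) - log10(1e-4)), 1)
  # the truth is not in the tail: its log-density beats the bulk of prior
  # draws under the same posterior
  lp_truth <- posterior_log_density(est, obs, matrix(truth, 1))
  lp_prior <- posterior_log_density(est, obs, sample_prior(est$prior, 200,
                                                           seed = 8))
  expect_gt(lp_truth, quantile(lp_prior, 0.05))
  expect_error(posterior_sample(est, obs[-1], m = 10), "does not match")
})

test_that("posterior medians rank-correlate with truth across a grid", {
  est <- shared_npe()
  grid <- expand.grid(s = c(0.02, 0.08, 0.2), delta = c(1e-5, 1e-4, 1e-3))
  set.seed(9)
  med <- t(apply(grid, 1, function(g) {
    th <- c(g[["s"]], g[["delta"]], 1e-4, g[["s"]], g[["delta"]], 1e-4)
    obs <- simulate_observation(th, est$config, est$noise_sigma)
    posterior_sample(est, obs, m = 500)$point[c("sG", "deltaG")]
  }))
  expect_gte(cor(grid$s, med[, 1], method = "spearman"), 0.8)
  expect_gte(cor(grid$delta, med[, 2], method = "spearman"), 0.8)
})

test_that("a single-replicate collective posterior equals the individual one", {
  est <- shared_npe()
  set.seed(10)
  obs <- simulate_observation(c(0.05, 1e-4, 1e-4, 0.05, 1e-4, 1e-4),
                              est$config, est$noise_sigma)
  ind <- posterior_sample(est, obs, m = 5000, seed = 11)
  col <- collective_posterior(est, list(obs), m = 5000, seed = 12)
  expect_equal(col$provenance, "collective")
  for (j in seq_len(6)) {
    ks <- suppressWarnings(
      ks.test(log(ind$theta[, j]), log(col$theta[, j])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the collective sampler matches a conjugate Gaussian oracle", {
  # stand-in posterior with known algebra: flat prior, x_i ~ N(theta, 1),
  # individual posterior N(x_i, 1); the collective across n replicates
  # must be N(mean(x), 1/n)
  gp <- structure(list(sigma = 1), class = "gauss_post")
  assign("posterior_sample.gauss_post",
         function(est, obs, m = 1000, ...) {
           structure(list(theta = matrix(rnorm(m, obs, est$sigma), m, 1),
                          point = obs, provenance = "individual"),
                     class = "posterior_samples")
         }, envir = globalenv())
  assign("posterior_log_density.gauss_post",
         function(est, obs, theta, ...) {
           dnorm(theta[, 1], obs, est$sigma, log = TRUE)
         }, envir = globalenv())
  on.exit({
    rm("posterior_sample.gauss_post", envir = globalenv())
    rm("posterior_log_density.gauss_post", envir = globalenv())
  })
  set.seed(13)
  xs <- rnorm(5, 2, 1)
  col <- collective_posterior(gp, as.list(xs), m = 20000, seed = 14)
  expect_equal(mean(col$theta), mean(xs), tolerance = 0.02)
  expect_equal(var(col$theta[, 1]), 1 / 5, tolerance = 0.1)
  expect_gt(col$ess, 50)
})

test_that("replicates sharpen the collective posterior", {
  est <- shared_npe()
  truth <- c(0.08, 1e-4, 1e-5, 0.08, 1e-4, 1e-5)
  set.seed(15)
  obs4 <- lapply(1:4, function(i)
    simulate_observation(truth, est$config, est$noise_sigma))
  ind <- posterior_sample(est, obs4[[1]], m = 2000, seed = 16)
  col <- collective_posterior(est, obs4, m = 2000, seed = 17)
  iqr_ind <- apply(log(ind$theta), 2, IQR)
  iqr_col <- apply(log(col$theta), 2, IQR)
  expect_true(all(iqr_col <= iqr_ind * 1.05))
})

test_that("posterior predictive checks report envelope, coverage and RMSE", {
  est <- shared_npe()
  truth <- c(0.08, 1e-4, 1e-5, 0.08, 1e-4, 1e-5)
  set.seed(18)
  obs <- simulate_observation(truth, est$config, est$noise_sigma)
  ps <- posterior_sample(est, obs, m = 500, seed = 19)
  ppc <- posterior_predictive_check(ps, obs, est$config, n_draws = 100,
                                    noise_sigma = est$noise_sigma, seed = 20)
  expect_equal(nrow(ppc$sims), 100L)
  expect_gte(ppc$coverage, 0.8)
  # degenerate check: deterministic simulator, zero noise, observation
  # equal to the simulation at a single parameter set => RMSE 0
  cfg_det <- pop_config(N = Inf, T_gen = 220)
  point <- matrix(truth, 10, 6, byrow = TRUE)
  obs_det <- cnvrevert:::.simulate_theta_matrix(point[1, , drop = FALSE],
                                                cfg_det)
  ppc0 <- posterior_predictive_check(point, as.numeric(obs_det), cfg_det,
                                     n_draws = 10, noise_sigma = 0)
  expect_lt(ppc0$rmse, 1e-9)
  expect_equal(ppc0$coverage, 1)
})

test_that("training-set serialization writes data plus provenance sidecar", {
  pr <- prior_spec(n_loci = 1)
  cfg <- pop_config(N = Inf, T_gen = 24, sample_gens = c(0, 12, 24))
  ts <- build_training_set(pr, cfg, n = 20, seed = 21)
  stem <- tempfile()
  write_training_set(ts, stem)
  tab <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(tab), 20L)
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(meta$noise_sigma, 0.02)
  expect_equal(unlist(meta$sample_gens), c(0, 12, 24))
})
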