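# Wright-Fisher reversion model: single-step arithmetic, absorbing states,
# agreement between the stochastic simulator and the deterministic
# (infinite-N) recursion, the joint two-locus genotype model, and
# fixation-time summaries.

test_that("parameter and configuration constructors validate their inputs", {
  expect_error(reversion_params(s = -0.1), "s")
  expect_error(reversion_params(delta = 1), "delta")
  expect_error(reversion_params(phi = -1e-9), "phi")
  expect_error(pop_config(sample_gens = c(0, 12, 12)), "increasing")
  expect_error(pop_config(T_gen = 100, sample_gens = c(0, 120)), "within")
  expect_error(epistasis_spec(-1), "1 \\+ e")
  expect_equal(generations_per_cycle(64), 6)
})

test_that("one Wright-Fisher step applies reversion then selection then drift", {
  # absorbing boundaries, any parameters
  p_any <- reversion_params(s = 0.2, delta = 0, phi = 0)
  expect_equal(wf_step_locus(0, p_any, N = Inf), 0)
  expect_equal(wf_step_locus(1, p_any, N = Inf), 1)
  set.seed(1)
  expect_equal(wf_step_locus(1, reversion_params(0.3, 0.01, 0), N = 100), 1)
  # hand-evaluated deterministic update:
  # p_mut = 0.1 + 0.9e-4 = 0.10009; p_sel = 0.110099 / 1.010009
  expect_equal(wf_step_locus(0.1, reversion_params(0.1, 1e-4, 0), N = Inf),
               0.109008, tolerance = 1e-6 / 0.109008)
  expect_error(wf_step_locus(1.2, p_any, N = Inf), "\\[0, 1\\]")
  expect_error(wf_step_locus(0.5, p_any, N = 0.5), "N")
})

test_that("deterministic trajectory matches closed forms and is monotone", {
  # s = 0, delta = 0: frequency frozen at phi
  d0 <- deterministic_trajectory(reversion_params(0, 0, 0.3), 10)
  expect_equal(d0$revertant_freq, rep(0.3, 11))
  # s = 0: pure geometric decay of the CNV class, 1 - (1-phi)(1-delta)^t
  d1 <- deterministic_trajectory(reversion_params(0, 0.1, 0), 2)
  expect_equal(d1$revertant_freq[3], 0.19)
  expect_equal(d1$cnv_freq[3], 0.81)
  # revertant frequency is non-decreasing whenever s, delta >= 0
  set.seed(42)
  for (i in 1:20) {
    pr <- reversion_params(s = runif(1, 0, 0.3), delta = runif(1, 0, 0.05),
                           phi = runif(1, 0, 0.5))
    expect_true(all(diff(deterministic_trajectory(pr, 100)$revertant_freq)
                    >= -1e-15))
  }
})

test_that("simulate_locus reports CNV frequency at the sampled generations", {
  cfg <- pop_config(N = Inf, T_gen = 24, sample_gens = seq(0, 24, 6))
  # no reversion possible: CNV fixed at 1
  tr <- simulate_locus(reversion_params(0.5, 0, 0), cfg)
  expect_equal(tr$cnv_freq, rep(1, 5))
  expect_equal(tr$generation, seq(0, 24, 6))
  # identical seed => identical stochastic output
  cfgN <- pop_config(N = 1e4, T_gen = 24, sample_gens = seq(0, 24, 6))
  pr <- reversion_params(0.1, 1e-3, 1e-3)
  expect_identical(simulate_locus(pr, cfgN, seed = 5),
                   simulate_locus(pr, cfgN, seed = 5))
})

test_that("stochastic mean trajectory converges to the deterministic oracle", {
  # 1000 replicates at N = 1e6 vs the infinite-N recursion, all sampled
  # generations of a 220-generation experiment, within 3 standard errors
  pr <- reversion_params(s = 0.08, delta = 1e-4, phi = 1e-5)
  cfg <- pop_config(N = 1e6, T_gen = 220)
  set.seed(99)
  xs <- cnvrevert:::.simulate_locus_many(1000, pr, cfg)
  oracle <- deterministic_trajectory(pr, 220)
  expect_rev <- oracle$revertant_freq[cfg$sample_gens + 1]
  se <- apply(xs, 2, sd) / sqrt(nrow(xs))
  dev <- abs(colMeans(xs) - expect_rev)
  expect_true(all(dev <= pmax(3 * se, 1e-12)))
})

test_that("two-locus model factorizes without epistasis and conserves mass", {
  cfg <- pop_config(N = Inf, T_gen = 220)
  pG <- reversion_params(0.05, 1e-4, 1e-4)
  pM <- reversion_params(0.10, 1e-3, 1e-4)
  # e = 0 joint genotype model equals independent single-locus chains
  joint <- simulate_strain_two_locus(pG, pM, cfg, epistasis = epistasis_spec(0),
                                     keep_genotypes = TRUE)
  indG <- simulate_locus(pG, cfg)
  indM <- simulate_locus(pM, cfg)
  expect_equal(joint$cnv_freq[joint$locus == "G"], indG$cnv_freq,
               tolerance = 1e-9)
  expect_equal(joint$cnv_freq[joint$locus == "M"], indM$cnv_freq,
               tolerance = 1e-9)
  # genotype frequencies sum to one at every sampled generation
  geno <- attr(joint, "genotypes")
  expect_true(all(abs(rowSums(geno) - 1) < 1e-12))
  # locked M locus stays at CNV frequency 1 while G evolves
  lock <- simulate_strain_two_locus(pG, reversion_params(0.2, 0, 0), cfg)
  expect_equal(lock$cnv_freq[lock$locus == "M"],
               rep(1, length(cfg$sample_gens)))
  expect_lt(min(lock$cnv_freq[lock$locus == "G"]), 1)
  # stochastic joint model also conserves mass
  cfgN <- pop_config(N = 1e4, T_gen = 220)
  st <- simulate_strain_two_locus(pG, pM, cfgN, epistasis = epistasis_spec(0.1),
                                  seed = 3, keep_genotypes = TRUE)
  expect_true(all(abs(rowSums(attr(st, "genotypes")) - 1) < 1e-12))
})

test_that("epistasis shifts the double-revertant genotype as specified", {
  cfg <- pop_config(N = Inf, T_gen = 100, sample_gens = c(0, 100))
  pG <- reversion_params(0.05, 1e-3, 1e-3)
  pM <- reversion_params(0.05, 1e-3, 1e-3)
  g0 <- attr(simulate_strain_two_locus(pG, pM, cfg, epistasis_spec(0),
                                       keep_genotypes = TRUE), "genotypes")
  gpos <- attr(simulate_strain_two_locus(pG, pM, cfg, epistasis_spec(0.5),
                                         keep_genotypes = TRUE), "genotypes")
  expect_gt(gpos[2, "G1M1"], g0[2, "G1M1"])
})

test_that("fixation times match the geometric closed form and handle censoring", {
  expect_error(fixation_generations(reversion_params(0.1, 0, 0)),
               "unreachable")
  # already above threshold
  hit0 <- fixation_generations(reversion_params(0, 1e-3, 0.999), N = Inf,
                               fix_threshold = 0.5)
  expect_equal(hit0$mean, 0)
  # s = 0 deterministic: crossing at ceil(log(0.01 / (1 - phi)) / log(1 - delta))
  delta <- 2e-3; phi <- 0.05
  fx <- fixation_generations(reversion_params(0, delta, phi), N = Inf,
                             fix_threshold = 0.99)
  expect_equal(fx$mean, ceiling(log(0.01 / (1 - phi)) / log(1 - delta)))
  expect_equal(fx$n_censored, 0)
  # generation cap censors replicates that cannot cross in time
  cen <- fixation_generations(reversion_params(0, 1e-5, 0), N = 1000,
                              fix_threshold = 0.99, reps = 5, max_gens = 50,
                              seed = 1)
  expect_equal(cen$n_censored, 5)
})

test_that("trajectory CSV round-trips", {
  df <- data.frame(strain = "G_4", population = "G_4_rep1", locus = "G",
                   generation = c(0, 12), cnv_freq = c(1, 0.97))
  path <- tempfile(fileext = ".csv")
  write_trajectories(df, path)
  back <- read_trajectories(path)
  expect_equal(back$cnv_freq, df$cnv_freq)
  expect_equal(back$strain, df$strain)
  expect_error(write_trajectories(df[, -1], path), "missing")
})
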