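# Shared trained posterior estimator, built once per test run and reused by
# the inference unit tests and the calibration checks. Training conditions
# mirror the study design: 220-generation two-locus Wright-Fisher
# simulations at the serial-transfer bottleneck size, observed every 12
# generations with N(0, 0.02) observation noise; the training set is 2,000
# simulations.
.npe_cache <- new.env(parent = emptyenv())

shared_npe <- function() {
  if (is.null(.npe_cache$est)) {
    prior <- prior_spec(n_loci = 2)
    cfg <- pop_config(N = 3e5, T_gen = 220)
    set.seed(20260401)
    ts <- build_training_set(prior, cfg, n = 2000, noise_sigma = 0.02)
    .npe_cache$ts <- ts
    .npe_cache$est <- train_npe(ts, seed = 20260401)
  }
  .npe_cache$est
}

shared_training_set <- function() {
  shared_npe()
  .npe_cache$ts
}

# Noisy observation simulated at a known parameter vector.
simulate_observation <- function(theta, config, noise_sigma = 0.02) {
  x <- cnvrevert:::.simulate_theta_matrix(matrix(theta, 1L), config)
  as.numeric(x) + stats::rnorm(length(x), 0, noise_sigma)
}
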