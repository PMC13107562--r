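# Log-uniform priors over the reversion parameters and the simulated
# training sets used for neural posterior estimation.

#' Log-uniform prior over reversion parameters
#'
#' Each parameter is sampled as `exp(Uniform(log lo, log hi))`. For a
#' two-locus strain the parameter vector is
#' `(sG, deltaG, phiG, sM, deltaM, phiM)`; for a single tracked locus it is
#' `(s, delta, phi)`. Default bounds bracket the reversion-rate and
#' selection estimates reported for nitrogen-transporter CNVs
#' (`delta` between 1e-5 and 1e-3 per cell per generation, `s` up to ~0.085).
#'
#' @param s Bounds `(lo, hi)` for the selection coefficient.
#' @param delta Bounds for the reversion rate.
#' @param phi Bounds for the initial revertant frequency.
#' @param n_loci 1 or 2 tracked loci.
#' @return An object of class `prior_spec` with fields `lo`, `hi` (named
#'   per-parameter bound vectors) and `n_loci`.
#' @export
prior_spec <- function(s = c(1e-3, 0.3), delta = c(1e-7, 1e-2),
                       phi = c(1e-7, 1e-1), n_loci = 2) {
  chk <- function(b, nm) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("invalid bounds for ", nm, ": need 0 < lo < hi")
  }
  chk(s, "s"); chk(delta, "delta"); chk(phi, "phi")
  stopifnot(n_loci %in% c(1L, 2L))
  base <- c(s = s[1], delta = delta[1], phi = phi[1])
  hi <- c(s = s[2], delta = delta[2], phi = phi[2])
  if (n_loci == 2L) {
    lo <- c(base, base)
    hi <- c(hi, hi)
    names(lo) <- names(hi) <-
      c("sG", "deltaG", "phiG", "sM", "deltaM", "phiM")
  } else {
    lo <- base
    names(lo) <- names(hi) <- c("s", "delta", "phi")
  }
  structure(list(lo = lo, hi = hi, n_loci = as.integer(n_loci)),
            class = "prior_spec")
}

#' Draw parameter vectors from a log-uniform prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return An `n x d` matrix with named columns, rows within the prior box.
#' @examples
#' th <- sample_prior(prior_spec(n_loci = 1), 5, seed = 1)
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- length(prior$lo)
  u <- matrix(stats::runif(n * d), n, d)
  th <- exp(sweep(sweep(u, 2L, log(prior$hi / prior$lo), `*`),
                  2L, log(prior$lo), `+`))
  colnames(th) <- names(prior$lo)
  th
}

# Rows of `theta` -> reversion_params per locus; used by the simulators.
.theta_rows_to_params <- function(theta_row, n_loci) {
  if (n_loci == 2L) {
    list(G = reversion_params(theta_row[1], theta_row[2], theta_row[3]),
         M = reversion_params(theta_row[4], theta_row[5], theta_row[6]))
  } else {
    list(G = reversion_params(theta_row[1], theta_row[2], theta_row[3]))
  }
}

# Simulate CNV-frequency observation vectors for each row of theta.
# Returns an n x k matrix, k = n_loci * |sample_gens|, loci concatenated
# (all G generations, then all M generations). Vectorized across rows:
# each parameter column drives its own set of n independent chains.
.simulate_theta_matrix <- function(theta, config) {
  n <- nrow(theta)
  n_loci <- if (ncol(theta) == 6L) 2L else 1L
  sim_one <- function(s, delta, phi) {
    x <- phi
    out <- matrix(NA_real_, n, length(config$sample_gens))
    idx <- 1L
    if (config$sample_gens[1] == 0L) { out[, 1L] <- x; idx <- 2L }
    for (g in seq_len(config$T_gen)) {
      p <- .wf_expected(x, s, delta)
      x <- if (is.infinite(config$N)) p else
        stats::rbinom(n, size = config$N, prob = p) / config$N
      if (idx <= length(config$sample_gens) && config$sample_gens[idx] == g) {
        out[, idx] <- x
        idx <- idx + 1L
      }
    }
    1 - out
  }
  xs <- sim_one(theta[, 1], theta[, 2], theta[, 3])
  if (n_loci == 2L)
    xs <- cbind(xs, sim_one(theta[, 4], theta[, 5], theta[, 6]))
  xs
}

#' Build a simulated training set for neural posterior estimation
#'
#' Draws `n` parameter vectors from the prior, simulates the Wright-Fisher
#' model for each (independent loci, no epistasis), and adds i.i.d.
#' Gaussian observation noise `N(0, noise_sigma^2)` to every entry. Noisy
#' values are deliberately not clipped to `[0, 1]`: the density estimator
#' is trained on the same unclipped representation it sees at inference.
#'
#' @param prior A [prior_spec()].
#' @param config A [pop_config()]; `config$N` sets the simulation
#'   population size (finite N trains the estimator on drift as well as
#'   noise).
#' @param n Number of simulations (the reference analysis used 10,000).
#' @param noise_sigma Observation noise SD (default 0.02).
#' @param seed Optional integer seed.
#' @return An object of class `npe_training_set`: list with `theta`
#'   (`n x d`), `x` (`n x k` noiseless), `x_noisy`, `noise_sigma`,
#'   `sample_gens`, `n_loci`, `prior`, `config`, `seed`.
#' @export
build_training_set <- function(prior, config, n, noise_sigma = 0.02,
                               seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "pop_config"),
            n >= 1, noise_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  theta <- sample_prior(prior, n)
  x <- .simulate_theta_matrix(theta, config)
  x_noisy <- x + matrix(stats::rnorm(length(x), 0, noise_sigma),
                        nrow(x), ncol(x))
  structure(list(theta = theta, x = x, x_noisy = x_noisy,
                 noise_sigma = noise_sigma,
                 sample_gens = config$sample_gens,
                 n_loci = prior$n_loci, prior = prior, config = config,
                 seed = seed),
            class = "npe_training_set")
}

#' Serialize a training set (or posterior samples) to CSV + JSON sidecar
#'
#' Writes the numeric table to `<path>.csv` and the provenance metadata
#' (prior bounds, seed, sampling generations, noise SD) to `<path>.json`.
#'
#' @param ts An `npe_training_set`.
#' @param path Path stem (without extension).
#' @return `path`, invisibly.
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "npe_training_set"))
  tab <- cbind(ts$theta, ts$x_noisy)
  colnames(tab) <- c(colnames(ts$theta),
                     paste0("x", seq_len(ncol(ts$x_noisy))))
  utils::write.csv(as.data.frame(tab), paste0(path, ".csv"), row.names = FALSE)
  meta <- list(prior_lo = as.list(ts$prior$lo), prior_hi = as.list(ts$prior$hi),
               n_loci = ts$n_loci, noise_sigma = ts$noise_sigma,
               sample_gens = ts$sample_gens,
               N = ts$config$N, T_gen = ts$config$T_gen,
               seed = ts$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
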