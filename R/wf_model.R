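# Wright-Fisher dynamics of CNV reversion.
#
# State per locus is the revertant (single-copy) frequency x. One generation
# applies, in order: reversion (CNV -> single copy, unidirectional), then
# selection (revertant fitness 1 + s relative to the CNV carrier), then
# binomial drift at population size N. N = Inf drops the drift step and
# gives the exact deterministic recursion.

# Vectorized deterministic part of the update: reversion then selection.
.wf_expected <- function(x, s, delta) {
  p_mut <- x + (1 - x) * delta
  p_mut * (1 + s) / (p_mut * (1 + s) + (1 - p_mut))
}

#' Advance the revertant frequency by one Wright-Fisher generation
#'
#' Applies reversion, selection and drift in that order:
#' `p_mut = x + (1 - x) delta`,
#' `p_sel = p_mut (1 + s) / (p_mut (1 + s) + 1 - p_mut)`,
#' `x' = Binomial(N, p_sel) / N`. With `N = Inf` the binomial draw is
#' skipped and `p_sel` is returned exactly.
#'
#' @param x Revertant frequency (or vector of frequencies, one per
#'   independent population), each in `[0, 1]`.
#' @param params A [reversion_params()] object.
#' @param N Population size (`>= 1`), or `Inf` for the deterministic update.
#' @return Updated frequency vector, same length as `x`.
#' @examples
#' wf_step_locus(0.1, reversion_params(s = 0.1, delta = 1e-4), N = Inf)
#' @export
wf_step_locus <- function(x, params, N = Inf) {
  stopifnot(inherits(params, "reversion_params"), is.numeric(x),
            length(x) >= 1, is.numeric(N), length(N) == 1L)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("`x` must lie in [0, 1]")
  if (N < 1) stop("`N` must be >= 1")
  p <- .wf_expected(x, params$s, params$delta)
  if (is.infinite(N)) p else stats::rbinom(length(p), size = N, prob = p) / N
}

# Run `n_pop` independent single-locus chains for T generations and return
# revertant frequencies (rows = populations, cols = sampled generations).
.simulate_locus_many <- function(n_pop, params, config) {
  x <- rep(params$phi, n_pop)
  out <- matrix(NA_real_, n_pop, length(config$sample_gens))
  idx <- 1L
  if (config$sample_gens[1] == 0L) {
    out[, 1L] <- x
    idx <- 2L
  }
  for (g in seq_len(config$T_gen)) {
    p <- .wf_expected(x, params$s, params$delta)
    x <- if (is.infinite(config$N)) p else
      stats::rbinom(n_pop, size = config$N, prob = p) / config$N
    if (idx <= length(config$sample_gens) && config$sample_gens[idx] == g) {
      out[, idx] <- x
      idx <- idx + 1L
    }
  }
  out
}

#' Simulate a CNV-frequency trajectory at one locus
#'
#' Iterates [wf_step_locus()] from the initial revertant frequency
#' `params$phi` and reports the CNV-carrier frequency `1 - x` at each
#' observation generation.
#'
#' @param params A [reversion_params()] object.
#' @param config A [pop_config()] object; `config$N = Inf` gives the
#'   deterministic trajectory.
#' @param locus Locus label stored in the result (default `"locus1"`).
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame of class `cnv_trajectory` with columns `locus`,
#'   `generation` and `cnv_freq`.
#' @examples
#' cfg <- pop_config(N = Inf, T_gen = 24, sample_gens = seq(0, 24, 12))
#' simulate_locus(reversion_params(s = 0.1, delta = 1e-3), cfg)
#' @export
simulate_locus <- function(params, config, locus = "locus1", seed = NULL) {
  stopifnot(inherits(params, "reversion_params"), inherits(config, "pop_config"))
  if (!is.null(seed)) set.seed(seed)
  x <- .simulate_locus_many(1L, params, config)[1L, ]
  structure(data.frame(locus = locus, generation = config$sample_gens,
                       cnv_freq = 1 - x, stringsAsFactors = FALSE),
            class = c("cnv_trajectory", "data.frame"))
}

#' Deterministic (infinite-N) CNV reversion trajectory
#'
#' Exact recursion `x_{t+1} = p_sel(x_t)` with no drift, reported at every
#' generation `0..T_gen`. Serves as the closed-form oracle against which the
#' stochastic simulator is checked.
#'
#' @param params A [reversion_params()] object.
#' @param T_gen Number of generations.
#' @return Data frame with columns `generation`, `revertant_freq`,
#'   `cnv_freq`.
#' @export
deterministic_trajectory <- function(params, T_gen) {
  stopifnot(inherits(params, "reversion_params"),
            is.numeric(T_gen), length(T_gen) == 1L, T_gen >= 0)
  T_gen <- as.integer(T_gen)
  x <- numeric(T_gen + 1L)
  x[1L] <- params$phi
  if (T_gen > 0) for (t in seq_len(T_gen))
    x[t + 1L] <- .wf_expected(x[t], params$s, params$delta)
  data.frame(generation = 0:T_gen, revertant_freq = x, cnv_freq = 1 - x)
}

# Genotype order used throughout the joint two-locus model.
.genotypes <- c("G2M2", "G2M1", "G1M2", "G1M1")

# One joint generation for the four-genotype system, vectorized over
# populations (rows of `f`). Reversion acts per locus at its own rate,
# selection multiplies by genotype fitness, drift is one multinomial draw.
.wf_step_two_locus <- function(f, sG, sM, dG, dM, e, N) {
  # reversion: columns G2M2, G2M1, G1M2, G1M1
  stayG <- 1 - dG; stayM <- 1 - dM
  f2 <- cbind(
    f[, 1] * stayG * stayM,
    f[, 2] * stayG + f[, 1] * stayG * dM,
    f[, 3] * stayM + f[, 1] * dG * stayM,
    f[, 4] + f[, 3] * dM + f[, 2] * dG + f[, 1] * dG * dM
  )
  w <- c(1, 1 + sM, 1 + sG, (1 + sG) * (1 + sM) * (1 + e))
  f3 <- sweep(f2, 2L, w, `*`)
  f3 <- f3 / rowSums(f3)
  if (is.infinite(N)) return(f3)
  t(apply(f3, 1L, function(p) stats::rmultinom(1L, size = N, prob = p)[, 1L] / N))
}

#' Simulate a two-locus strain (e.g. GAP1 and MEP2 reversions)
#'
#' Without epistasis the two loci are independent alleles and are simulated
#' as two independent single-locus chains. With an [epistasis_spec()], the
#' four genotypes (G2M2, G2M1, G1M2, G1M1) are tracked jointly with
#' fitnesses `1`, `1 + sM`, `1 + sG` and `(1 + sG)(1 + sM)(1 + e)`, and
#' drift is a single multinomial draw of size `N`.
#'
#' @param paramsG,paramsM [reversion_params()] for the two loci.
#' @param config A [pop_config()] object.
#' @param epistasis `NULL` (independent loci) or an [epistasis_spec()].
#' @param seed Optional integer seed.
#' @param keep_genotypes If `TRUE` (joint model only), attach the genotype
#'   frequency matrix at sampled generations as attribute `"genotypes"`.
#' @return A data frame of class `cnv_trajectory` with columns `locus`
#'   (`"G"`, `"M"`), `generation`, `cnv_freq` (marginal CNV-carrier
#'   frequency per locus).
#' @export
simulate_strain_two_locus <- function(paramsG, paramsM, config,
                                      epistasis = NULL, seed = NULL,
                                      keep_genotypes = FALSE) {
  stopifnot(inherits(paramsG, "reversion_params"),
            inherits(paramsM, "reversion_params"),
            inherits(config, "pop_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(epistasis)) {
    tG <- simulate_locus(paramsG, config, locus = "G")
    tM <- simulate_locus(paramsM, config, locus = "M")
    out <- rbind(tG, tM)
    class(out) <- c("cnv_trajectory", "data.frame")
    return(out)
  }
  stopifnot(inherits(epistasis, "epistasis_spec"))
  # initial genotype frequencies from independent initial revertant freqs
  pG <- paramsG$phi; pM <- paramsM$phi
  f <- matrix(c((1 - pG) * (1 - pM), (1 - pG) * pM, pG * (1 - pM), pG * pM),
              nrow = 1L)
  keep <- config$sample_gens
  geno <- matrix(NA_real_, length(keep), 4L,
                 dimnames = list(NULL, .genotypes))
  idx <- 1L
  if (keep[1] == 0L) { geno[1L, ] <- f; idx <- 2L }
  for (g in seq_len(config$T_gen)) {
    f <- .wf_step_two_locus(f, paramsG$s, paramsM$s, paramsG$delta,
                            paramsM$delta, epistasis$e, config$N)
    if (idx <= length(keep) && keep[idx] == g) {
      geno[idx, ] <- f
      idx <- idx + 1L
    }
  }
  cnvG <- geno[, "G2M2"] + geno[, "G2M1"]  # two copies at G
  cnvM <- geno[, "G2M2"] + geno[, "G1M2"]  # two copies at M
  out <- data.frame(
    locus = rep(c("G", "M"), each = length(keep)),
    generation = rep(keep, 2L),
    cnv_freq = c(cnvG, cnvM), stringsAsFactors = FALSE)
  class(out) <- c("cnv_trajectory", "data.frame")
  if (keep_genotypes) attr(out, "genotypes") <- geno
  out
}

#' Generations until the revertant allele reaches a fixation threshold
#'
#' Simulates replicate populations until the revertant frequency first
#' reaches `fix_threshold` (or a generation cap) and summarizes the crossing
#' times. With `N = Inf` the recursion is deterministic and a single
#' replicate suffices; for `s = 0` the crossing generation then has the
#' closed form `ceiling(log((1 - fix_threshold) / (1 - phi)) / log(1 - delta))`.
#'
#' @param params A [reversion_params()] object with `delta > 0` or
#'   `phi > 0`.
#' @param N Population size, or `Inf`.
#' @param fix_threshold Revertant frequency counted as fixation (in
#'   `(0, 1]`, default 0.99).
#' @param reps Number of replicate populations (ignored when `N = Inf`).
#' @param max_gens Generation cap; replicates that never cross are censored.
#' @param seed Optional integer seed.
#' @return List with `mean`, `ci` (2.5/97.5 percentiles over replicates),
#'   `n_censored`, `generations` (per-replicate crossing times, `NA` when
#'   censored) and `max_gens`.
#' @export
fixation_generations <- function(params, N = 3e5, fix_threshold = 0.99,
                                 reps = 100, max_gens = 50000, seed = NULL) {
  stopifnot(inherits(params, "reversion_params"),
            fix_threshold > 0, fix_threshold <= 1)
  if (params$delta == 0 && params$phi == 0)
    stop("fixation unreachable: delta = 0 and phi = 0 admit no revertants")
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(N)) reps <- 1L
  x <- rep(params$phi, reps)
  crossed <- rep(NA_real_, reps)
  if (params$phi >= fix_threshold) crossed[] <- 0
  g <- 0L
  while (anyNA(crossed) && g < max_gens) {
    g <- g + 1L
    alive <- is.na(crossed)
    p <- .wf_expected(x[alive], params$s, params$delta)
    x[alive] <- if (is.infinite(N)) p else
      stats::rbinom(sum(alive), size = N, prob = p) / N
    hit <- alive
    hit[alive] <- x[alive] >= fix_threshold
    crossed[hit] <- g
  }
  obs <- crossed[!is.na(crossed)]
  list(mean = if (length(obs)) mean(obs) else NA_real_,
       ci = if (length(obs)) unname(stats::quantile(obs, c(0.025, 0.975)))
            else c(NA_real_, NA_real_),
       n_censored = sum(is.na(crossed)),
       generations = crossed,
       max_gens = max_gens)
}

#' Read or write CNV-frequency trajectories as CSV
#'
#' Trajectory files carry one row per observation with columns `strain`,
#' `population`, `locus`, `generation`, `cnv_freq`.
#'
#' @param traj Data frame with at least the columns above.
#' @param path File path.
#' @return `read_trajectories()` returns the data frame;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(traj, path) {
  need <- c("strain", "population", "locus", "generation", "cnv_freq")
  miss <- setdiff(need, names(traj))
  if (length(miss)) stop("missing trajectory columns: ", paste(miss, collapse = ", "))
  utils::write.csv(traj[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "population", "locus", "generation", "cnv_freq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing trajectory columns: ", paste(miss, collapse = ", "))
  df
}
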