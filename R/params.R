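#' Reversion parameters for one locus
#'
#' Bundles the three quantities that govern the loss dynamics of a copy-number
#' amplification at a single locus: the selection coefficient of the
#' single-copy revertant relative to the CNV carrier, the per-cell
#' per-generation reversion rate, and the revertant frequency at the start of
#' the experiment. Revertants are assumed beneficial or effectively neutral,
#' so `s >= 0` and the CNV fitness relative to wild type is `1 / (1 + s)`.
#'
#' @param s Selection coefficient of the revertant over the CNV carrier
#'   (dimensionless, `>= 0`).
#' @param delta Reversion rate per cell per generation (probability in
#'   `[0, 1)`).
#' @param phi Initial revertant frequency (proportion in `[0, 1)`).
#' @return An object of class `reversion_params`.
#' @examples
#' reversion_params(s = 0.08, delta = 1e-4, phi = 1e-5)
#' @export
reversion_params <- function(s = 0, delta = 0, phi = 0) {
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (s < 0) stop("`s` must be >= 0: revertants are beneficial or neutral")
  if (delta < 0 || delta >= 1) stop("`delta` must lie in [0, 1)")
  if (phi < 0 || phi >= 1) stop("`phi` must lie in [0, 1)")
  structure(list(s = s, delta = delta, phi = phi), class = "reversion_params")
}

#' @export
print.reversion_params <- function(x, ...) {
  cat(sprintf("reversion_params: s = %g, delta = %g, phi = %g\n",
              x$s, x$delta, x$phi))
  invisible(x)
}

#' Population and sampling configuration for a serial-transfer experiment
#'
#' Describes the constant-size Wright-Fisher chain that approximates serial
#' batch propagation: population size, experiment length, the generations at
#' which the population is observed by flow cytometry, and the number of
#' generations per transfer cycle.
#'
#' @param N Effective population size (cells). The default `3e5` corresponds
#'   to the bottleneck of a 200 uL culture at roughly 1e8 cells/mL diluted
#'   1:64 at each transfer. Use `Inf` for the deterministic (infinite-N)
#'   model.
#' @param T_gen Total number of generations (default 220).
#' @param sample_gens Ordered vector of observation generations within
#'   `[0, T_gen]`. Defaults to every 12 generations, matching a 12-18
#'   generation flow-cytometry cadence.
#' @param cycle_length Generations per serial-transfer cycle. A 1:64
#'   dilution corresponds to `log2(64) = 6` doublings per cycle.
#' @return An object of class `pop_config`.
#' @seealso [generations_per_cycle()]
#' @export
pop_config <- function(N = 3e5, T_gen = 220,
                       sample_gens = seq(0, T_gen, by = 12),
                       cycle_length = 6) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1,
            is.numeric(T_gen), length(T_gen) == 1L, T_gen >= 1,
            is.numeric(sample_gens), length(sample_gens) >= 1,
            is.numeric(cycle_length), length(cycle_length) == 1L,
            cycle_length >= 1)
  sample_gens <- as.integer(round(sample_gens))
  if (any(diff(sample_gens) <= 0)) stop("`sample_gens` must be strictly increasing")
  if (min(sample_gens) < 0 || max(sample_gens) > T_gen)
    stop("`sample_gens` must lie within [0, T_gen]")
  structure(list(N = N, T_gen = as.integer(T_gen), sample_gens = sample_gens,
                 cycle_length = as.integer(cycle_length)),
            class = "pop_config")
}

#' Generations per serial-transfer cycle implied by a dilution factor
#'
#' Each 1:`dilution` back-dilution requires `log2(dilution)` doublings to
#' return the culture to saturation, so a 1:64 transfer regime corresponds
#' to six generations per cycle.
#'
#' @param dilution Fold-dilution at each transfer (e.g. 64 for 1:64).
#' @return Number of generations per cycle.
#' @examples
#' generations_per_cycle(64) # 6
#' @export
generations_per_cycle <- function(dilution) {
  stopifnot(is.numeric(dilution), length(dilution) == 1L, dilution > 1)
  log2(dilution)
}

#' Epistasis specification for the two-locus model
#'
#' A multiplicative interaction applied to the fitness of the double
#' revertant: `w(G1M1) = (1 + sG) (1 + sM) (1 + e)`. `e = 0` recovers
#' independent (multiplicative) loci.
#'
#' @param e Interaction coefficient; must satisfy `1 + e > 0`.
#' @return An object of class `epistasis_spec`.
#' @export
epistasis_spec <- function(e = 0) {
  stopifnot(is.numeric(e), length(e) == 1L, is.finite(e))
  if (1 + e <= 0) stop("epistasis requires 1 + e > 0")
  structure(list(e = e), class = "epistasis_spec")
}

#' Fitness transforms between selection coefficients and relative fitness
#'
#' Converts per-locus revertant selection coefficients into the fitness of
#' the CNV strain relative to the single-copy wild type, `w = 1 / (1 + s)`,
#' and combines loci multiplicatively, `1 + s_GM = (1 + sG) (1 + sM)`.
#'
#' @param sG Selection coefficient at the first locus (`> -1`).
#' @param sM Optional selection coefficient at the second locus (`> -1`).
#' @return A list with `w_G`, and when `sM` is supplied also `w_M`,
#'   `s_GM = (1 + sG)(1 + sM) - 1` and the whole-strain CNV fitness
#'   `w_strain = 1 / (1 + s_GM)`.
#' @examples
#' fitness_transforms(0.0846)           # w_G ~ 0.922
#' fitness_transforms(0.02, 0.05)$s_GM  # 0.071
#' @export
fitness_transforms <- function(sG, sM = NULL) {
  stopifnot(is.numeric(sG), length(sG) == 1L, is.finite(sG))
  if (sG <= -1) stop("selection coefficients must exceed -1")
  out <- list(w_G = 1 / (1 + sG))
  if (!is.null(sM)) {
    stopifnot(is.numeric(sM), length(sM) == 1L, is.finite(sM))
    if (sM <= -1) stop("selection coefficients must exceed -1")
    s_GM <- (1 + sG) * (1 + sM) - 1
    out$w_M <- 1 / (1 + sM)
    out$s_GM <- s_GM
    out$w_strain <- 1 / (1 + s_GM)
  }
  out
}
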