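# Seeded generators for every input the pipeline consumes: per-cell
# fluorescence samples, CNV-frequency trajectories, competition-assay time
# series, gene-duplication cost tables, and sequencing-depth tracks. Each
# generator is bit-reproducible under a fixed seed and emits the ground
# truth alongside the data, so recovery tests can compare estimates
# against what was generated.

#' Log-normal mixture specification for normalized fluorescence
#'
#' Models per-cell reporter fluorescence (divided by forward scatter) as a
#' log-normal per copy-number class with a shared coefficient of variation.
#' The default one- and two-copy locations differ by a factor of two
#' (fluorescence proportional to copy number) and the shared `sdlog` of
#' 0.18 gives an optimal-threshold misclassification between the one- and
#' two-copy classes of about 2.7%, reproducing the small overlap seen in
#' real reporter distributions.
#'
#' @param meanlog Log-scale locations of the 0-, 1- and 2-copy classes
#'   (strictly increasing).
#' @param sdlog Shared log-scale SD (`> 0`).
#' @param weights Mixture weights over the three classes (sum to 1).
#' @param n_cells Cells per sample (default 10,000).
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(meanlog = log(c(0.25, 1, 2)), sdlog = 0.18,
                      weights = c(0, 1, 0), n_cells = 10000) {
  stopifnot(length(meanlog) == 3L, all(diff(meanlog) > 0), sdlog > 0,
            length(weights) == 3L, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9, n_cells >= 1)
  structure(list(meanlog = meanlog, sdlog = sdlog, weights = weights,
                 n_cells = as.integer(n_cells)),
            class = "flow_spec")
}

#' Optimal-threshold misclassification between two fluorescence classes
#'
#' Finds the fluorescence threshold minimizing the total equal-prior error
#' between two copy-number classes of a [flow_spec()] and returns the
#' minimized error rate (the Bayes rate for single-threshold rules).
#'
#' @param spec A [flow_spec()].
#' @param classes Which two classes to compare (default one- vs two-copy).
#' @return List with `threshold` and `error`.
#' @export
bayes_misclassification <- function(spec, classes = c(2L, 3L)) {
  stopifnot(inherits(spec, "flow_spec"), length(classes) == 2L)
  ml <- spec$meanlog[classes]
  err <- function(thr)
    0.5 * (stats::plnorm(thr, ml[1], spec$sdlog, lower.tail = FALSE) +
             stats::plnorm(thr, ml[2], spec$sdlog))
  opt <- stats::optimize(err, interval = exp(ml))
  list(threshold = opt$minimum, error = opt$objective)
}

#' Generate a per-cell fluorescence sample with true class labels
#'
#' @param spec A [flow_spec()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `cell_id`, `norm_fluor`, `true_class`
#'   (0, 1 or 2).
#' @export
gen_flow_sample <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "flow_spec"))
  if (!is.null(seed)) set.seed(seed)
  cls <- sample.int(3L, spec$n_cells, replace = TRUE, prob = spec$weights)
  data.frame(cell_id = seq_len(spec$n_cells),
             norm_fluor = stats::rlnorm(spec$n_cells,
                                        spec$meanlog[cls], spec$sdlog),
             true_class = cls - 1L)
}

#' Simulate replicate CNV-frequency trajectories for a set of strains
#'
#' Runs the Wright-Fisher model for each strain and replicate population,
#' samples the CNV-carrier frequency at the configured observation
#' generations, and adds Gaussian observation noise `N(0, noise_sigma^2)`.
#' Percentages are reported both clipped to `[0, 100]` (as a gating
#' pipeline would emit) and unclipped (the representation the posterior
#' estimator is trained on).
#'
#' @param strains Named list; each element is a list with `G` (a
#'   [reversion_params()]) and optionally `M` for a second tracked locus.
#' @param config A [pop_config()].
#' @param replicates Replicate populations per strain (default 3).
#' @param noise_sigma Observation noise SD (default 0.02 on the frequency
#'   scale).
#' @param seed Optional integer seed.
#' @return List with `trajectories` (data frame: `strain`, `population`,
#'   `locus`, `generation`, `cnv_freq` unclipped, `pct_cnv` clipped) and
#'   `ground_truth` (list per strain: true parameters, true relative
#'   fitness of the CNV strain from [fitness_transforms()], deterministic
#'   phase times per locus, plus `seed`, `noise_sigma`, `config`).
#' @export
gen_strain_trajectories <- function(strains, config, replicates = 3,
                                    noise_sigma = 0.02, seed = NULL) {
  stopifnot(is.list(strains), length(strains) >= 1,
            !is.null(names(strains)), inherits(config, "pop_config"),
            replicates >= 1, noise_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  truth <- list()
  for (st in names(strains)) {
    sp <- strains[[st]]
    loci <- c("G", if (!is.null(sp$M)) "M")
    det <- lapply(loci, function(lc)
      deterministic_trajectory(sp[[lc]], config$T_gen))
    names(det) <- loci
    true_phases <- lapply(det, function(d)
      phase_times(d$generation, 100 * d$cnv_freq))
    s_vec <- vapply(loci, function(lc) sp[[lc]]$s, numeric(1))
    w_cnv <- 1 / prod(1 + s_vec)
    for (r in seq_len(replicates)) {
      for (lc in loci) {
        tr <- simulate_locus(sp[[lc]], config, locus = lc)
        f <- tr$cnv_freq + stats::rnorm(nrow(tr), 0, noise_sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = st, population = paste0(st, "_rep", r), locus = lc,
          generation = tr$generation, cnv_freq = f,
          pct_cnv = pmin(pmax(100 * f, 0), 100),
          stringsAsFactors = FALSE)
      }
    }
    truth[[st]] <- list(params = sp[loci], true_fitness = w_cnv,
                        phase_times = true_phases)
  }
  list(trajectories = do.call(rbind, rows),
       ground_truth = c(truth, list(seed = seed, noise_sigma = noise_sigma,
                                    config = config)))
}

#' Simulate a pairwise competition assay
#'
#' The true log-ratio line has slope `true_fitness - 1` from the fixed
#' intercept `b0`; at each time point the observed counts are a binomial
#' draw of `n_cells` cells from the true strain proportion (use
#' `n_cells = Inf` for noiseless ratios).
#'
#' @param true_fitness True relative fitness of the query strain (`> 0`).
#' @param b0 `ln` starting ratio (default 0, a 1:1 mix).
#' @param generations Measurement generations.
#' @param n_cells Cells counted per time point (`>= 100`, or `Inf`).
#' @param replicates Number of replicate assays.
#' @param seed Optional integer seed.
#' @return Data frame with columns `replicate`, `generation`,
#'   `query_count`, `reference_count` (`NA` when `n_cells = Inf`),
#'   `ln_ratio`; attribute `b0` and `true_fitness`.
#' @export
gen_competition_series <- function(true_fitness, b0 = 0,
                                   generations = c(0, 2, 4, 8, 12, 16),
                                   n_cells = 10000, replicates = 3,
                                   seed = NULL) {
  stopifnot(true_fitness > 0, is.finite(b0), length(generations) >= 2,
            n_cells >= 100, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (r in seq_len(replicates)) {
    lnr_true <- b0 + (true_fitness - 1) * generations
    if (is.infinite(n_cells)) {
      q <- NA_integer_; ref <- NA_integer_; lnr <- lnr_true
    } else {
      p <- stats::plogis(lnr_true)
      q <- stats::rbinom(length(p), n_cells, p)
      # guard the log against empty gates at extreme ratios
      q <- pmin(pmax(q, 1L), n_cells - 1L)
      ref <- n_cells - q
      lnr <- log(q / ref)
    }
    out[[r]] <- data.frame(replicate = r, generation = generations,
                           query_count = q, reference_count = ref,
                           ln_ratio = lnr)
  }
  res <- do.call(rbind, out)
  attr(res, "b0") <- b0
  attr(res, "true_fitness") <- true_fitness
  res
}

#' Generate a synthetic gene-duplication cost table
#'
#' Places `n_genes` genes with coordinates on a set of chromosomes and
#' draws per-gene duplication costs from a two-component model:
#' significant genes (FDR below 0.05) from `N(sig_mean, sig_sd)` and
#' non-significant genes from `N(0, nonsig_sd)`. All costs are then
#' shifted by a constant so that the all-gene mean equals `target_mean`
#' exactly, mirroring the genome-wide average of the reference screen.
#'
#' @param n_genes Number of genes.
#' @param frac_significant Fraction of genes with significant costs.
#' @param sig_mean,sig_sd Cost distribution of significant genes.
#' @param nonsig_sd Cost SD of non-significant genes.
#' @param target_mean Target all-gene mean cost (default -0.33).
#' @param chromosomes Chromosome labels to place genes on (round-robin).
#' @param gene_span,gene_gap Gene length and intergenic gap in bp.
#' @param seed Optional integer seed.
#' @return Data frame with columns `gene`, `chromosome`, `start`, `end`
#'   (0-based half-open), `cost`, `fdr`, `significant`.
#' @export
gen_gene_cost_table <- function(n_genes = 500, frac_significant = 0.1,
                                sig_mean = -2, sig_sd = 1.5,
                                nonsig_sd = 0.25, target_mean = -0.33,
                                chromosomes = as.character(utils::as.roman(1:16)),
                                gene_span = 1500, gene_gap = 500,
                                seed = NULL) {
  stopifnot(n_genes >= 1, frac_significant >= 0, frac_significant <= 1)
  if (!is.null(seed)) set.seed(seed)
  sig <- stats::runif(n_genes) < frac_significant
  cost <- ifelse(sig, stats::rnorm(n_genes, sig_mean, sig_sd),
                 stats::rnorm(n_genes, 0, nonsig_sd))
  cost <- cost + (target_mean - mean(cost))
  chrom <- rep(chromosomes, length.out = n_genes)
  idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- (idx_on_chrom - 1L) * (gene_span + gene_gap)
  data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
             chromosome = chrom, start = start, end = start + gene_span,
             cost = cost,
             fdr = ifelse(sig, stats::runif(n_genes, 0, 0.049),
                          stats::runif(n_genes, 0.05, 1)),
             significant = sig, stringsAsFactors = FALSE)
}

#' Generate a sequencing-depth track with an amplified segment
#'
#' Draws per-window depths as Poisson counts at `mean_depth`, multiplied
#' by `multiplier` for windows wholly inside the CNV segment.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param cnv_segment `NULL`, or a list with `chrom`, `start`, `end`
#'   (0-based half-open) locating the amplified segment.
#' @param multiplier Depth multiplier inside the segment (`>= 0`; the
#'   segment's copy number relative to baseline).
#' @param mean_depth Baseline mean depth (`> 0`).
#' @param window Window size in bp.
#' @param seed Optional integer seed.
#' @return Data frame with columns `chrom`, `start`, `end`, `depth`
#'   (suitable for [pncn_track()] and [write_bedgraph()]).
#' @export
gen_depth_track <- function(chrom_lengths, cnv_segment = NULL,
                            multiplier = 1, mean_depth = 50, window = 100,
                            seed = NULL) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)), mean_depth > 0, multiplier >= 0,
            window >= 1)
  if (!is.null(cnv_segment)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(cnv_segment)))
    if (!cnv_segment$chrom %in% names(chrom_lengths) ||
        cnv_segment$start < 0 ||
        cnv_segment$end > chrom_lengths[[cnv_segment$chrom]])
      stop("CNV segment lies outside the genome")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(0L, len - 1L, by = window)
    end <- pmin(start + window, len)
    lambda <- rep(mean_depth, length(start))
    if (!is.null(cnv_segment) && cnv_segment$chrom == ch) {
      inside <- start >= cnv_segment$start & end <= cnv_segment$end
      lambda[inside] <- mean_depth * multiplier
    }
    data.frame(chrom = ch, start = start, end = end,
               depth = stats::rpois(length(start), lambda),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
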