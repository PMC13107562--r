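---
title: "Modeling and inferring CNV reversion dynamics after removal of selection"
author: "cnvrevert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inferring CNV reversion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrevert)
```

## The scientific problem

Adaptive copy-number amplifications (CNVs) — extra copies of a genomic
segment or a whole chromosome — arise recurrently when microbial
populations are selected in nutrient-limited environments, typically by
amplifying a nutrient-transporter gene. When the selective pressure is
removed, the amplification no longer pays its way: any fitness *cost* of
the extra copies is exposed, and cells that spontaneously revert to the
single-copy state can sweep through the population. `cnvrevert`
implements the computational machinery for studying this process in
serial-batch evolution experiments with budding yeast: a Wright-Fisher
model of reversion, simulation-based Bayesian inference of the reversion
rate and fitness effect from CNV-frequency trajectories, the
fixed-intercept regression used in pairwise competitive fitness assays,
predicted fitness-cost scores for amplified regions, flow-cytometry
gating, CNV-loss phase statistics, and ploidy-normalized copy-number
(PNCN) tracks from sequencing depth.

## The Wright-Fisher reversion model

The state of one locus in one population is the revertant (single-copy)
frequency $x$. One generation applies three steps in a fixed order:

1. **Reversion** (mutation): $p_{\mathrm{mut}} = x + (1 - x)\,\delta$,
   where $\delta$ is the per-cell per-generation reversion rate.
   Reversion is unidirectional — the model tracks loss of the
   amplification only, not re-amplification.
2. **Selection**: the revertant has fitness $1 + s$ relative to the CNV
   carrier ($s \ge 0$; revertants are beneficial or effectively neutral),
   so $p_{\mathrm{sel}} = p_{\mathrm{mut}}(1+s) \,/\,
   \big(p_{\mathrm{mut}}(1+s) + 1 - p_{\mathrm{mut}}\big)$.
3. **Drift**: $x' = \mathrm{Binomial}(N, p_{\mathrm{sel}})/N$, dropped
   when `N = Inf` (the deterministic recursion used as the oracle in our
   tests).

The update order is a modeling choice; exchanging reversion and
selection changes results at order $s\delta$ per generation, negligible
at the parameter scales of interest ($s \lesssim 0.3$,
$\delta \lesssim 10^{-2}$). The third parameter of the model is
$\varphi$, the revertant frequency already present when the experiment
starts.

The CNV fitness relative to the single-copy wild type is
$w = 1/(1+s)$, and two loci combine multiplicatively,
$1 + s_{GM} = (1+s_G)(1+s_M)$ (`fitness_transforms()`).

**Population size.** Serial 1:64 batch transfer means
$\log_2 64 = 6$ doublings per cycle (`generations_per_cycle()`). The
boom-bust census is approximated by a constant-size Wright-Fisher chain;
the default $N = 3\times10^5$ corresponds to the bottleneck of a 200 µL
culture at $\sim 10^8$ cells/mL diluted 1:64. Both $N$ and the sampling
cadence (default: every 12 generations of a 220-generation experiment,
within the 12–18-generation measurement cadence and a multiple of the
6-generation cycle) are configurable via `pop_config()`.

**Two loci and epistasis.** Without epistasis the two reversions are
independent alleles and are simulated as independent chains. With
epistasis the four genotypes (two copy-number states at each locus) are
tracked jointly; the double revertant's fitness is
$(1+s_G)(1+s_M)(1+e)$, drift is a single multinomial draw, and $e = 0$
recovers the factorized model exactly (verified to $10^{-9}$ in the
tests). The multiplicative $(1+e)$ interaction form is this package's
choice; the model family is deliberately minimal.

**Neutral-reversion forecasts.** `fixation_generations()` reports the
generations until the revertant allele crosses a fixation threshold.
For $s = 0$ and `N = Inf` the crossing time has the closed form
$\lceil \ln\!\big((1-c)/(1-\varphi)\big) / \ln(1-\delta) \rceil$ at
threshold $c$; e.g. $\delta = 2\times10^{-4}$, $\varphi = 0$, $c = 0.99$
gives $\approx 23{,}000$ generations — reversion without selection is
extremely slow, which is why negative selection, not reversion pressure,
drives observed CNV loss. Because the answer depends strongly on
$\delta$, $N$ and the threshold, all three are explicit arguments.

## Neural posterior estimation

The inference target is $\theta = (s_G, \delta_G, \varphi_G, s_M,
\delta_M, \varphi_M)$ given noisy CNV-frequency trajectories
$x_{\mathrm{noisy}}(\theta) = x(\theta) + \varepsilon$,
$\varepsilon \sim N(0, 0.02)$. Priors are log-uniform with defaults
$s \in [10^{-3}, 0.3]$, $\delta \in [10^{-7}, 10^{-2}]$,
$\varphi \in [10^{-7}, 10^{-1}]$, chosen to bracket reported reversion
rates ($10^{-5}$–$10^{-3}$ per cell per generation) and selection
coefficients (up to $\sim 0.085$); all bounds are configurable in
`prior_spec()`.

`build_training_set()` simulates the model for prior draws and adds the
observation noise. Noisy values are *not* clipped to $[0,1]$; the
estimator is trained on the same unclipped representation it sees at
inference, avoiding boundary bias. A single network estimates all six
parameters jointly from the concatenated two-locus trajectories; strains
with one tracked locus use a separately trained three-parameter network
(`prior_spec(n_loci = 1)`).

### The conditional flow

The conditional density estimator is a masked autoregressive flow,
written in R (no deep-learning runtime is required): a stack of five
affine autoregressive transforms, each parameterized by a MADE-masked
network with two hidden layers of 50 tanh units, conditioned on the
observation vector, trained by Adam on the negative conditional
log-likelihood with a 10% validation split and early stopping.
Gradients are exact reverse-mode derivatives (validated against finite
differences to $\sim 10^{-7}$ relative error), and sampling is the exact
sequential inverse of the density pass.

Choices that matter for calibration, found by inspecting
simulation-based-calibration rank histograms during development:

* **Parameter representation.** $\theta$ is mapped to its position $q$
  in the log-prior box and then through the Gaussian quantile
  $u = \Phi^{-1}(q)$. Under the log-uniform prior $u$ is *exactly*
  standard normal, so the identity flow already reproduces the prior;
  the network only has to learn where the data constrain it. (A logit
  map, by contrast, leaves a logistic-vs-Gaussian mismatch that shows up
  directly in calibration checks.) Samples map back inside the prior box
  by construction; a rejection guard remains for custom priors.
* **Conditioning summaries.** The flow conditions on the raw trajectory
  *plus* a small set of summary features per locus: terminal, minimum
  and mean frequency, the steepest per-interval drop, and the scaled
  first-crossing indices below 75/50/25% CNV frequency. Posteriors for
  $\delta$ and $\varphi$ have sharp data-dependent upper cutoffs (a flat
  trajectory excludes large $\delta$), and the crossing-time features
  let the flow place those cutoffs accurately.
* **Noise augmentation.** The observation noise is resampled every
  training epoch. The noise model is known, so this is exact data
  augmentation; it substantially reduces overfitting of the conditional
  at moderate training-set sizes.
* **Deep ensemble.** `train_npe()` trains six flows from independent
  initializations, drops members whose held-out loss is more than 0.5
  nats worse than the best (a poorly converged member degrades the
  mixture), and uses the equal mixture of the survivors as the
  posterior. Sampling assigns draws to members multinomially — an
  exactly balanced split would bias rank statistics away from the
  extremes.
* **Optimization.** Learning rate $10^{-3}$, batch 128, up to 800
  epochs, patience 80; on a validation plateau the optimizer restarts
  from the best weights at 0.3x the learning rate.

Point estimates are per-parameter posterior medians.

### Collective posteriors, calibration, predictive checks

`collective_posterior()` combines replicate populations of one strain
into a single posterior targeting
$p(\theta)\prod_i p(\theta\mid x_i)/p(\theta)$, by importance
resampling with the equal mixture of the individual posteriors as the
proposal (with the flat prior in $u$-space the weights reduce to
$\prod_i q_i / \overline{q}_i$). No MCMC tuning is needed and the
effective sample size is reported; results with ESS below 50 carry a
warning. The sampler is validated in the tests against a conjugate
Gaussian oracle where the product posterior is known in closed form.

`sbc_ranks()` / `sbc_uniformity()` implement simulation-based
calibration: for prior draws $\theta^\ast$, the rank of each true
parameter among $m$ posterior draws must be discrete-uniform. Uniformity
is tested per parameter by a chi-squared test whose bin probabilities
respect the discrete rank support, with Bonferroni adjustment across the
six parameters; the family-wise check is `min(p_adjusted) > alpha`
(six unadjusted tests at $\alpha = 0.01$ would false-alarm about 6% of
the time).

`posterior_predictive_check()` simulates trajectories for (by default)
100 posterior parameter sets and reports the pointwise predictive median,
the central 95% envelope, the fraction of observed points inside the
envelope, and the RMSE between observation and predictive median.

## Competitive fitness assays

Competition assays start from a known strain ratio, so the intercept of
$\ln(\text{query}/\text{reference})$ against generations is fixed at
$b_0 = \ln(\text{starting ratio})$ and only the slope is fitted:
$\hat\beta = \sum_j g_j (y_j - b_0) \,/\, \sum_j g_j^2$ over all points
pooled across replicates (pooling, rather than averaging per-replicate
slopes, uses all independent values in one regression). Relative fitness
is $\hat\beta + 1$, exactly 1 for the reference strain. The standard
error uses residual variance with $n - 1$ degrees of freedom (one fitted
parameter — the reference does not state the df convention), giving a
symmetric 95% CI and a two-sided t-test of $\beta = 0$ at
$\alpha = 0.05$. `b0` defaults to the theoretical value of the
configured starting mix rather than a measured generation-0 ratio; both
are accepted. Because the intercept is anchored at $g = 0$, shifting the
generation axis changes the estimate — generations must be counted from
the start of the assay (this non-invariance is tested deliberately).
Monte-Carlo checks in the test suite confirm the estimator is unbiased
to $\pm 0.003$ and that CI coverage is 93–97% at nominal 95%.

```{r fitness}
g <- rep(c(0, 2, 4, 8, 12, 16), 3)
fit_relative_fitness(g, 0.05 * g, b0 = 0)
```

## Predicted CNV fitness costs

Given a table of per-gene duplication costs (log2 fold-change units)
with FDR < 0.05 significance flags, the predicted cost of an amplified
region is

$$\text{cost} = (\text{copy number} - 1) \times \Big[
  \sum_{\text{significant genes}} \text{cost}_g +
  n_{\text{non-significant}} \times \overline{\text{cost}} \Big],$$

with $\overline{\text{cost}} = -0.33$ by default (the genome-wide mean
of the reference screen; `mean_gene_cost()` recomputes it from any
table, and the default is an input so synthetic tables can use their own
mean). Whole-chromosome duplications use the same bracket over all genes
on the chromosome with one extra copy, and a double aneuploidy is the
sum of the two single-chromosome costs (`aneuploidy_cost()`). Genes
belong to a segmental region when wholly contained within its
breakpoints (boundary-straddling genes are excluded — annotation
coordinates, not breakpoint-refined ones). `pearson_cost_fitness()`
correlates predicted cost with measured fitness; its default 95% CI is
a bias-corrected bootstrap over pairs (10,000 seeded resamples), which
accommodates the asymmetric sampling distribution of $r$; a Fisher-z
interval is available. Measured coverage at $n = 10$, $\rho = 0.4$:
bootstrap 0.96, Fisher 0.94.

```{r cost}
region <- data.frame(gene = letters[1:5], cost = c(-1.5, 0.2, 0, 0, 0),
                     significant = c(TRUE, TRUE, FALSE, FALSE, FALSE))
total_cnv_cost(region, extra_copies = 2, mean_all_genes = -0.33)
```

## Flow-cytometry gating and CNV-loss phases

`build_gates()` stands in for manual gating: each copy-number control
(0, 1, 2 copies of the reporter) contributes its central 95% quantile
interval of normalized fluorescence, and the class boundary between
adjacent controls is the midpoint of the overlap (or gap) of their
intervals. The three gates partition the positive axis, so
`classify_cells()` fractions always sum to 1. The achieved containment
of each control inside its own gate is reported so any shortfall from
the 95% target is visible; when controls are unimodal with monotone
densities at the boundary, misclassification between adjacent classes is
bounded by one minus the containment.

`phase_times()` converts a trajectory of percent CNV-containing cells
into the generations at which 25/50/75% of cells have lost the CNV
(early/middle/late phases), linearly interpolating between the flanking
observations — reported phase times fall between sampling points, which
implies interpolation rather than first-sampled-crossing; thresholds
never reached are censored at the horizon. `compare_phase_times()` runs
paired t-tests between CNV types; censored populations enter the test at
the experiment horizon (220 generations by default) and the number
substituted is reported, while group medians use observed populations
only. How censored populations should be encoded in a paired t-test is
genuinely ambiguous; the horizon convention is conservative (it
understates differences when one group is censored) and is flagged in
the output. Pairing is by population label: for two loci measured in the
same cells this is the natural within-population pairing; comparisons
across strains pair by within-strain index, which is arbitrary and
should be stated when used.

## Ploidy-normalized copy number

`pncn_track()` averages a bedGraph depth track in fixed windows (0-based
half-open) and divides by the genome-wide mean depth. A locus present at
the strain's base ploidy has PNCN 1; a triplicated segment in a diploid
reads 3 per chromosome copy. The track is invariant to depth rescaling.
Note that the genome-wide mean includes the amplified mass, so with a
large amplified fraction the baseline reads slightly below 1; the
segment-to-baseline *ratio* recovers the true multiplier (the test suite
checks a 135 kb 3x segment this way). bedGraph I/O goes through
`rtracklayer`, and windowing through `GenomicRanges`.

## What the synthetic generators emulate

`gen_flow_sample()` draws per-cell normalized fluorescence from a
log-normal mixture with a shared log-scale SD (0.18), class locations
proportional to copy number, and 10,000 cells per sample; the implied
optimal-threshold misclassification between one and two copies is
$\approx 2.7\%$, matching the "small overlap" regime of real reporter
distributions. `gen_strain_trajectories()` runs the Wright-Fisher model
per replicate (3–4 replicates, 220 generations, sampling every 12) and
adds the $N(0, 0.02)$ observation noise, emitting both clipped
percentages (what a gating pipeline reports) and unclipped frequencies
(what the estimator consumes), plus a ground-truth sidecar with the true
parameters, true fitness and deterministic phase times.
`gen_competition_series()` observes an exact log-ratio line through
binomial counting noise. `gen_gene_cost_table()` draws significant and
non-significant gene costs and shifts them so the all-gene mean hits
-0.33 exactly. `gen_depth_track()` lays Poisson depths over windows with
a multiplied segment.

What they deliberately do **not** emulate: instrument-level artifacts
(debris/doublet pre-filtering, spectral compensation, fluorescence decay
in stationary phase), growth-phase structure within a transfer cycle,
linkage between loci (trajectory replicates simulate loci
independently), clonal interference among distinct revertant lineages,
and read-level sequencing error. Passing recovery tests on these
generators therefore demonstrates correctness of the estimators under
the model's own assumptions, not robustness to instrument artifacts.

## Numerical choices and problem sizes

* Frequencies are kept in double precision with no clamping inside the
  simulator; genotype frequencies renormalize after selection and are
  conserved to $10^{-12}$.
* The flow's log-scale outputs are soft-clamped to $\pm 4$ via tanh for
  numerical stability.
* The test suite trains one shared estimator on 2,000 simulations
  (about 5 minutes of CPU), a deliberate scale-down from the 10,000
  simulations a production analysis would use; recovery tolerances in
  the tests reflect that size. Monte-Carlo checks use 400–1,000
  replicates. Simulation-based calibration uses 200 prior draws with
  100 posterior draws each.
* Training is deterministic given the training set and seed; all
  generators are bit-reproducible under fixed seeds.

## Known limitations

* The constant-N approximation ignores the within-cycle bottleneck
  structure; selection during lag/exponential/stationary phases is
  summarized by one per-generation coefficient.
* The affine autoregressive flow smooths very sharp posterior cutoffs;
  the ensemble and crossing-time summaries mitigate this, and residual
  approximation error is monitored by simulation-based calibration
  rather than assumed away.
* The collective posterior assumes replicates are conditionally
  independent given $\theta$ (isogenic founders, no shared environmental
  shocks across wells).
* Cost predictions inherit the assumptions of the underlying per-gene
  screen (additivity across genes, per-extra-copy linearity).
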