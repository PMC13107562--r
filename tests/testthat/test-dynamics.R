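# Gating, copy-number classification, CNV-loss phases, PNCN tracks.

test_that("gates from non-overlapping uniform controls sit at the midpoints", {
  set.seed(1)
  controls <- list(runif(5000, 0, 1), runif(5000, 2, 3), runif(5000, 4, 5))
  g <- build_gates(controls, containment = 0.95)
  # central 95% quantile intervals leave the gaps intact:
  # boundaries at the midpoints of (: 1, 2 :) and (: 3, 4 :)
  expect_equal(g$boundaries, c(1.5, 3.5), tolerance = 0.02)
  expect_equal(unname(g$achieved), c(1, 1, 1))
})

test_that("heavily overlapping controls are rejected", {
  set.seed(2)
  same <- rlnorm(1000, 0, 0.2)
  expect_error(build_gates(list(rlnorm(1000, -2, 0.2), same, same)),
               "increasing")
  expect_error(build_gates(list(runif(50, 0, 1), runif(50, 2, 3),
                                runif(50, 4, 5))), "100 cells")
})

test_that("simulated log-normal controls achieve the 95% containment target", {
  spec <- flow_spec()
  set.seed(3)
  controls <- lapply(1:3, function(k) {
    w <- c(0, 0, 0); w[k] <- 1
    gen_flow_sample(flow_spec(weights = w))$norm_fluor
  })
  g <- build_gates(controls, containment = 0.95)
  expect_true(all(g$achieved >= 0.95))
})

test_that("classification partitions every sample and bounds misclassification", {
  set.seed(4)
  controls <- lapply(1:3, function(k) {
    w <- c(0, 0, 0); w[k] <- 1
    gen_flow_sample(flow_spec(weights = w))$norm_fluor
  })
  g <- build_gates(controls)
  # an even 1-copy / 2-copy mixture: the 2+ fraction reflects the mixture
  # weight to within the gate misclassification (<= 5%)
  mix <- gen_flow_sample(flow_spec(weights = c(0, 0.5, 0.5)), seed = 5)
  cl <- classify_cells(mix$norm_fluor, g)
  expect_equal(sum(cl$fractions), 1, tolerance = 1e-12)
  expect_gte(cl$fractions[["copy2plus"]], 0.45)
  expect_lte(cl$fractions[["copy2plus"]], 0.55)
  # all cells in the top gate
  high <- rlnorm(1000, log(4), 0.1)
  expect_equal(unname(classify_cells(high, g)$fractions),
               c(0, 0, 1))
  expect_error(classify_cells(numeric(0), g), "empty")
})

test_that("observed misclassification of controls stays within 1 - containment", {
  # unimodal controls with monotone densities at the boundary: the
  # construction guarantees the error bound empirically
  set.seed(6)
  one <- gen_flow_sample(flow_spec(weights = c(0, 1, 0)))$norm_fluor
  two <- gen_flow_sample(flow_spec(weights = c(0, 0, 1)))$norm_fluor
  zero <- gen_flow_sample(flow_spec(weights = c(1, 0, 0)))$norm_fluor
  g <- build_gates(list(zero, one, two), containment = 0.95)
  mis1 <- mean(one > g$boundaries[2])   # 1-copy called 2+
  mis2 <- mean(two <= g$boundaries[2])  # 2-copy called <= 1
  expect_lte(mis1, 0.05)
  expect_lte(mis2, 0.05)
})

test_that("phase times interpolate linearly and respect censoring", {
  # 25% loss between 100% at g0 and 70% at g12: 12 * (25 / 30) = 10
  pt <- phase_times(c(0, 12), c(100, 70))
  expect_equal(pt$generation[pt$phase == "early"], 10)
  expect_true(all(pt$censored[pt$phase %in% c("middle", "late")]))
  expect_equal(unique(pt$horizon), 12)
  # a trajectory that never drops below 75% is censored everywhere
  flat <- phase_times(seq(0, 220, 12), rep(98, 19))
  expect_true(all(flat$censored))
  # an observation exactly at the threshold is the crossing
  hit <- phase_times(c(0, 36, 48), c(100, 75, 10))
  expect_equal(hit$generation[hit$phase == "early"], 36)
  # monotone: early <= middle <= late whenever all observed
  set.seed(7)
  for (i in 1:20) {
    pct <- 100 * sort(runif(10, 0, 1), decreasing = TRUE)
    pct[1] <- 100
    pt <- phase_times(seq(0, 108, 12), pct)
    obs <- pt$generation[!pt$censored]
    expect_true(all(diff(obs) >= 0))
  }
})

test_that("paired phase comparisons handle censoring and degenerate cases", {
  A <- data.frame(population = paste0("p", 1:4),
                  early = c(20, 25, 18, 30), middle = c(40, 45, 39, 50))
  expect_error(compare_phase_times(A, A[-1, ]), "unpaired")
  same <- compare_phase_times(A, A)
  expect_equal(same$t, c(0, 0))
  expect_equal(same$p_value, c(1, 1))
  # constant nonzero difference: p reported as 0 (< 1e-12)
  B <- A; B$early <- A$early + 10; B$middle <- A$middle + 10
  const <- compare_phase_times(A, B)
  expect_true(all(const$p_value < 1e-12))
  # censored populations enter at the horizon
  C <- A; C$middle[2] <- NA
  cen <- compare_phase_times(A, C, horizon = 220)
  expect_equal(cen$n_censored_B[cen$phase == "middle"], 1L)
  expect_lt(cen$mean_diff[cen$phase == "middle"], 0)
})

test_that("paired t-test detects a 30-generation shift with high power", {
  # closed-form benchmark: n = 13 pairs, sd 10, delta 30 => noncentral t
  # with ncp = 30 / (10 / sqrt(13)) ~ 10.8, power ~ 1 at alpha = 0.05
  set.seed(8)
  rejections <- replicate(1000, {
    a <- rnorm(13, 100, 12)
    d <- rnorm(13, 30, 10)
    A <- data.frame(population = paste0("p", 1:13), middle = a + d)
    B <- data.frame(population = paste0("p", 1:13), middle = a)
    compare_phase_times(A, B)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.99)
})

test_that("PNCN is depth normalized to the genome mean, scale-invariant", {
  lens <- c(chrI = 20000, chrII = 30000)
  uniform <- gen_depth_track(lens, mean_depth = 40, window = 100, seed = 9)
  uniform$depth <- 40  # exactly uniform
  tr <- pncn_track(uniform, window = 1000)
  expect_true(all(abs(tr$pncn - 1) < 1e-12))
  # scale invariance
  scaled <- uniform; scaled$depth <- uniform$depth * 7.5
  expect_equal(pncn_track(scaled, window = 1000)$pncn, tr$pncn)
  # zero-depth segment has PNCN 0
  hole <- uniform
  hole$depth[hole$chrom == "chrI" & hole$start >= 5000 &
               hole$end <= 10000] <- 0
  trh <- pncn_track(hole, window = 1000)
  expect_true(all(trh$pncn[trh$chrom == "chrI" & trh$start >= 5000 &
                             trh$end <= 10000] == 0))
  expect_warning(pncn_track(uniform, window = 25000), "whole-chromosome")
})

test_that("a 3x amplified segment is recovered from Poisson depth", {
  lens <- c(chrXI = 400000)
  seg <- list(chrom = "chrXI", start = 100000, end = 235000)  # 135 kb
  depth <- gen_depth_track(lens, cnv_segment = seg, multiplier = 3,
                           mean_depth = 50, window = 100, seed = 10)
  tr <- pncn_track(depth, window = 5000)
  inside <- tr$start >= seg$start & tr$end <= seg$end
  # baseline is diluted by the amplified mass, so compare ratios:
  # segment / outside should be 3 within Poisson noise
  ratio <- mean(tr$pncn[inside]) / mean(tr$pncn[!inside])
  expect_equal(ratio, 3, tolerance = 0.1 / 3)
  expect_error(gen_depth_track(lens, cnv_segment = list(
    chrom = "chrXI", start = 0, end = 500000), multiplier = 3), "outside")
})

test_that("bedGraph round-trips through rtracklayer", {
  lens <- c(chrI = 5000)
  depth <- gen_depth_track(lens, mean_depth = 30, window = 500, seed = 11)
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(depth, path)
  back <- read_bedgraph(path)
  expect_equal(back$depth, depth$depth)
  expect_equal(back$start, depth$start)
})
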