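# Pairwise competitive fitness assays: fixed-intercept log-ratio regression.

#' Natural log-ratio of query to reference counts
#'
#' @param query_counts,reference_counts Positive cell counts at each time
#'   point (equal lengths).
#' @return `ln(query / reference)` elementwise.
#' @examples
#' ln_ratios(c(100, 200), c(100, 100)) # 0, log(2)
#' @export
ln_ratios <- function(query_counts, reference_counts) {
  stopifnot(length(query_counts) == length(reference_counts))
  bad <- which(query_counts <= 0 | reference_counts <= 0)
  if (length(bad))
    stop("non-positive count at time point(s): ", paste(bad, collapse = ", "))
  log(query_counts / reference_counts)
}

#' Relative fitness from a pooled fixed-intercept regression
#'
#' Competition assays start at a known strain ratio, so the intercept of
#' the `ln(query / reference)` vs generations line is fixed at
#' `b0 = ln(starting ratio)` and only the slope is estimated:
#' `slope = sum(g * (y - b0)) / sum(g^2)` over all points pooled across
#' replicates. Relative fitness is `slope + 1` (1 for the reference strain
#' by definition). The standard error uses the residual variance with
#' `n - 1` degrees of freedom (one fitted parameter), giving a symmetric
#' 95% confidence interval and a two-sided t-test of `slope = 0`.
#'
#' Because the intercept is anchored at generation 0, shifting all
#' generation values by a constant changes the estimate; generations must
#' be measured from the start of the assay.
#'
#' @param generations Generation of each measurement (pooled across
#'   replicates; at least one nonzero).
#' @param ln_ratio `ln(query / reference)` at each measurement.
#' @param b0 Fixed intercept, `ln` of the starting ratio (default 0 for a
#'   1:1 mix).
#' @param alpha Significance level for the confidence interval.
#' @return An object of class `fitness_estimate`: list with `slope`, `se`,
#'   `fitness = slope + 1`, `ci95`, `p_value`, `n_points`, `df`, `b0`.
#' @examples
#' g <- rep(c(0, 2, 4, 8, 12, 16), 3)
#' fit_relative_fitness(g, 0.05 * g)$fitness # 1.05
#' @export
fit_relative_fitness <- function(generations, ln_ratio, b0 = 0,
                                 alpha = 0.05) {
  stopifnot(length(generations) == length(ln_ratio),
            length(generations) >= 2, is.finite(b0))
  if (all(generations == 0)) stop("slope unidentifiable: all generations are zero")
  g <- as.numeric(generations)
  y <- as.numeric(ln_ratio) - b0
  slope <- sum(g * y) / sum(g^2)
  n <- length(g)
  df <- n - 1L
  resid <- y - slope * g
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sum(g^2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  p_value <- if (se == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(slope / se), df)
  }
  structure(list(slope = slope, se = se, fitness = slope + 1,
                 ci95 = c(slope + 1 - tcrit * se, slope + 1 + tcrit * se),
                 p_value = p_value, n_points = n, df = df, b0 = b0),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf(paste0("relative fitness: %.4f (95%% CI %.4f-%.4f)\n",
                     "  slope %.4f +/- %.4f per generation, ",
                     "p = %.3g (n = %d, df = %d)\n"),
              x$fitness, x$ci95[1], x$ci95[2], x$slope, x$se, x$p_value,
              x$n_points, x$df))
  invisible(x)
}

#' Fit relative fitness for every strain in a competition table
#'
#' @param data Data frame with columns `strain`, `replicate`, `generation`
#'   and either `ln_ratio` or both `query_count` and `reference_count`.
#' @param b0 Fixed intercept (see [fit_relative_fitness()]).
#' @param alpha Significance level.
#' @return Data frame with one row per strain: `strain`, `fitness`,
#'   `ci_low`, `ci_high`, `p_value`, `n_points`.
#' @export
fitness_table <- function(data, b0 = 0, alpha = 0.05) {
  stopifnot(all(c("strain", "generation") %in% names(data)))
  if (!"ln_ratio" %in% names(data)) {
    if (!all(c("query_count", "reference_count") %in% names(data)))
      stop("need `ln_ratio` or `query_count` + `reference_count` columns")
    data$ln_ratio <- ln_ratios(data$query_count, data$reference_count)
  }
  out <- lapply(split(data, data$strain), function(d) {
    f <- fit_relative_fitness(d$generation, d$ln_ratio, b0 = b0,
                              alpha = alpha)
    data.frame(strain = d$strain[1], fitness = f$fitness,
               ci_low = f$ci95[1], ci_high = f$ci95[2],
               p_value = f$p_value, n_points = f$n_points)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
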