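# Flow-cytometry gating, CNV-loss phase statistics, and ploidy-normalized
# copy-number tracks.

#' Build copy-number gates from control samples
#'
#' Given normalized-fluorescence samples from control strains carrying
#' zero, one and two copies of the reporter, computes the central
#' `containment` quantile interval of each control and places the class
#' boundary between adjacent controls at the midpoint of the overlap of
#' their intervals (or of the gap, when they do not overlap). The three
#' resulting intervals partition the positive fluorescence axis into the
#' 0-, 1- and 2-or-more-copy gates. The achieved containment of each
#' control inside its own gate is reported; the construction targets 95%.
#'
#' @param controls List of three numeric vectors of per-cell normalized
#'   fluorescence (zero-, one-, two-copy controls, in that order), each
#'   with at least 100 cells.
#' @param containment Central quantile mass per control, in `(0.5, 1)`
#'   (default 0.95).
#' @return An object of class `gate_set`: list with `boundaries` (two cut
#'   points), `intervals` (3 x 2 matrix), `achieved` (containment per
#'   control), `containment`.
#' @export
build_gates <- function(controls, containment = 0.95) {
  stopifnot(is.list(controls), length(controls) == 3L)
  if (any(vapply(controls, length, integer(1)) < 100L))
    stop("each control sample needs at least 100 cells")
  if (containment <= 0.5 || containment >= 1)
    stop("`containment` must lie in (0.5, 1)")
  if (any(vapply(controls, function(v) any(!is.finite(v) | v <= 0),
                 logical(1))))
    stop("fluorescence values must be finite and positive")
  med <- vapply(controls, stats::median, numeric(1))
  if (any(diff(med) <= 0))
    stop("control medians must be strictly increasing with copy number ",
         "(0 < 1 < 2); got ", paste(signif(med, 4), collapse = ", "))
  probs <- c((1 - containment) / 2, (1 + containment) / 2)
  qs <- t(vapply(controls, stats::quantile, numeric(2), probs = probs,
                 names = FALSE))
  # boundary between classes k and k+1: midpoint of interval overlap or gap
  boundaries <- c((qs[1, 2] + qs[2, 1]) / 2, (qs[2, 2] + qs[3, 1]) / 2)
  if (diff(boundaries) <= 0)
    stop("degenerate gates: control distributions overlap too heavily")
  intervals <- rbind(c(0, boundaries[1]),
                     c(boundaries[1], boundaries[2]),
                     c(boundaries[2], Inf))
  rownames(intervals) <- c("copy0", "copy1", "copy2plus")
  colnames(intervals) <- c("lower", "upper")
  achieved <- vapply(seq_len(3L), function(k)
    mean(controls[[k]] > intervals[k, 1] & controls[[k]] <= intervals[k, 2]),
    numeric(1))
  names(achieved) <- rownames(intervals)
  structure(list(boundaries = boundaries, intervals = intervals,
                 achieved = achieved, containment = containment),
            class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("gate_set: boundaries at %.4g and %.4g\n",
              x$boundaries[1], x$boundaries[2]))
  cat(sprintf("  achieved containment (target >= %.2f): %s\n",
              x$containment,
              paste(sprintf("%s %.3f", names(x$achieved), x$achieved),
                    collapse = ", ")))
  invisible(x)
}

#' Classify cells into copy-number classes
#'
#' Assigns every cell to exactly one of the 0-, 1- or 2-or-more-copy gates
#' (the gates partition the positive axis, so fractions always sum to 1).
#'
#' @param values Per-cell normalized fluorescence (positive).
#' @param gates A [build_gates()] result.
#' @return List with `fractions` (named, sums to 1), `counts`, `n`, and
#'   `pct_cnv` (percentage of cells in the 2-or-more-copy gate).
#' @export
classify_cells <- function(values, gates) {
  stopifnot(inherits(gates, "gate_set"))
  if (!length(values)) stop("empty cell sample")
  if (any(!is.finite(values) | values <= 0))
    stop("fluorescence values must be finite and positive")
  cls <- findInterval(values, gates$boundaries, left.open = TRUE)
  counts <- tabulate(cls + 1L, nbins = 3L)
  names(counts) <- rownames(gates$intervals)
  fr <- counts / length(values)
  list(fractions = fr, counts = counts, n = length(values),
       pct_cnv = 100 * fr[["copy2plus"]])
}

#' Generations at which a population reaches 25/50/75% CNV loss
#'
#' For each loss threshold `q` (percent of cells that have lost the CNV),
#' finds the first generation at which the percentage of CNV-containing
#' cells drops to `100 - q`, linearly interpolating between the two
#' flanking observations. Thresholds never reached within the trajectory
#' are censored at the last observed generation (the horizon).
#'
#' @param generation,pct_cnv Observed trajectory: generations (increasing)
#'   and percent CNV-containing cells at each.
#' @param thresholds Loss percentages defining the phases (default
#'   `c(25, 50, 75)`, i.e. early/middle/late).
#' @param horizon Censoring horizon (default: last observed generation).
#' @return Data frame of class `phase_times` with columns `phase`,
#'   `threshold`, `generation`, `censored`, `horizon`.
#' @examples
#' phase_times(c(0, 12), c(100, 70))  # 25% loss at generation 10
#' @export
phase_times <- function(generation, pct_cnv, thresholds = c(25, 50, 75),
                        horizon = NULL) {
  stopifnot(length(generation) == length(pct_cnv), length(generation) >= 2,
            all(diff(generation) > 0), all(pct_cnv >= 0 & pct_cnv <= 100))
  if (is.null(horizon)) horizon <- max(generation)
  nm <- if (identical(sort(thresholds), c(25, 50, 75)))
    c("early", "middle", "late")[order(order(thresholds))]
  else paste0("loss", thresholds)
  out <- lapply(seq_along(thresholds), function(j) {
    target <- 100 - thresholds[j]
    hit <- which(pct_cnv <= target)
    if (!length(hit))
      return(data.frame(phase = nm[j], threshold = thresholds[j],
                        generation = NA_real_, censored = TRUE,
                        horizon = horizon))
    i <- hit[1L]
    g <- if (i == 1L || pct_cnv[i] == target) generation[i] else {
      p1 <- pct_cnv[i - 1L]; p2 <- pct_cnv[i]
      generation[i - 1L] +
        (generation[i] - generation[i - 1L]) * (p1 - target) / (p1 - p2)
    }
    data.frame(phase = nm[j], threshold = thresholds[j], generation = g,
               censored = FALSE, horizon = horizon)
  })
  res <- do.call(rbind, out)
  class(res) <- c("phase_times", "data.frame")
  res
}

#' Paired t-tests of CNV-loss phase times between two CNV types
#'
#' Pairs populations one-to-one by the `population` column and compares
#' each phase with a paired t-test on the per-pair differences. Censored
#' populations (``NA`` phase times) enter the test at the experiment
#' horizon, and the number substituted is reported; group medians are
#' computed over the observed (non-censored) populations only.
#'
#' @param groupA,groupB Data frames with a `population` column and one
#'   column per phase (e.g. `early`, `middle`, `late`), `NA` meaning
#'   censored.
#' @param horizon Value substituted for censored phase times (default
#'   220 generations).
#' @return Data frame with one row per phase: `phase`, `t`, `df`,
#'   `p_value`, `mean_diff` (A - B), `median_A`, `median_B`, `n_pairs`,
#'   `n_censored_A`, `n_censored_B`.
#' @export
compare_phase_times <- function(groupA, groupB, horizon = 220) {
  stopifnot("population" %in% names(groupA),
            "population" %in% names(groupB))
  unpaired <- c(setdiff(groupA$population, groupB$population),
                setdiff(groupB$population, groupA$population))
  if (length(unpaired))
    stop("unpaired population(s): ", paste(unique(unpaired), collapse = ", "))
  if (anyDuplicated(groupA$population) || anyDuplicated(groupB$population))
    stop("duplicate population labels")
  if (nrow(groupA) < 2L) stop("need at least 2 pairs")
  phases <- intersect(setdiff(names(groupA), "population"),
                      setdiff(names(groupB), "population"))
  if (!length(phases)) stop("no shared phase columns")
  B <- groupB[match(groupA$population, groupB$population), , drop = FALSE]
  out <- lapply(phases, function(ph) {
    a <- groupA[[ph]]; b <- B[[ph]]
    ca <- is.na(a); cb <- is.na(b)
    a[ca] <- horizon; b[cb] <- horizon
    d <- a - b
    if (stats::sd(d) == 0) {
      tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                 parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    data.frame(phase = ph, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               mean_diff = mean(d),
               median_A = stats::median(groupA[[ph]][!ca]),
               median_B = stats::median(B[[ph]][!cb]),
               n_pairs = length(d), n_censored_A = sum(ca),
               n_censored_B = sum(cb))
  })
  res <- do.call(rbind, out)
  attr(res, "horizon") <- horizon
  res
}

#' Ploidy-normalized copy-number track from sequencing depth
#'
#' Averages depth in fixed windows and divides by the genome-wide mean
#' depth, yielding the ploidy-normalized copy number (PNCN): 1 for regions
#' present at the strain's base ploidy, 2 for a duplicated region, and so
#' on. Windows use 0-based half-open coordinates; the track is invariant
#' to rescaling the depth by any constant.
#'
#' @param depth Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and `depth`, as read by [read_bedgraph()].
#' @param window Window size in bp. A window larger than a chromosome
#'   yields a single whole-chromosome window (with a warning).
#' @param ploidy Base ploidy of the strain (metadata; PNCN is already
#'   expressed per chromosome copy since the genome-wide mean scales with
#'   ploidy).
#' @return Data frame with columns `chrom`, `start`, `end`, `pncn`, and
#'   attribute `genome_mean_depth`.
#' @export
pncn_track <- function(depth, window = 1000, ploidy = 1) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(depth)),
            window >= 1, all(depth$depth >= 0), all(depth$end > depth$start))
  seqlens <- vapply(split(depth$end, depth$chrom), max, numeric(1))
  if (window > min(seqlens))
    warning("window exceeds the length of chromosome(s) ",
            paste(names(seqlens)[seqlens < window], collapse = ", "),
            "; using a single whole-chromosome window there")
  gr <- GenomicRanges::GRanges(
    depth$chrom, IRanges::IRanges(depth$start + 1L, depth$end))
  GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
  cov <- GenomicRanges::coverage(gr, weight = depth$depth)
  gmean <- sum(vapply(cov, function(r) sum(as.numeric(r)), numeric(1))) /
    sum(as.numeric(seqlens))
  if (gmean <= 0) stop("genome-wide mean depth must be positive")
  bins <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(gr),
                                    tilewidth = window,
                                    cut.last.tile.in.chrom = TRUE)
  binned <- GenomicRanges::binnedAverage(bins, cov, "mean_depth")
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(binned)),
    start = GenomicRanges::start(binned) - 1L,
    end = GenomicRanges::end(binned),
    pncn = binned$mean_depth / gmean,
    stringsAsFactors = FALSE)
  attr(out, "genome_mean_depth") <- gmean
  attr(out, "ploidy") <- ploidy
  out
}

#' Read or write depth/PNCN tracks as bedGraph
#'
#' Thin wrappers around `rtracklayer` import/export. The data frame
#' representation uses 0-based half-open `start`/`end` and a `depth`
#' column (the bedGraph score).
#'
#' @param path bedGraph file path.
#' @param track Data frame with `chrom`, `start`, `end` and a score column
#'   (`depth` or `pncn`).
#' @return `read_bedgraph()` returns the data frame; `write_bedgraph()`
#'   returns `path` invisibly.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             depth = gr$score, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  score_col <- intersect(c("depth", "pncn", "score"), names(track))[1]
  if (is.na(score_col)) stop("no score column (`depth`, `pncn` or `score`)")
  gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1L, track$end),
    score = track[[score_col]])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
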