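# Predicted fitness costs of segmental CNVs and aneuploidies from per-gene
# duplication-cost tables.
#
# The cost table gives, for each gene, the fitness cost of carrying one
# extra copy (log2 fold-change units) and whether that cost is significant
# at FDR < 0.05 in the source screen. The cost of an amplified region is
#
#   extra_copies * [ sum(costs of significant genes)
#                    + n_nonsignificant * mean_all_genes ]
#
# with extra_copies = copy_number - 1 and mean_all_genes the genome-wide
# average gene cost (-0.33 in the reference screen).

.check_cost_table <- function(table) {
  need <- c("gene", "cost")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cost table is missing columns: ", paste(miss, collapse = ", "))
  if (!"significant" %in% names(table)) {
    if (!"fdr" %in% names(table))
      stop("cost table needs a `significant` flag or an `fdr` column")
    table$significant <- table$fdr < 0.05
  }
  table
}

#' Total predicted fitness cost of an amplified region
#'
#' @param records Cost-table rows for the genes in the amplified region
#'   (columns `gene`, `cost`, and `significant` or `fdr`).
#' @param extra_copies Extra copies of the region per chromosome copy
#'   (`copy_number - 1`, `>= 0`).
#' @param mean_all_genes Genome-wide mean gene cost used for
#'   non-significant genes (default -0.33).
#' @return An object of class `cost_estimate`: list with `total_cost`,
#'   `n_significant`, `n_nonsignificant`, `mean_all_genes`,
#'   `extra_copies`.
#' @examples
#' tab <- data.frame(gene = letters[1:5], cost = c(-1.5, 0.2, 0, 0, 0),
#'                   significant = c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' total_cnv_cost(tab, extra_copies = 2)$total_cost # -4.58
#' @export
total_cnv_cost <- function(records, extra_copies, mean_all_genes = -0.33) {
  stopifnot(is.numeric(extra_copies), length(extra_copies) == 1L,
            extra_copies >= 0, is.finite(mean_all_genes))
  if (nrow(records) == 0L) {
    if (extra_copies > 0)
      warning("empty gene set for an amplified region; total cost is 0")
    return(structure(list(total_cost = 0, n_significant = 0L,
                          n_nonsignificant = 0L,
                          mean_all_genes = mean_all_genes,
                          extra_copies = extra_copies),
                     class = "cost_estimate"))
  }
  records <- .check_cost_table(records)
  sig <- records$significant %in% TRUE
  bracket <- sum(records$cost[sig]) + sum(!sig) * mean_all_genes
  structure(list(total_cost = extra_copies * bracket,
                 n_significant = sum(sig), n_nonsignificant = sum(!sig),
                 mean_all_genes = mean_all_genes,
                 extra_copies = extra_copies),
            class = "cost_estimate")
}

#' @export
print.cost_estimate <- function(x, ...) {
  cat(sprintf(paste0("predicted CNV cost: %.4f\n",
                     "  %d significant + %d non-significant genes ",
                     "(mean gene cost %.2f), %g extra cop%s\n"),
              x$total_cost, x$n_significant, x$n_nonsignificant,
              x$mean_all_genes, x$extra_copies,
              if (x$extra_copies == 1) "y" else "ies"))
  invisible(x)
}

#' Predicted fitness cost of whole-chromosome duplications
#'
#' A single aneuploidy costs [total_cnv_cost()] over all genes on the
#' chromosome with one extra copy; a double aneuploidy is the sum of the
#' two single-chromosome costs.
#'
#' @param table Full gene cost table with a `chromosome` column.
#' @param chromosomes One (single) or two (double) chromosome labels.
#' @param mean_all_genes Genome-wide mean gene cost.
#' @return A `cost_estimate`; for two chromosomes the `per_chromosome`
#'   field holds the individual costs.
#' @export
aneuploidy_cost <- function(table, chromosomes, mean_all_genes = -0.33) {
  table <- .check_cost_table(table)
  if (!"chromosome" %in% names(table))
    stop("cost table needs a `chromosome` column")
  stopifnot(length(chromosomes) %in% 1:2)
  known <- unique(table$chromosome)
  unknown <- setdiff(chromosomes, known)
  if (length(unknown))
    stop("chromosome label(s) not in table: ", paste(unknown, collapse = ", "))
  singles <- lapply(chromosomes, function(ch) {
    rec <- table[table$chromosome == ch, , drop = FALSE]
    if (nrow(rec) == 0L)
      warning("no genes on chromosome ", ch, " in the cost table")
    total_cnv_cost(rec, extra_copies = 1, mean_all_genes = mean_all_genes)
  })
  if (length(chromosomes) == 1L) return(singles[[1L]])
  out <- structure(list(
    total_cost = sum(vapply(singles, `[[`, numeric(1), "total_cost")),
    n_significant = sum(vapply(singles, `[[`, integer(1), "n_significant")),
    n_nonsignificant = sum(vapply(singles, `[[`, integer(1),
                                  "n_nonsignificant")),
    mean_all_genes = mean_all_genes, extra_copies = 1,
    per_chromosome = stats::setNames(
      vapply(singles, `[[`, numeric(1), "total_cost"), chromosomes)),
    class = "cost_estimate")
  out
}

#' Genome-wide mean gene-duplication cost
#'
#' @param table Full cost table (`cost` column); `NA` costs are excluded
#'   and counted.
#' @return The arithmetic mean over all genes, with attribute
#'   `n_missing`.
#' @export
mean_gene_cost <- function(table) {
  if (!nrow(table)) stop("cost table is empty")
  cost <- table$cost
  n_missing <- sum(is.na(cost))
  if (n_missing)
    message(n_missing, " gene(s) with missing cost excluded from the mean")
  structure(mean(cost, na.rm = TRUE), n_missing = n_missing)
}

#' Pearson correlation between predicted cost and measured fitness
#'
#' Computes the Pearson correlation coefficient with a 95% confidence
#' interval, by default from a bias-corrected bootstrap over pairs (which
#' accommodates the asymmetric sampling distribution of r); the Fisher
#' z-transform interval is available as an alternative.
#'
#' @param cost Predicted CNV costs.
#' @param fitness Measured relative fitness, paired with `cost`.
#' @param method `"bootstrap"` (bias-corrected percentile) or `"fisher"`.
#' @param n_boot Bootstrap resamples (default 10,000).
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `r`, `ci` (length 2), `method`, `n`.
#' @export
pearson_cost_fitness <- function(cost, fitness,
                                 method = c("bootstrap", "fisher"),
                                 n_boot = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(cost) == length(fitness), length(cost) >= 3,
            all(is.finite(cost)), all(is.finite(fitness)))
  if (stats::sd(cost) == 0 || stats::sd(fitness) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(cost, fitness)
  n <- length(cost)
  if (method == "fisher") {
    z <- atanh(r)
    hw <- stats::qnorm(0.975) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    xb <- matrix(cost[idx], n_boot, n)
    yb <- matrix(fitness[idx], n_boot, n)
    xc <- xb - rowMeans(xb)
    yc <- yb - rowMeans(yb)
    denom <- sqrt(rowSums(xc^2) * rowSums(yc^2))
    rb <- rowSums(xc * yc) / denom
    rb <- rb[is.finite(rb)]
    # bias-corrected percentile interval
    z0 <- stats::qnorm(mean(rb < r))
    probs <- stats::pnorm(2 * z0 + stats::qnorm(c(0.025, 0.975)))
    ci <- unname(stats::quantile(rb, probs))
  }
  list(r = r, ci = ci, method = method, n = n)
}

#' Read a gene-duplication cost table from CSV/TSV
#'
#' Expects columns `gene`, `chromosome`, `start`, `end`, `cost` and either
#' `fdr` or `significant`.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` for tab, otherwise comma).
#' @return Data frame with a logical `significant` column.
#' @export
read_cost_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .check_cost_table(df)
}

#' Genes of a cost table wholly contained in a genomic region
#'
#' Region membership uses 0-based half-open coordinates as in BED: a gene
#' counts when `start >= region_start` and `end <= region_end` on the same
#' chromosome. Genes straddling a breakpoint are excluded.
#'
#' @param table Cost table with `chromosome`, `start`, `end` columns.
#' @param chromosome Chromosome label of the region.
#' @param region_start,region_end Region bounds (0-based half-open).
#' @return The subset of `table` inside the region.
#' @export
genes_in_region <- function(table, chromosome, region_start, region_end) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(table)),
            region_start < region_end)
  table[table$chromosome == chromosome & table$start >= region_start &
          table$end <= region_end, , drop = FALSE]
}
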