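# Per-gene median-split relapse-free-survival screen with Bonferroni
# family-wise error control: for each gene, patients are dichotomized at
# the cohort median of its expression, groups are compared by the log-rank
# test, and the hazard ratio (high vs low) comes from a univariate Cox fit
# on the group indicator.

#' Median split of an expression vector
#'
#' Patients at or below the median go to the `low` group; strictly above
#' to `high`. With even n and no ties at the median the groups are equal
#' sized. The partition depends only on values, not input order.
#'
#' @param expr_vector Numeric vector, length >= 4.
#' @return Character vector of `"low"`/`"high"` labels, or `NULL` (with a
#'   warning) for a constant vector.
#' @export
median_split <- function(expr_vector) {
  if (length(expr_vector) < 4) stop("need at least 4 patients")
  if (diff(range(expr_vector)) == 0) {
    warning("constant expression; gene cannot be split")
    return(NULL)
  }
  ifelse(expr_vector <= median(expr_vector), "low", "high")
}

#' Screen a single gene for survival association
#'
#' @param expr_vector Per-patient expression of one gene, aligned with the
#'   cohort.
#' @param cohort A [survival_cohort].
#' @param gene_id Optional label carried into the record.
#' @return One-row `screen_record` data.frame: `gene_id`, `hr` (high vs
#'   low), `ci_low`, `ci_high`, `logrank_p`, `prognosis_class`
#'   (`favorable` if hr < 1, `adverse` otherwise), or `NULL` when the gene
#'   is skipped (constant expression).
#' @export
screen_gene <- function(expr_vector, cohort, gene_id = "gene") {
  stopifnot(inherits(cohort, "survival_cohort"),
            length(expr_vector) == length(cohort$time))
  grp <- median_split(expr_vector)
  if (is.null(grp) || length(unique(grp)) < 2) return(NULL)
  lr <- logrank_test(cohort$time, cohort$event, grp)
  fit <- cox_fit(as.numeric(grp == "high"), cohort$time, cohort$event)
  data.frame(gene_id = gene_id, hr = unname(fit$hr),
             ci_low = unname(fit$ci95[1, 1]),
             ci_high = unname(fit$ci95[1, 2]),
             logrank_p = lr$p,
             prognosis_class = if (fit$hr < 1) "favorable" else "adverse",
             row.names = NULL)
}

#' Screen every gene in a matrix against survival
#'
#' Applies [screen_gene()] per gene and marks significance at the
#' Bonferroni level `alpha / m`, where `m` is the number of genes actually
#' tested (constant genes are skipped and do not enter the denominator).
#'
#' @param matrix An [expr_matrix] whose columns are the cohort patients.
#' @param cohort A [survival_cohort].
#' @param alpha Family-wise error level before correction.
#' @return A `screen_table` data.frame of screen records with a
#'   `significant` flag; attributes carry `threshold` (`alpha/m`), `m`,
#'   `skipped`, and a `summary` vector `(n_significant, n_hr_lt_1,
#'   n_hr_gt_1)` over the significant genes.
#' @export
screen_all <- function(matrix, cohort, alpha = 0.05) {
  stopifnot(inherits(matrix, "expr_matrix"),
            ncol(matrix$values) == length(cohort$time))
  if (nrow(matrix$values) < 1) stop("need at least one gene")
  recs <- lapply(rownames(matrix$values), function(g)
    suppressWarnings(screen_gene(matrix$values[g, ], cohort, g)))
  skipped <- rownames(matrix$values)[vapply(recs, is.null, logical(1))]
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no screenable genes")
  m <- nrow(out)
  thr <- alpha / m
  out$significant <- out$logrank_p < thr
  attr(out, "threshold") <- thr
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "skipped") <- skipped
  attr(out, "summary") <- c(
    n_significant = sum(out$significant),
    n_hr_lt_1 = sum(out$significant & out$hr < 1),
    n_hr_gt_1 = sum(out$significant & out$hr > 1))
  class(out) <- c("screen_table", "data.frame")
  out
}

#' @export
print.screen_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<screen_table> %d gene(s) screened, Bonferroni threshold %.3g\n  significant: %d (HR<1: %d, HR>1: %d)%s\n",
    attr(x, "m"), attr(x, "threshold"), s["n_significant"],
    s["n_hr_lt_1"], s["n_hr_gt_1"],
    if (length(attr(x, "skipped")))
      sprintf("; skipped: %d", length(attr(x, "skipped"))) else ""))
  invisible(x)
}
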