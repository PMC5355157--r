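#' Expression matrix container
#'
#' A features x samples log2-scale expression matrix with per-sample class
#' labels. The whole pipeline standardises on log2-scale values, so a
#' between-class mean difference of `d` corresponds to a linear fold change
#' of `2^d`.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Must carry unique rownames (feature ids) and colnames (sample ids)
#'   or they are supplied via `feature_ids`/`sample_ids`.
#' @param sample_class Character/factor of length `ncol(values)` with
#'   levels among `"tumor"`, `"normal"`, `"unlabeled"`.
#' @param feature_ids,sample_ids Optional id vectors overriding dimnames.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `feature_ids`, `sample_ids`, `sample_class`.
#' @export
expr_matrix <- function(values, sample_class = NULL,
                        feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature and sample ids")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(sample_class)) sample_class <- rep("unlabeled", ncol(values))
  sample_class <- as.character(sample_class)
  if (length(sample_class) != ncol(values))
    stop("sample_class length must equal number of samples")
  bad <- setdiff(unique(sample_class), c("tumor", "normal", "unlabeled"))
  if (length(bad))
    stop("unknown sample_class label(s): ", paste(bad, collapse = ", "))
  structure(
    list(values = values,
         feature_ids = rownames(values),
         sample_ids = colnames(values),
         sample_class = sample_class),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cls <- table(x$sample_class)
  cat(sprintf("<expr_matrix> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Restrict an expr_matrix to a subset of samples (by index or id).
subset_samples <- function(x, idx) {
  v <- x$values[, idx, drop = FALSE]
  expr_matrix(v, sample_class = x$sample_class[idx])
}

#' Survival cohort container
#'
#' Couples per-patient follow-up with an expression slice and optional
#' clinical covariates. Expression columns, outcome entries and covariate
#' rows refer to the same patients in the same order.
#'
#' @param time Positive follow-up times (any consistent unit).
#' @param event Event indicator, 0 = censored, 1 = event.
#' @param expression An [expr_matrix] whose columns are the cohort patients.
#' @param covariates Optional data.frame of per-patient clinical covariates
#'   (e.g. age, stage, ER, PR, subtype), rownames = patient ids.
#'
#' @return Object of class `survival_cohort`.
#' @export
survival_cohort <- function(time, event, expression, covariates = NULL) {
  stopifnot(inherits(expression, "expr_matrix"))
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != ncol(expression$values) ||
      length(event) != length(time))
    stop("time/event length must match number of patients")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("follow-up times must be strictly positive")
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0/1")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(time))
      stop("covariates must have one row per patient")
    rownames(covariates) <- expression$sample_ids
  }
  structure(
    list(time = time, event = event,
         patient_ids = expression$sample_ids,
         expression = expression, covariates = covariates),
    class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf(
    "<survival_cohort> %d patients, %d events (%.1f%%), %d features%s\n",
    length(x$time), sum(x$event), 100 * mean(x$event),
    nrow(x$expression$values),
    if (is.null(x$covariates)) ""
    else sprintf(", covariates: %s", paste(names(x$covariates), collapse = ", "))))
  invisible(x)
}

# Restrict a cohort to a patient subset, preserving order of idx.
subset_cohort <- function(cohort, idx) {
  survival_cohort(
    time = cohort$time[idx],
    event = cohort$event[idx],
    expression = subset_samples(cohort$expression, idx),
    covariates = if (is.null(cohort$covariates)) NULL
                 else cohort$covariates[idx, , drop = FALSE])
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d DE features, %d block(s), %d negative hub(s), %d signature gene(s)\n",
    length(x$de_features),
    length(setdiff(unique(x$block_assignments), 0L)),
    length(x$negative_hubs), length(x$signature_genes)))
  invisible(x)
}
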