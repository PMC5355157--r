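# Plain-text interchange: expression / class / survival TSVs, signature
# JSON, and planted-truth JSON. All writers round-trip through the
# matching readers.

#' Write / read an expression matrix TSV
#'
#' First column `feature_id`, remaining columns one per sample. The sample
#' class travels in a companion two-column TSV (`sample_id`, `class`).
#'
#' @param matrix An [expr_matrix].
#' @param path Expression TSV path.
#' @param class_path Optional sample-class TSV path.
#' @return `path`, invisibly (writer); an [expr_matrix] (reader).
#' @export
write_expression_tsv <- function(matrix, path, class_path = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(feature_id = matrix$feature_ids, matrix$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(class_path))
    write.table(data.frame(sample_id = matrix$sample_ids,
                           class = matrix$sample_class),
                class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, class_path = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  cls <- NULL
  if (!is.null(class_path)) {
    cdf <- read.delim(class_path, stringsAsFactors = FALSE)
    cls <- cdf$class[match(colnames(vals), cdf$sample_id)]
  }
  expr_matrix(vals, sample_class = cls)
}

#' Write / read a survival cohort TSV
#'
#' Columns `patient_id`, `time`, `event`, then any covariates. Expression
#' goes in its own TSV via [write_expression_tsv()]; the reader joins the
#' two on patient id.
#'
#' @param cohort A [survival_cohort].
#' @param path Survival TSV path.
#' @param expression An [expr_matrix] to attach on read.
#' @return `path`, invisibly (writer); a [survival_cohort] (reader).
#' @export
write_survival_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "survival_cohort"))
  df <- data.frame(patient_id = cohort$patient_ids, time = cohort$time,
                   event = cohort$event)
  if (!is.null(cohort$covariates)) df <- cbind(df, cohort$covariates)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path, expression) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "time", "event") %in% names(df)))
  idx <- match(expression$sample_ids, df$patient_id)
  if (anyNA(idx)) stop("patients in expression matrix missing from survival table")
  df <- df[idx, , drop = FALSE]
  covs <- df[, setdiff(names(df), c("patient_id", "time", "event")),
             drop = FALSE]
  survival_cohort(df$time, df$event, expression,
                  covariates = if (ncol(covs)) covs else NULL)
}

#' Write / read a signature model as JSON
#'
#' Serializes genes, averaged betas, per-split betas, selection
#' frequencies, the cutpoint, and provenance (plan seed, frequency
#' threshold) so a score computed from the JSON reproduces the in-memory
#' score to machine precision.
#'
#' @param model A `signature_model`.
#' @param path JSON path.
#' @return `path`, invisibly (writer); a `signature_model` (reader).
#' @export
write_signature_json <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  obj <- list(genes = model$genes,
              beta_mean = as.list(setNames(model$beta_mean, model$genes)),
              cutpoint = model$cutpoint,
              selection_freq = if (is.null(model$selection_freq)) NULL
                               else as.list(model$selection_freq),
              beta_per_split = model$beta_per_split,
              freq_threshold = model$freq_threshold,
              plan_seed = model$plan_seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bps <- obj$beta_per_split
  if (!is.null(bps)) {
    bps <- as.matrix(bps)
    colnames(bps) <- obj$genes
  }
  structure(list(genes = obj$genes,
                 beta_mean = unlist(obj$beta_mean)[obj$genes],
                 cutpoint = obj$cutpoint,
                 selection_freq = if (is.null(obj$selection_freq)) NULL
                                  else unlist(obj$selection_freq),
                 beta_per_split = bps,
                 freq_threshold = obj$freq_threshold,
                 plan_seed = obj$plan_seed),
            class = "signature_model")
}

#' Write planted simulation truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- list(de_features = as.list(truth$de_features),
              block_assignments = as.list(truth$block_assignments),
              negative_hubs = truth$negative_hubs,
              signature_genes = truth$signature_genes,
              signature_betas = as.list(truth$signature_betas))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
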