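# Prognostic-score computation and validation: per-test-set forest
# statistics, external-cohort scoring, multivariate forced-entry Cox with
# clinical covariates, and subtype-stratified survival.

#' Per-patient prognostic score
#'
#' The weighted expression sum `score_i = sum_g beta_mean_g * x_{g,i}` --
#' exact linear arithmetic, no rescaling. All signature genes must be
#' present; missing genes are an error, never silently imputed.
#'
#' @param matrix An [expr_matrix].
#' @param model A completed `signature_model` (or any list with `genes`
#'   and `beta_mean`).
#' @return Named numeric vector of scores, ordered like the matrix
#'   columns.
#' @export
prognostic_score <- function(matrix, model) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (is.null(model$beta_mean)) stop("model has no fitted coefficients")
  miss <- setdiff(model$genes, matrix$feature_ids)
  if (length(miss))
    stop("signature gene(s) missing from matrix: ",
         paste(miss, collapse = ", "))
  colSums(matrix$values[model$genes, , drop = FALSE] * model$beta_mean)
}

#' Forest statistics over the plan's test sets
#'
#' For every resample, patients in the test set are scored, dichotomized
#' at the model cutpoint (the averaged training-median score), and
#' compared by log-rank and by a Cox fit on the high-vs-low indicator.
#' Rows where the cutpoint leaves a group empty (or the group has no
#' events) are flagged and excluded from the summary.
#'
#' @param matrix,cohort,plan As in [select_signature()]; the model must
#'   have been fitted from the same plan's training halves.
#' @param model Completed `signature_model`.
#' @return Object of class `forest_table`: `rows` (split, n_test, hr,
#'   ci_low, ci_high, logrank_p, ok) and `frac_ci_crossing_1` over the
#'   valid rows.
#' @export
evaluate_test_sets <- function(matrix, cohort, model, plan) {
  .check_aligned(matrix, cohort)
  stopifnot(inherits(plan, "split_plan"), !is.null(model$cutpoint))
  scores <- prognostic_score(matrix, model)
  rows <- lapply(seq_len(plan$k), function(r) {
    te <- plan$test[[r]]
    grp <- ifelse(scores[te] > model$cutpoint, "high", "low")
    row <- data.frame(split = r, n_test = length(te), hr = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      logrank_p = NA_real_, ok = FALSE)
    if (length(unique(grp)) < 2 || sum(cohort$event[te]) == 0) return(row)
    fit <- tryCatch(
      suppressWarnings(cox_fit(as.numeric(grp == "high"),
                               cohort$time[te], cohort$event[te])),
      error = function(e) NULL)
    lr <- tryCatch(logrank_test(cohort$time[te], cohort$event[te], grp),
                   error = function(e) NULL)
    if (is.null(fit) || is.null(lr) || anyNA(fit$se)) return(row)
    row$hr <- unname(fit$hr)
    row$ci_low <- unname(fit$ci95[1, 1])
    row$ci_high <- unname(fit$ci95[1, 2])
    row$logrank_p <- lr$p
    row$ok <- TRUE
    row
  })
  rows <- do.call(rbind, rows)
  valid <- rows[rows$ok, , drop = FALSE]
  if (nrow(valid) < nrow(rows))
    warning(sprintf("%d test set(s) flagged and excluded from the summary",
                    nrow(rows) - nrow(valid)))
  frac <- if (nrow(valid)) mean(valid$ci_low <= 1 & valid$ci_high >= 1)
          else NA_real_
  structure(list(rows = rows, frac_ci_crossing_1 = frac,
                 n_valid = nrow(valid)),
            class = "forest_table")
}

#' @export
print.forest_table <- function(x, ...) {
  cat(sprintf(
    "<forest_table> %d test set(s) (%d valid); CI crossing 1: %.1f%%\n",
    nrow(x$rows), x$n_valid, 100 * x$frac_ci_crossing_1))
  invisible(x)
}

#' Score and validate the signature on an independent cohort
#'
#' Scores all patients, splits the cohort into two equal-sized groups at
#' the cohort median score (ties to the low group), and reports KM curves,
#' the log-rank test, and the Cox hazard ratio of high vs low. With
#' `refit_betas = TRUE`, the coefficients are first re-estimated on this
#' cohort by forced-entry Cox on the signature genes -- the usual
#' procedure when transferring a signature onto a platform with a
#' different expression scale (e.g. z-scored RNA-seq).
#'
#' @param matrix An [expr_matrix] over the cohort patients.
#' @param cohort A [survival_cohort].
#' @param model Completed `signature_model`.
#' @param refit_betas Re-estimate betas on this cohort before scoring.
#' @return Object of class `score_report`: `scores`, `group`, `cutpoint`
#'   (the cohort median), `km_low`, `km_high`, `logrank_p`, `cox_hr`,
#'   `ci95`, `betas_used`, `refit`.
#' @export
validate_external <- function(matrix, cohort, model, refit_betas = FALSE) {
  .check_aligned(matrix, cohort)
  betas <- model$beta_mean
  if (refit_betas) {
    fit <- cox_fit(t(matrix$values[model$genes, , drop = FALSE]),
                   cohort$time, cohort$event)
    betas <- fit$beta
  }
  m2 <- list(genes = model$genes, beta_mean = betas)
  scores <- prognostic_score(matrix, m2)
  cut <- median(scores)
  grp <- ifelse(scores > cut, "high", "low")
  if (length(unique(grp)) < 2)
    stop("median split left one score group empty")
  lr <- logrank_test(cohort$time, cohort$event, grp)
  fit_g <- cox_fit(as.numeric(grp == "high"), cohort$time, cohort$event)
  structure(list(
    scores = scores, group = grp, cutpoint = cut,
    km_low = km_estimate(cohort$time[grp == "low"],
                         cohort$event[grp == "low"]),
    km_high = km_estimate(cohort$time[grp == "high"],
                          cohort$event[grp == "high"]),
    logrank_p = lr$p, cox_hr = unname(fit_g$hr),
    ci95 = unname(fit_g$ci95[1, ]), betas_used = betas,
    refit = refit_betas),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(
    "<score_report> %d patients; high vs low HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g%s\n",
    length(x$scores), x$cox_hr, x$ci95[1], x$ci95[2], x$logrank_p,
    if (x$refit) " [betas refit on this cohort]" else ""))
  invisible(x)
}

#' Multivariate forced-entry Cox with clinical covariates
#'
#' Single forced-entry Cox fit of the score group together with clinical
#' covariates. Factors and ordered factors are expanded to reference-coded
#' dummies (first/lowest level as reference, e.g. stage I); character
#' columns are treated as factors. Rows with missing values are dropped
#' (complete-case) and counted. Collinear dummy columns are an error
#' naming the offending terms.
#'
#' @param scores Per-patient prognostic scores.
#' @param cohort_covariates Data.frame of clinical covariates aligned with
#'   `scores`.
#' @param time,event Outcome vectors.
#' @param cutpoint Score dichotomization point (default: median of
#'   `scores`); set to `NULL` to enter the continuous score.
#' @return Data.frame with one row per model term: `term`, `beta`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `p`; attributes `n_used`, `n_dropped`,
#'   `fit`.
#' @export
multivariate_validate <- function(scores, cohort_covariates, time, event,
                                  cutpoint = median(scores)) {
  cov <- as.data.frame(cohort_covariates)
  stopifnot(length(scores) == nrow(cov), length(time) == length(scores))
  score_term <- if (is.null(cutpoint)) scores
                else as.numeric(scores > cutpoint)
  dat <- cbind(score_group = score_term, cov)
  cc <- complete.cases(dat) & !is.na(time) & !is.na(event)
  n_drop <- sum(!cc)
  if (n_drop) message(sprintf("%d row(s) with missing values dropped", n_drop))
  dat <- dat[cc, , drop = FALSE]
  for (j in names(dat))
    if (is.character(dat[[j]])) dat[[j]] <- factor(dat[[j]])
  mm <- model.matrix(~ ., data = dat,
                     contrasts.arg = lapply(
                       Filter(is.factor, dat),
                       function(f) "contr.treatment"))
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  fit <- cox_fit(mm, time[cc], event[cc])
  out <- data.frame(term = names(fit$beta), beta = unname(fit$beta),
                    se = unname(fit$se), hr = unname(fit$hr),
                    ci_low = unname(fit$ci95[, 1]),
                    ci_high = unname(fit$ci95[, 2]),
                    p = unname(fit$p), row.names = NULL)
  attr(out, "n_used") <- sum(cc)
  attr(out, "n_dropped") <- n_drop
  attr(out, "fit") <- fit
  out
}

#' Subtype-stratified survival by prognostic score
#'
#' Stratifies patients by molecular subtype and compares high- vs
#' low-score groups within each subtype by log-rank. `mode = "global-cut"`
#' dichotomizes once at the whole-cohort median score;
#' `mode = "within-subtype"` recomputes the median inside each subtype
#' (the sensitivity check against unequal group sizes). Subtypes with
#' fewer than 2 patients per group, or without events, are skipped with a
#' warning.
#'
#' @param scores Per-patient prognostic scores.
#' @param subtype_labels Per-patient subtype labels.
#' @param time,event Outcome vectors.
#' @param mode `"global-cut"` or `"within-subtype"`.
#' @return Data.frame with `subtype`, `n`, `n_low`, `n_high`, `chi2`,
#'   `logrank_p`, `skipped`.
#' @export
subtype_stratified <- function(scores, subtype_labels, time, event,
                               mode = c("global-cut", "within-subtype")) {
  mode <- match.arg(mode)
  stopifnot(length(scores) == length(subtype_labels),
            length(scores) == length(time))
  subtype_labels <- as.character(subtype_labels)
  global_cut <- median(scores)
  rows <- lapply(sort(unique(subtype_labels)), function(s) {
    idx <- subtype_labels == s
    cut <- if (mode == "global-cut") global_cut else median(scores[idx])
    grp <- ifelse(scores[idx] > cut, "high", "low")
    row <- data.frame(subtype = s, n = sum(idx),
                      n_low = sum(grp == "low"), n_high = sum(grp == "high"),
                      chi2 = NA_real_, logrank_p = NA_real_, skipped = TRUE)
    if (min(table(factor(grp, levels = c("low", "high")))) < 2 ||
        sum(event[idx]) == 0) {
      warning(sprintf("subtype '%s' skipped (too few patients per group or no events)", s))
      return(row)
    }
    lr <- logrank_test(time[idx], event[idx], grp)
    row$chi2 <- lr$chi2
    row$logrank_p <- lr$p
    row$skipped <- FALSE
    row
  })
  do.call(rbind, rows)
}
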