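# Resampling stability selection of a prognostic signature: repeated
# train/test splits, forward-conditional Cox selection per training set,
# frequency-thresholded gene inclusion, then forced-entry refits whose
# coefficients are averaged into the final weighting.

#' Plan repeated train/test splits
#'
#' Each of `k` resamples draws `n_train` patients uniformly without
#' replacement; the complement forms the test set. Resamples are
#' independent given the seed.
#'
#' @param n_patients Cohort size.
#' @param n_train Training-set size (0 < n_train < n_patients).
#' @param k Number of resamples.
#' @param seed Integer seed.
#' @return Object of class `split_plan`: `k`, `n_patients`, `n_train`,
#'   `train` / `test` (lists of index vectors), `seed`.
#' @export
make_splits <- function(n_patients, n_train, k, seed) {
  stopifnot(k >= 1)
  if (!(n_train > 0 && n_train < n_patients))
    stop("need 0 < n_train < n_patients")
  with_seed(seed, {
    train <- lapply(seq_len(k), function(i)
      sort(sample.int(n_patients, n_train)))
    test <- lapply(train, function(tr) setdiff(seq_len(n_patients), tr))
    structure(list(k = k, n_patients = n_patients, n_train = n_train,
                   train = train, test = test, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d resample(s) of %d/%d train/test from %d patients (seed %s)\n",
              x$k, x$n_train, x$n_patients - x$n_train, x$n_patients,
              format(x$seed)))
  invisible(x)
}

.check_aligned <- function(matrix, cohort) {
  stopifnot(inherits(matrix, "expr_matrix"),
            inherits(cohort, "survival_cohort"))
  if (!identical(matrix$sample_ids, cohort$patient_ids))
    stop("matrix samples and cohort patients must match in order")
}

#' Stability selection of signature genes
#'
#' Runs [cox_forward_conditional()] over the candidate genes on every
#' training split and tallies, for each candidate, the fraction of splits
#' that selected it. Genes selected in strictly more than
#' `freq_threshold` of the (successful) splits form the signature. Splits
#' whose stepwise run fails outright are dropped from the frequency
#' denominator with a warning.
#'
#' @param matrix An [expr_matrix] over the cohort patients.
#' @param cohort A [survival_cohort].
#' @param candidates Candidate gene ids (rows of `matrix`).
#' @param plan A [make_splits()] plan for the cohort.
#' @param p_enter,p_remove Stepwise thresholds (see
#'   [cox_forward_conditional()]).
#' @param freq_threshold Inclusion needs selection frequency strictly
#'   above this ("more than half" at the 0.5 default).
#' @param ties Tie correction.
#' @return Object of class `signature_model` with `genes` (ordered by
#'   decreasing frequency), `selection_freq` (all candidates),
#'   `k_effective`, `freq_threshold`, `per_split_selected`. Coefficients
#'   are added by [fit_signature_betas()].
#' @export
select_signature <- function(matrix, cohort, candidates, plan,
                             p_enter = 0.05, p_remove = 0.10,
                             freq_threshold = 0.5, ties = "efron") {
  .check_aligned(matrix, cohort)
  stopifnot(inherits(plan, "split_plan"),
            plan$n_patients == length(cohort$time))
  miss <- setdiff(candidates, matrix$feature_ids)
  if (length(miss)) stop("candidates not in matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  Xall <- t(matrix$values[candidates, , drop = FALSE])
  sel_list <- vector("list", plan$k)
  ok <- logical(plan$k)
  for (r in seq_len(plan$k)) {
    tr <- plan$train[[r]]
    res <- tryCatch(
      suppressWarnings(cox_forward_conditional(
        Xall[tr, , drop = FALSE], cohort$time[tr], cohort$event[tr],
        p_enter = p_enter, p_remove = p_remove, ties = ties)),
      error = function(e) NULL)
    if (is.null(res)) next
    sel_list[[r]] <- res$trace$selected
    ok[r] <- TRUE
  }
  if (!any(ok)) stop("stepwise selection failed on every split")
  if (any(!ok))
    warning(sprintf("%d split(s) failed and were dropped from the denominator",
                    sum(!ok)))
  k_eff <- sum(ok)
  counts <- table(factor(unlist(sel_list[ok]), levels = candidates))
  freq <- setNames(as.numeric(counts) / k_eff, candidates)
  genes <- names(sort(freq[freq > freq_threshold], decreasing = TRUE))
  structure(list(genes = genes, selection_freq = freq,
                 k_effective = k_eff, freq_threshold = freq_threshold,
                 per_split_selected = sel_list,
                 beta_mean = NULL, beta_per_split = NULL, cutpoint = NULL,
                 plan_seed = plan$seed),
            class = "signature_model")
}

#' Averaged forced-entry coefficients and score cutpoint
#'
#' For each split, the signature genes are refit jointly by forced-entry
#' Cox on the training patients; the per-split coefficient vectors are
#' averaged into `beta_mean`, the model's weighting. Per-split training
#' prognostic scores (weighted by `beta_mean`) give per-split median
#' cutpoints, whose mean is the model cutpoint used to dichotomize test
#' sets. A gene that cannot be fit (e.g. constant in a training set) in
#' more than 20% of splits is dropped with a warning.
#'
#' @param matrix,cohort,plan As in [select_signature()].
#' @param genes Signature gene ids, or a `signature_model` from
#'   [select_signature()] to complete.
#' @param ties Tie correction.
#' @return A completed `signature_model`: `genes`, `beta_mean`,
#'   `beta_per_split` (k x genes, `NA` for failed splits), `cutpoint`.
#' @export
fit_signature_betas <- function(matrix, cohort, genes, plan,
                                ties = "efron") {
  .check_aligned(matrix, cohort)
  stopifnot(inherits(plan, "split_plan"))
  model <- NULL
  if (inherits(genes, "signature_model")) {
    model <- genes
    genes <- model$genes
  }
  if (!length(genes)) stop("empty signature")
  miss <- setdiff(genes, matrix$feature_ids)
  if (length(miss)) stop("genes not in matrix: ", paste(miss, collapse = ", "))
  B <- matrix(NA_real_, plan$k, length(genes),
              dimnames = list(NULL, genes))
  for (r in seq_len(plan$k)) {
    tr <- plan$train[[r]]
    Xtr <- t(matrix$values[genes, tr, drop = FALSE])
    usable <- apply(Xtr, 2, function(col) diff(range(col)) > 0)
    if (!any(usable)) next
    fit <- tryCatch(
      suppressWarnings(cox_fit(Xtr[, usable, drop = FALSE],
                               cohort$time[tr], cohort$event[tr],
                               ties = ties)),
      error = function(e) NULL)
    if (!is.null(fit)) B[r, usable] <- fit$beta
  }
  fail_frac <- colMeans(is.na(B))
  if (any(fail_frac > 0.2)) {
    dropped <- genes[fail_frac > 0.2]
    warning("gene(s) failing in >20% of splits dropped: ",
            paste(dropped, collapse = ", "))
    genes <- setdiff(genes, dropped)
    if (!length(genes)) stop("no signature gene survived the refits")
    B <- B[, genes, drop = FALSE]
  }
  beta_mean <- colMeans(B, na.rm = TRUE)
  cuts <- vapply(seq_len(plan$k), function(r) {
    if (all(is.na(B[r, ]))) return(NA_real_)
    sc <- colSums(matrix$values[genes, plan$train[[r]], drop = FALSE] *
                    beta_mean)
    median(sc)
  }, numeric(1))
  out <- model %||% structure(list(selection_freq = NULL,
                                   k_effective = NULL,
                                   freq_threshold = NULL,
                                   per_split_selected = NULL,
                                   plan_seed = plan$seed),
                              class = "signature_model")
  out$genes <- genes
  out$beta_mean <- beta_mean
  out$beta_per_split <- B
  out$cutpoint <- mean(cuts, na.rm = TRUE)
  out
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d gene(s)%s\n", length(x$genes),
              if (is.null(x$beta_mean)) " (betas not fitted)"
              else sprintf(", cutpoint %.4f", x$cutpoint)))
  if (!is.null(x$beta_mean)) {
    df <- data.frame(gene = x$genes, beta_mean = round(x$beta_mean, 4))
    if (!is.null(x$selection_freq))
      df$selection_freq <- x$selection_freq[x$genes]
    print(df, row.names = FALSE)
  } else if (length(x$genes)) {
    cat(" ", paste(x$genes, collapse = ", "), "\n")
  }
  invisible(x)
}
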