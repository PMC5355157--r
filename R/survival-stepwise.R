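#' Forward-conditional stepwise Cox covariate selection
#'
#' SPSS-style "forward conditional" selection for a Cox model: at each
#' iteration the excluded covariate with the smallest Rao score-test
#' p-value enters if that p-value is below `p_enter`; after every entry,
#' each included covariate is retested by a likelihood-ratio test against
#' the model without it and the worst is removed while its p-value exceeds
#' `p_remove`. Selection stops when no entry qualifies, when `max_steps`
#' is reached, or when a model state repeats (cycling guard).
#'
#' @param X_candidates Patients x candidates matrix with column names.
#'   Constant candidates are skipped. Candidates whose entry makes the fit
#'   fail (collinearity, separation) are dropped from further consideration.
#' @param time,event Follow-up and 0/1 indicator.
#' @param p_enter,p_remove Entry / removal thresholds; requires
#'   `0 < p_enter <= p_remove < 1` to guard stepping cycles.
#' @param max_steps Cap on total enter+remove actions.
#' @param ties Tie correction passed to [cox_fit()].
#' @return List with `trace` (class `stepwise_trace`: `selected`, `steps`
#'   data.frame with action/covariate/stat/p, `stopped`) and `fit`
#'   (final [cox_fit()] refit, or `NULL` for an empty model).
#' @export
cox_forward_conditional <- function(X_candidates, time, event,
                                    p_enter = 0.05, p_remove = 0.10,
                                    max_steps = 200, ties = "efron") {
  X <- as.matrix(X_candidates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 1) stop("need at least one candidate")
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove < 1))
    stop("need 0 < p_enter <= p_remove < 1")
  time <- as.numeric(time)
  event <- as.numeric(event)

  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  eligible <- colnames(X)[!const]
  Xc <- sweep(X, 2, colMeans(X))
  prep <- .cox_prep(time, event)
  Xs <- Xc[prep$o, , drop = FALSE]

  included <- character(0)
  fit <- NULL
  steps <- list()
  visited <- character(0)
  stopped <- "no_entry"
  sig <- function(s) paste(sort(s), collapse = "|")
  n_actions <- 0

  refit <- function(cols) {
    f <- tryCatch(
      withCallingHandlers(
        cox_fit(X[, cols, drop = FALSE], time, event, ties = ties),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (!is.null(f) && !f$converged) f <- NULL
    f
  }

  repeat {
    # -- entry scan (Rao score test for each excluded candidate)
    excl <- setdiff(eligible, included)
    if (!length(excl) || n_actions >= max_steps) {
      if (n_actions >= max_steps) stopped <- "max_steps"
      break
    }
    Xs_cur <- if (length(included)) Xs[, included, drop = FALSE] else NULL
    beta_cur <- if (is.null(fit)) numeric(0) else fit$beta
    sc <- .cox_score_scan(Xs_cur, beta_cur, Xs[, excl, drop = FALSE],
                          prep, ties)
    ps <- setNames(sc$p, excl)
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= p_enter) break
    best <- excl[which.min(ps)]
    new_fit <- refit(c(included, best))
    if (is.null(new_fit)) {         # collinear / separated candidate
      eligible <- setdiff(eligible, best)
      next
    }
    included <- c(included, best)
    fit <- new_fit
    n_actions <- n_actions + 1
    steps[[length(steps) + 1]] <- data.frame(
      action = "enter", covariate = best,
      stat = setNames(sc$stat, excl)[best], p = ps[best])

    # -- removal scan (conditional LR test per included covariate)
    repeat {
      if (length(included) == 0 || n_actions >= max_steps) break
      lr_p <- vapply(included, function(j) {
        red <- setdiff(included, j)
        red_ll <- if (length(red) == 0) fit$loglik_null else {
          rf <- refit(red)
          if (is.null(rf)) return(NA_real_)
          rf$loglik
        }
        pchisq(2 * (fit$loglik - red_ll), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (all(is.na(lr_p)) || max(lr_p, na.rm = TRUE) <= p_remove) break
      worst <- included[which.max(lr_p)]
      pw <- max(lr_p, na.rm = TRUE)
      included <- setdiff(included, worst)
      fit <- if (length(included)) refit(included) else NULL
      n_actions <- n_actions + 1
      steps[[length(steps) + 1]] <- data.frame(
        action = "remove", covariate = worst, stat = NA_real_, p = pw)
      s <- sig(included)
      if (s %in% visited) {         # cycle: same model seen before
        warning("stepwise cycling detected; stopping")
        stopped <- "cycle"
        break
      }
    }
    if (stopped == "cycle") break
    visited <- c(visited, sig(included))
  }

  trace <- structure(
    list(selected = included,
         steps = if (length(steps)) do.call(rbind, steps)
                 else data.frame(action = character(0),
                                 covariate = character(0),
                                 stat = numeric(0), p = numeric(0)),
         stopped = stopped),
    class = "stepwise_trace")
  list(trace = trace, fit = fit)
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("<stepwise_trace> %d step(s), selected: %s [stop: %s]\n",
              nrow(x$steps),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)", x$stopped))
  invisible(x)
}
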