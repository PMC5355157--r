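# Cox proportional-hazards kernel.
#
# The partial likelihood, its gradient and observed information are computed
# on data sorted by follow-up time; at tied times events precede censorings,
# so the risk set for an event time is every patient whose recorded time is
# >= that time. When no two events share a time the Efron and Breslow
# corrections coincide and everything reduces to reverse cumulative sums
# (no loop); with tied events a per-event-time loop applies the correction.

# Sort bookkeeping shared by all evaluations on one dataset.
.cox_prep <- function(time, event) {
  o <- order(time)
  ts <- time[o]
  ev <- event[o]
  fi <- match(ts, ts)              # first index of each tied-time block
  e_idx <- which(ev == 1)
  list(o = o, ts = ts, ev = ev, fi = fi, e_idx = e_idx,
       tied = anyDuplicated(ts[e_idx]) > 0)
}

# loglik / gradient / information at beta. Xs must already be sorted by prep$o.
.cox_deriv <- function(Xs, prep, beta, ties = "efron") {
  p <- ncol(Xs)
  eta <- as.vector(Xs %*% beta)
  eta <- eta - max(eta)            # partial likelihood is shift-invariant
  w <- exp(eta)
  e_idx <- prep$e_idx
  fi <- prep$fi
  S0 <- rev(cumsum(rev(w)))
  S1 <- rev_cumsum_mat(Xs * w)

  if (!prep$tied) {
    r <- fi[e_idx]                 # risk-set start index per event
    s0 <- S0[r]
    M <- S1[r, , drop = FALSE] / s0
    loglik <- sum(eta[e_idx]) - sum(log(s0))
    grad <- colSums(Xs[e_idx, , drop = FALSE]) - colSums(M)
    # sum_events S2(r)/S0 collapses to a weighted crossproduct:
    # c[k] = sum over events with risk start <= k of 1/S0
    acc <- numeric(length(w))
    acc[r] <- 1 / s0
    cw <- w * cumsum(acc)
    info <- crossprod(Xs * sqrt(cw)) - crossprod(M)
    return(list(loglik = loglik, grad = grad, info = info))
  }
  XXw <- Xs[, rep(seq_len(p), times = p), drop = FALSE] *
         Xs[, rep(seq_len(p), each = p), drop = FALSE] * w
  S2 <- rev_cumsum_mat(XXw)

  loglik <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in unique(prep$ts[e_idx])) {
    D <- which(prep$ts == t & prep$ev == 1)
    r <- fi[D[1]]
    d <- length(D)
    s0r <- S0[r]
    s1r <- S1[r, ]
    s2r <- matrix(S2[r, ], p, p)
    loglik <- loglik + sum(eta[D])
    grad <- grad + colSums(Xs[D, , drop = FALSE])
    if (ties == "efron" && d > 1) {
      s0d <- sum(w[D])
      s1d <- colSums(Xs[D, , drop = FALSE] * w[D])
      s2d <- matrix(colSums(XXw[D, , drop = FALSE]), p, p)
      for (l in seq_len(d) - 1) {
        f <- l / d
        phi <- s0r - f * s0d
        mu <- (s1r - f * s1d) / phi
        loglik <- loglik - log(phi)
        grad <- grad - mu
        info <- info + (s2r - f * s2d) / phi - tcrossprod(mu)
      }
    } else {
      mu <- s1r / s0r
      loglik <- loglik - d * log(s0r)
      grad <- grad - d * mu
      info <- info + d * (s2r / s0r - tcrossprod(mu))
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with the Efron
#' tie correction (default) or Breslow's approximation, with step-halving
#' when a step would decrease the likelihood. Standard errors come from the
#' inverse observed information at the maximum. Monotone likelihoods
#' (perfect separation) are flagged via `converged = FALSE` and a warning,
#' never silently.
#'
#' @param X Covariate matrix (patients x covariates) or a single vector.
#'   Constant columns are an error.
#' @param time Positive follow-up times.
#' @param event 0/1 event indicator.
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter,tol Newton iteration cap and convergence tolerance on
#'   the largest coefficient update.
#' @return Object of class `cox_fit`: `beta`, `se`, `hr`, `ci95`
#'   (2-column matrix), `z`, `p`, `loglik`, `loglik_null`, `converged`,
#'   `n`, `n_events`, `iter`.
#' @export
cox_fit <- function(X, time, event, ties = c("efron", "breslow"),
                    max_iter = 100, tol = 1e-7) {
  ties <- match.arg(ties)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  time <- as.numeric(time)
  event <- as.numeric(event)
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (anyNA(X) || anyNA(time) || anyNA(event)) stop("missing values in input")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) stop("no events; Cox model cannot be fit")
  cvar <- apply(X, 2, function(col) diff(range(col)))
  if (any(cvar == 0))
    stop("constant column(s): ",
         paste(colnames(X)[cvar == 0], collapse = ", "))
  p <- ncol(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)           # centering: identical beta, stable exp()
  prep <- .cox_prep(time, event)
  Xs <- Xc[prep$o, , drop = FALSE]

  beta <- numeric(p)
  dv <- .cox_deriv(Xs, prep, beta, ties)
  loglik_null <- dv$loglik
  converged <- FALSE
  iter <- 0
  singular <- FALSE
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(dv$info, dv$grad), error = function(e) NULL)
    if (is.null(step)) { singular <- TRUE; break }
    half <- 0
    repeat {
      cand <- beta + step
      dv_new <- .cox_deriv(Xs, prep, cand, ties)
      if (is.finite(dv_new$loglik) && dv_new$loglik >= dv$loglik - 1e-9) break
      step <- step / 2
      half <- half + 1
      if (half > 25) break
    }
    if (half > 25) break           # likelihood cannot be improved
    beta <- cand
    dv <- dv_new
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (singular)
    warning("singular information matrix; fit flagged as non-converged")
  if (!converged && !singular)
    warning("Cox fit did not converge (possible monotone likelihood / separation)")
  se <- tryCatch({
    v <- diag(solve(dv$info))
    ifelse(is.finite(v) & v > 0, sqrt(v), NA_real_)
  }, error = function(e) rep(NA_real_, p))
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- colnames(X)
  structure(list(beta = beta, se = se, hr = exp(beta), ci95 = ci,
                 z = z, p = 2 * pnorm(-abs(z)),
                 loglik = dv$loglik, loglik_null = loglik_null,
                 converged = converged, n = length(time),
                 n_events = sum(event), ties = ties, iter = iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d, loglik=%.3f (null %.3f)%s\n",
              x$n, x$n_events, x$loglik, x$loglik_null,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(beta = round(x$beta, 4), se = round(x$se, 4),
                   HR = round(x$hr, 4),
                   ci_low = round(x$ci95[, 1], 4),
                   ci_high = round(x$ci95[, 2], 4),
                   p = signif(x$p, 3)))
  invisible(x)
}

# Rao score test for adding one candidate column to a fitted model.
# Evaluates gradient and information of the augmented model at
# (beta_hat, 0); the statistic is g' I^{-1} g ~ chi^2(1).
.cox_score_test <- function(Xs_cur, beta_cur, xs_cand, prep, ties = "efron") {
  Xa <- cbind(Xs_cur, xs_cand)
  dv <- .cox_deriv(Xa, prep, c(beta_cur, 0), ties)
  stat <- tryCatch(as.numeric(crossprod(dv$grad, solve(dv$info, dv$grad))),
                   error = function(e) NA_real_)
  list(stat = stat,
       p = if (is.na(stat)) NA_real_
           else pchisq(stat, df = 1, lower.tail = FALSE))
}

# Batched score tests for many candidate columns against one fitted model.
# Tie-free fast path: shared risk-set sums plus the block-inverse identity
#   g' I^{-1} g = g_t' a + (U_j - I_jt a)^2 / (I_jj - I_jt b_j),
# with a = I_tt^{-1} g_t and b_j = I_tt^{-1} I_tj, reproduces the
# per-candidate statistic exactly. With tied event times it falls back to
# the exact per-candidate evaluation.
.cox_score_scan <- function(Xs_cur, beta_cur, Xs_cands, prep,
                            ties = "efron") {
  m <- ncol(Xs_cands)
  if (prep$tied) {
    out <- vapply(seq_len(m), function(j)
      unlist(.cox_score_test(Xs_cur, beta_cur,
                             Xs_cands[, j, drop = FALSE], prep, ties)),
      numeric(2))
    return(list(stat = out["stat", ], p = out["p", ]))
  }
  p <- if (is.null(Xs_cur)) 0L else ncol(Xs_cur)
  eta <- if (p > 0) as.vector(Xs_cur %*% beta_cur) else numeric(nrow(Xs_cands))
  w <- exp(eta - max(eta))
  e <- prep$e_idx
  r <- prep$fi[e]
  s0 <- rev(cumsum(rev(w)))[r]
  acc <- numeric(length(w))
  acc[r] <- 1 / s0
  cw <- w * cumsum(acc)
  A <- Xs_cands * w
  Mc <- rev_cumsum_mat(A)[r, , drop = FALSE] / s0
  U <- colSums(Xs_cands[e, , drop = FALSE]) - colSums(Mc)
  Ijj <- colSums(Xs_cands^2 * cw) - colSums(Mc^2)
  if (p == 0) {
    stat <- U^2 / Ijj
  } else {
    M <- rev_cumsum_mat(Xs_cur * w)[r, , drop = FALSE] / s0
    g_t <- colSums(Xs_cur[e, , drop = FALSE]) - colSums(M)
    Itt <- crossprod(Xs_cur * sqrt(cw)) - crossprod(M)
    Ijt <- crossprod(Xs_cands * cw, Xs_cur) - crossprod(Mc, M)
    inv <- tryCatch(solve(Itt), error = function(e) NULL)
    if (is.null(inv))
      return(list(stat = rep(NA_real_, m), p = rep(NA_real_, m)))
    a <- as.vector(inv %*% g_t)
    V <- Ijj - rowSums((Ijt %*% inv) * Ijt)
    stat <- as.numeric(crossprod(g_t, a)) + (U - as.vector(Ijt %*% a))^2 / V
    stat[V <= 0] <- NA_real_
  }
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}
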