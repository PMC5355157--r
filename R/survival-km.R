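#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survivor function S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), where d_i is the number of events and n_i the number at
#' risk just before t_i. Censoring times that carry no event do not create
#' steps; at tied times, events are taken to precede censorings, so patients
#' censored at an event time are still counted at risk for it.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicator.
#' @return Object of class `km_curve` with `event_times`, `survival`,
#'   `at_risk`, `n_events`, and an `all_censored` flag. With no events the
#'   curve is flat (no steps) and a warning is raised.
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  n <- length(time)
  if (sum(event) == 0) {
    warning("all observations censored; flat survival curve")
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n_events = integer(0),
                          n = n, all_censored = TRUE),
                     class = "km_curve"))
  }
  et <- sort(unique(time[event == 1]))
  at_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  d <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - d / at_risk)
  structure(list(event_times = et, survival = surv,
                 at_risk = as.integer(at_risk), n_events = as.integer(d),
                 n = n, all_censored = FALSE),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d, %d event time(s)%s\n", x$n,
              length(x$event_times),
              if (x$all_censored) " [all censored]" else ""))
  if (length(x$event_times)) {
    idx <- unique(round(seq(1, length(x$event_times), length.out = 6)))
    print(data.frame(time = x$event_times[idx], at_risk = x$at_risk[idx],
                     events = x$n_events[idx],
                     survival = round(x$survival[idx], 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A [km_estimate()] result.
#' @param t Times at which to read off the step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    k <- sum(curve$event_times <= ti)
    if (k == 0) 1 else curve$survival[k]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard (Mantel-Cox) two-sample log-rank test: at each distinct event
#' time the observed events in group 1 are compared with the
#' hypergeometric expectation given the margins, and
#' `chi2 = (O1 - E1)^2 / V` is referred to a chi-square distribution with
#' one degree of freedom.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicator.
#' @param group Two-level grouping vector.
#' @return List with `chi2`, `p`, `observed`, `expected` (both per group).
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  group <- as.character(group)
  stopifnot(length(time) == length(event), length(time) == length(group))
  lv <- sort(unique(group))
  if (length(lv) != 2)
    stop("log-rank test requires exactly 2 non-empty groups, got ",
         length(lv))
  if (sum(event) == 0) stop("log-rank test requires at least one event")
  g1 <- group == lv[1]
  et <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  O <- sum(event)
  list(chi2 = chi2, p = p,
       observed = setNames(c(O1, O - O1), lv),
       expected = setNames(c(E1, O - E1), lv))
}
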