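# Product-limit estimation and the k-group log-rank test, implemented from
# first principles on (time, event) data in months.

check_surv_input <- function(time, event) {
  if (length(time) == 0L) stop("empty survival input")
  if (length(time) != length(event))
    stop("time and event vectors differ in length")
  if (any(is.na(time)) || any(is.na(event)))
    stop("missing values in survival input")
  if (any(time < 0)) stop("negative survival times")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with
#' d_i deaths among the n_i subjects at risk just before t_i.
#'
#' @param time Follow-up times (months, >= 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return An object of class `km_curve`: a data frame with one row per
#'   distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`), plus `attr(, "n")`.
#' @export
km_estimate <- function(time, event) {
  check_surv_input(time, event)
  n <- length(time)
  tt <- sort(unique(time))
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0), numeric(1))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv)
  attr(out, "n") <- n
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The median is the smallest event time at which the estimated survival
#' drops to 0.5 or below. When the curve never reaches 0.5 within the
#' observed follow-up the median is not reached and `NA` is returned.
#'
#' @param curve A `km_curve`.
#' @return The median survival time in months, or `NA_real_` ("not reached").
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$surv <= 0.5 & curve$n_event > 0)
  if (length(hit) == 0L) return(NA_real_)
  curve$time[hit[1L]]
}

#' Number of patients at risk at selected times
#'
#' Risk-table companion to a Kaplan-Meier plot: the number of subjects still
#' under observation at each requested time.
#'
#' @param time,event Survival data as in [km_estimate()].
#' @param at Times at which to count (months).
#' @return Integer vector of at-risk counts.
#' @export
n_at_risk <- function(time, event, at) {
  check_surv_input(time, event)
  vapply(at, function(t) sum(time >= t), integer(1))
}

#' k-group log-rank test
#'
#' Observed-minus-expected statistic over the distinct event times with the
#' hypergeometric variance, compared to a chi-square distribution on
#' (number of groups - 1) degrees of freedom.
#'
#' @param time,event Survival data as in [km_estimate()].
#' @param group Group labels (factor or coercible); >= 2 non-empty groups.
#' @return List of class `logrank_test` with `statistic`, `df`, `p_value`,
#'   and the per-group observed and expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2L) stop("log-rank test needs at least 2 groups")
  lev <- levels(group)
  if (sum(event) == 0) stop("log-rank test needs at least one event")
  tt <- sort(unique(time[event == 1]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ng <- vapply(lev, function(g) sum(at_risk & group == g), numeric(1))
    dg <- vapply(lev, function(g) sum(event == 1 & time == t & group == g),
                 numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      p <- ng / n
      V <- V + d * (n - d) / (n - 1) * (diag(p, nrow = k) - tcrossprod(p))
    }
  }
  idx <- seq_len(k - 1L)
  ome <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(ome) %*% solve(Vsub, ome)),
                   error = function(e)
                     stop("singular log-rank variance matrix; a group may have no events at risk"))
  res <- list(statistic = stat, df = k - 1L,
              p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
              observed = stats::setNames(O, lev),
              expected = stats::setNames(E, lev))
  class(res) <- "logrank_test"
  res
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 5),
      "on", x$df, "df, p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @export
print.km_curve <- function(x, ...) {
  med <- median_survival(x)
  cat("Kaplan-Meier curve: n =", attr(x, "n"),
      ", events =", sum(x$n_event),
      ", median =", if (is.na(med)) "not reached" else format(med), "\n")
  invisible(x)
}
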