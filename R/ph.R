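# Proportional-hazards diagnostics via scaled Schoenfeld residuals tested
# against a Kaplan-Meier-based time transform (Grambsch-Therneau).

#' Schoenfeld residuals of a Cox fit
#'
#' One residual row per event, ordered by event time: the covariate vector
#' of the failing subject minus the risk-set weighted covariate mean at that
#' time (tie handling matches the fit, so the residuals sum to the score
#' vector, which is zero at the maximum).
#'
#' @param fit A `cna_cox` fit.
#' @return Matrix (events x terms) with `attr(, "time")` giving event times.
#' @export
schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "cna_cox"))
  X <- fit$model$X; time <- fit$model$time; event <- fit$model$event
  p <- ncol(X)
  prep <- cox_prep(X, time, event)
  eta <- drop(prep$Xs %*% fit$beta)
  w <- exp(eta - max(eta))
  RS0 <- revcumsum(w)
  RS1 <- revcumsum(w * prep$Xs)
  res <- NULL; res_time <- NULL
  for (k in seq_along(prep$etimes)) {
    idx <- prep$first_idx[k]
    D <- prep$death_idx[[k]]
    d <- length(D)
    S0 <- RS0[idx]; S1 <- RS1[idx, ]
    if (fit$ties == "breslow" || d == 1L) {
      mbar <- S1 / S0
    } else {
      wD <- w[D]
      S0D <- sum(wD)
      S1D <- colSums(wD * prep$Xs[D, , drop = FALSE])
      ms <- vapply(seq_len(d) - 1L, function(l) {
        f <- l / d
        (S1 - f * S1D) / (S0 - f * S0D)
      }, numeric(p))
      mbar <- if (p == 1L) mean(ms) else rowMeans(matrix(ms, nrow = p))
    }
    r <- sweep(prep$Xs[D, , drop = FALSE], 2L, mbar)
    res <- rbind(res, r)
    res_time <- c(res_time, rep(prep$etimes[k], d))
  }
  colnames(res) <- fit$terms
  attr(res, "time") <- res_time
  res
}

#' Test the proportional-hazards assumption
#'
#' Scaled Schoenfeld residuals are regressed on a time transform
#' g(t) = 1 - KM(t) (the Kaplan-Meier estimate on the fitted cohort). A
#' non-zero slope indicates a time-varying coefficient, i.e. a PH violation.
#' Per-term and global chi-square statistics follow the Grambsch-Therneau
#' construction.
#'
#' @param fit A `cna_cox` fit with at least 2 events.
#' @param transform `"km"` (default) or `"identity"` or `"rank"`.
#' @return Object of class `ph_diagnostics`: data frame `table` with one row
#'   per term plus a GLOBAL row (`rho` correlation with g(t), `chisq`, `df`,
#'   `p_value`).
#' @export
ph_diagnostics <- function(fit, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  if (fit$n_event < 2L) stop("PH diagnostics need at least 2 events")
  R <- schoenfeld_residuals(fit)
  etime <- attr(R, "time")
  m <- nrow(R); p <- ncol(R)
  g <- switch(transform,
              km = {
                km <- km_estimate(fit$model$time, fit$model$event)
                1 - km$surv[match(etime, km$time)]
              },
              identity = etime,
              rank = rank(etime))
  gc <- g - mean(g)
  V <- fit$var
  u <- drop(crossprod(R, gc))                 # p-vector: sum_i gc_i * r_i
  gss <- sum(gc^2)
  r2 <- R %*% V * m                           # scaled residuals
  per_chisq <- (drop(crossprod(r2, gc)))^2 / (m * diag(V) * gss)
  per_rho <- apply(r2, 2L, function(col) stats::cor(gc, col))
  global_chisq <- drop(m * t(u) %*% V %*% u / gss)
  tab <- data.frame(
    term = c(fit$terms, "GLOBAL"),
    rho = c(per_rho, NA_real_),
    chisq = c(per_chisq, global_chisq),
    df = c(rep(1L, p), p),
    p_value = c(stats::pchisq(per_chisq, 1L, lower.tail = FALSE),
                stats::pchisq(global_chisq, p, lower.tail = FALSE)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, transform = transform, n_event = m),
            class = "ph_diagnostics")
}

#' @export
print.ph_diagnostics <- function(x, ...) {
  cat("Proportional-hazards diagnostics (", x$transform, " transform, ",
      x$n_event, " events)\n", sep = "")
  tab <- x$table
  tab$rho <- round(tab$rho, 4); tab$chisq <- round(tab$chisq, 3)
  tab$p_value <- format.pval(tab$p_value, digits = 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
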