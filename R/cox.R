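# Cox proportional-hazards regression by Newton-Raphson maximisation of the
# partial likelihood, with Efron (default) or Breslow handling of tied event
# times, the Breslow baseline cumulative hazard, and the likelihood-ratio,
# Wald and score tests.

revcumsum <- function(v) {
  if (is.matrix(v)) apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 2L, cumsum)[rev(seq_len(nrow(v))), , drop = FALSE]
  else rev(cumsum(rev(v)))
}

# indices of the lower-triangle-with-diagonal pairs for a p x p symmetric
# matrix stored as a q = p(p+1)/2 column block
sym_pairs <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

expand_sym <- function(v, p, pairs) {
  m <- matrix(0, p, p)
  m[pairs] <- v
  m[pairs[, c(2L, 1L), drop = FALSE]] <- v
  m
}

# Partial-likelihood value, gradient and observed information at beta.
cox_derivs <- function(X, time, event, beta, ties, prep = NULL) {
  p <- ncol(X)
  if (is.null(prep)) prep <- cox_prep(X, time, event)
  Xs <- prep$Xs; ts <- prep$ts; es <- prep$es
  pairs <- prep$pairs; XX <- prep$XX
  eta <- drop(Xs %*% beta)
  eta_c <- eta - max(eta)              # guard overflow; constants cancel
  w <- exp(eta_c)
  RS0 <- revcumsum(w)
  RS1 <- revcumsum(w * Xs)
  RS2 <- revcumsum(w * XX)
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  for (k in seq_along(prep$etimes)) {
    idx <- prep$first_idx[k]
    D <- prep$death_idx[[k]]
    d <- length(D)
    S0 <- RS0[idx]; S1 <- RS1[idx, ]; S2 <- expand_sym(RS2[idx, ], p, pairs)
    sum_eta <- sum(eta_c[D])
    sum_x <- colSums(Xs[D, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      ll <- ll + sum_eta - d * log(S0)
      m <- S1 / S0
      grad <- grad + sum_x - d * m
      info <- info + d * (S2 / S0 - tcrossprod(m))
    } else {
      wD <- w[D]
      S0D <- sum(wD)
      S1D <- colSums(wD * Xs[D, , drop = FALSE])
      S2D <- expand_sym(colSums(wD * XX[D, , drop = FALSE]), p, pairs)
      ll <- ll + sum_eta
      for (l in seq_len(d) - 1L) {
        f <- l / d
        den <- S0 - f * S0D
        m <- (S1 - f * S1D) / den
        ll <- ll - log(den)
        grad <- grad + sum_x / d - m
        info <- info + (S2 - f * S2D) / den - tcrossprod(m)
      }
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

cox_prep <- function(X, time, event) {
  ord <- order(time)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]; es <- event[ord]
  p <- ncol(X)
  pairs <- sym_pairs(p)
  XX <- Xs[, pairs[, 1L], drop = FALSE] * Xs[, pairs[, 2L], drop = FALSE]
  etimes <- unique(ts[es == 1])
  first_idx <- match(etimes, ts)
  death_idx <- lapply(etimes, function(t) which(ts == t & es == 1))
  list(Xs = Xs, ts = ts, es = es, ord = ord, pairs = pairs, XX = XX,
       etimes = etimes, first_idx = first_idx, death_idx = death_idx)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the partial likelihood by Newton-Raphson with step-halving.
#' Tied event times are handled by the Efron correction by default; the
#' Breslow approximation is available (and makes the single-covariate score
#' test algebraically comparable to the log-rank statistic). The covariance
#' matrix is the inverse observed information at the maximum, hazard-ratio
#' confidence intervals are Wald intervals on the log scale, and the baseline
#' cumulative hazard is the Breslow estimator at the fitted coefficients.
#'
#' @param design Numeric design matrix as from [build_design()] (or any
#'   numeric matrix with column names).
#' @param time,event Survival outcome; see [km_estimate()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the relative change in the partial
#'   log-likelihood.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return An object of class `cna_cox` with elements `terms`, `beta`, `se`,
#'   `var`, `hr`, `ci95`, `loglik` (null, fitted), `lr_test`, `wald_test`,
#'   `score_test`, `ties`, `n`, `n_event`, `baseline` (Breslow cumulative
#'   hazard), `iterations`, and the model frame needed for diagnostics.
#' @export
cox_fit <- function(design, time, event, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_surv_input(time, event)
  if (nrow(X) != length(time)) stop("design and outcome sizes differ")
  if (sum(event) < 1) stop("no events in the data")
  if (qr(X)$rank < ncol(X))
    stop("design columns are linearly dependent on this cohort")
  p <- ncol(X)
  prep <- cox_prep(X, time, event)
  beta <- numeric(p)
  d0 <- cox_derivs(X, time, event, beta, ties, prep)
  loglik_null <- d0$loglik
  score_stat <- drop(t(d0$grad) %*% solve(d0$info, d0$grad))
  ll_old <- d0$loglik
  deriv <- d0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- solve(deriv$info, deriv$grad)
    halve <- 0L
    repeat {
      beta_new <- beta + step
      deriv_new <- cox_derivs(X, time, event, beta_new, ties, prep)
      if (is.finite(deriv_new$loglik) && deriv_new$loglik >= ll_old - 1e-12) break
      halve <- halve + 1L
      if (halve > 25L) break
      step <- step / 2
    }
    beta <- beta_new
    deriv <- deriv_new
    if (abs(deriv$loglik - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- deriv$loglik
      break
    }
    ll_old <- deriv$loglik
  }
  if (!converged)
    stop("Cox Newton-Raphson did not converge in ", max_iter,
         " iterations; gradient norm ", format(sqrt(sum(deriv$grad^2))))
  if (any(abs(beta) > 15))
    warning("very large coefficient(s); the partial likelihood may be monotone (separation)")
  V <- solve(deriv$info)
  se <- sqrt(diag(V))
  z975 <- 1.959964
  ci <- cbind(lower = exp(beta - z975 * se), upper = exp(beta + z975 * se))
  rownames(ci) <- colnames(X)
  lr_stat <- 2 * (ll_old - loglik_null)
  wald_stat <- drop(t(beta) %*% solve(V, beta))
  mk_test <- function(stat) list(statistic = stat, df = p,
                                 p_value = stats::pchisq(stat, p, lower.tail = FALSE))
  # Breslow baseline cumulative hazard at beta-hat (reference profile)
  eta <- drop(prep$Xs %*% beta)
  w <- exp(eta)
  RS0 <- revcumsum(w)
  d_k <- vapply(prep$death_idx, length, integer(1))
  h0 <- d_k / RS0[prep$first_idx]
  baseline <- data.frame(time = prep$etimes, n_event = d_k,
                         cumhaz = cumsum(h0))
  fit <- list(terms = colnames(X),
              beta = stats::setNames(beta, colnames(X)),
              se = stats::setNames(se, colnames(X)),
              var = V,
              hr = stats::setNames(exp(beta), colnames(X)),
              ci95 = ci,
              loglik = c(null = loglik_null, fitted = ll_old),
              lr_test = mk_test(lr_stat),
              wald_test = mk_test(wald_stat),
              score_test = mk_test(score_stat),
              ties = ties,
              n = nrow(X), n_event = sum(event),
              baseline = baseline,
              iterations = iter,
              model = list(X = X, time = time, event = event,
                           term_info = attr(design, "term_info"),
                           terms_parsed = attr(design, "terms_parsed"),
                           formula = attr(design, "formula")))
  class(fit) <- "cna_cox"
  fit
}

#' Fit the luminal CNA-quartile Cox model from clinical data
#'
#' Convenience wrapper: builds the treatment-coded design from a formula and
#' fits the Cox model for the chosen outcome.
#'
#' @param clinical A `clinical_table`.
#' @param score A `score_table` supplying CNA quartiles.
#' @param formula Model formula string; defaults to the full
#'   subtype + grade + size + nodes + age + HER2 + quartile model with
#'   quartile-by-subtype interactions.
#' @param outcome `"os"` or `"dss"`.
#' @param references Optional reference-level overrides (see
#'   [build_design()]).
#' @param ties Tie-handling method.
#' @return A `cna_cox` fit.
#' @export
fit_cox_model <- function(clinical, score,
                          formula = luminal_dss_formula(),
                          outcome = "dss", references = NULL,
                          ties = "efron") {
  X <- build_design(clinical, score, formula, references)
  y <- survival_outcome(clinical, outcome)
  cox_fit(X, y$time, y$event, ties = ties)
}

#' The full interaction model formula
#'
#' PAM50 subtype, histological grade, tumour size, positive lymph nodes, age
#' at diagnosis, HER2 status, CNA quartile, and quartile-by-subtype
#' interactions: 13 design columns under the default reference levels.
#'
#' @return Formula string.
#' @export
luminal_dss_formula <- function() {
  paste("pam50 + grade + tumour_size + positive_lymph_nodes +",
        "age_at_diagnosis + her2_status + quartile + quartile:pam50")
}

#' Refit a Cox model with a different reference level
#'
#' Swaps the reference level of one or more categorical covariates and
#' refits; useful for reading within-subtype quartile contrasts directly
#' (e.g. quartile effects within luminal B rather than luminal A).
#'
#' @param clinical,score,formula,outcome,ties As in [fit_cox_model()].
#' @param new_reference Named list, e.g. `list(pam50 = "lumB")`.
#' @return A `cna_cox` fit under the new coding.
#' @export
reparametrize_reference <- function(clinical, score,
                                    formula = luminal_dss_formula(),
                                    outcome = "dss", new_reference,
                                    ties = "efron") {
  fit_cox_model(clinical, score, formula, outcome,
                references = new_reference, ties = ties)
}

#' Coefficient table of a Cox fit
#'
#' One row per design column with the log-hazard coefficient, its standard
#' error, the hazard ratio with 95% Wald confidence interval, the two-sided
#' p-value and a significance code. Stored p-values are full precision;
#' truncation (e.g. "<0.001") happens only in rendering.
#'
#' @param fit A `cna_cox` fit.
#' @return Data frame with columns `term`, `beta`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value`, `signif`.
#' @export
cox_summary_table <- function(fit) {
  stopifnot(inherits(fit, "cna_cox"))
  z <- fit$beta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = fit$terms,
             beta = unname(fit$beta),
             se = unname(fit$se),
             hr = unname(fit$hr),
             ci_lower = unname(fit$ci95[, "lower"]),
             ci_upper = unname(fit$ci95[, "upper"]),
             p_value = unname(p),
             signif = signif_code(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

signif_code <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
                   labels = c("***", "**", "*", ".", ""), right = FALSE))
}

#' A linear contrast of Cox coefficients
#'
#' Estimate, standard error and Wald test for `L'beta`; e.g. the within-lumB
#' Q4 effect is the sum of the Q4 main effect and the Q4:lumB interaction.
#'
#' @param fit A `cna_cox` fit.
#' @param weights Named numeric vector of contrast weights over `fit$terms`.
#' @return List with `estimate`, `se`, `hr`, `ci95`, `p_value`.
#' @export
cox_contrast <- function(fit, weights) {
  L <- numeric(length(fit$terms))
  names(L) <- fit$terms
  unknown <- setdiff(names(weights), fit$terms)
  if (length(unknown) > 0L)
    stop("unknown term(s) in contrast: ", paste(unknown, collapse = ", "))
  L[names(weights)] <- weights
  est <- sum(L * fit$beta)
  se <- sqrt(drop(t(L) %*% fit$var %*% L))
  z975 <- 1.959964
  list(estimate = est, se = se, hr = exp(est),
       ci95 = c(lower = exp(est - z975 * se), upper = exp(est + z975 * se)),
       p_value = 2 * stats::pnorm(-abs(est / se)))
}

#' Covariate-adjusted survival curves
#'
#' Predicted survival for chosen covariate profiles from a fitted Cox model:
#' S(t | x) = exp(-H0(t))^exp(lp(x)) with H0 the Breslow baseline cumulative
#' hazard. The conventional display fixes unvaried covariates at their
#' median (quantitative) or mode (categorical); build such profiles with
#' [covariate_profile()].
#'
#' @param fit A `cna_cox` fit produced from a [build_design()] design.
#' @param profiles Named list of profiles; each profile is a named list
#'   supplying a value for every covariate in the model formula.
#' @return Named list of data frames (`time`, `surv`), one per profile.
#' @export
adjusted_survival_curves <- function(fit, profiles) {
  stopifnot(inherits(fit, "cna_cox"))
  if (is.null(fit$model$term_info))
    stop("fit lacks design metadata; build the design with build_design()")
  if (!is.list(profiles[[1L]])) profiles <- list(profile = profiles)
  H0 <- fit$baseline
  lapply(profiles, function(prof) {
    x <- design_row(fit$model$term_info, fit$model$terms_parsed, prof)
    x <- x[, fit$terms, drop = FALSE]
    lp <- drop(x %*% fit$beta)
    data.frame(time = H0$time,
               surv = exp(-H0$cumhaz * exp(lp)),
               lp = lp)
  })
}

#' Serialize a Cox fit to JSON
#'
#' @param fit A `cna_cox` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cox_json <- function(fit, path) {
  obj <- list(terms = fit$terms, beta = as.list(fit$beta),
              se = as.list(fit$se),
              covariance = unname(as.matrix(fit$var)),
              hr = as.list(fit$hr),
              loglik = as.list(fit$loglik),
              lr_test = fit$lr_test, wald_test = fit$wald_test,
              score_test = fit$score_test,
              ties = fit$ties, n = fit$n, n_event = fit$n_event)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cna_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  tab <- cox_summary_table(x)
  tab$beta <- round(tab$beta, 3); tab$se <- round(tab$se, 3)
  tab$hr <- round(tab$hr, 3)
  tab$ci_lower <- round(tab$ci_lower, 3); tab$ci_upper <- round(tab$ci_upper, 3)
  tab$p_value <- format.pval(tab$p_value, digits = 3, eps = 1e-16)
  print(tab, row.names = FALSE)
  cat("Likelihood ratio =", format(x$lr_test$statistic, digits = 5),
      "on", x$lr_test$df, "df, p =",
      format.pval(x$lr_test$p_value, digits = 3, eps = 1e-16), "\n")
  invisible(x)
}
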