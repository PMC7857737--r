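test_that("identical survival in both groups gives beta near 0, HR near 1", {
  time <- rep(c(1, 2, 3, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1, 1, 0), 2)
  x <- matrix(rep(c(0, 1), each = 6), ncol = 1, dimnames = list(NULL, "g"))
  fit <- cox_fit(x, time, event)
  expect_lt(abs(fit$beta), 1e-8)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-8)
})

test_that("a 6-subject fit matches a fine grid search of the partial likelihood", {
  time <- c(1, 3, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 1, 1)
  x <- c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9)
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                   time, event, ties = ties)
    grid <- seq(-3, 3, by = 1e-4)
    ll <- vapply(grid, cox_partial_loglik_oracle, numeric(1),
                 x = x, time = time, event = event, ties = ties)
    expect_equal(unname(fit$beta), grid[which.max(ll)], tolerance = 1e-4)
    expect_equal(unname(fit$loglik["fitted"]),
                 cox_partial_loglik_oracle(unname(fit$beta), x, time, event,
                                           ties),
                 tolerance = 1e-10)
  }
})

test_that("coefficients, errors and tests match coxph on tied and untied data", {
  for (seed in 1:3) {
    co <- random_cohort(80, seed = 300 + seed)
    x2 <- rbinom(80, 1, 0.5)
    X <- cbind(x = co$x, grp = x2)
    # introduce ties by rounding
    time_t <- round(co$time, 0) + 0.5
    for (ties in c("efron", "breslow")) {
      fit <- cox_fit(X, time_t, co$event, ties = ties)
      cp <- survival::coxph(survival::Surv(time_t, co$event) ~ X,
                            ties = ties)
      expect_equal(unname(fit$beta), unname(coef(cp)), tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cp)))),
                   tolerance = 1e-6)
      expect_equal(fit$lr_test$statistic,
                   2 * diff(cp$loglik), tolerance = 1e-6)
      expect_equal(fit$score_test$statistic, unname(cp$score),
                   tolerance = 1e-6)
      expect_equal(unname(fit$loglik), unname(cp$loglik), tolerance = 1e-8)
    }
  }
})

test_that("the Breslow baseline cumulative hazard matches survfit", {
  co <- random_cohort(60, seed = 310)
  X <- cbind(x = co$x)
  fit <- cox_fit(X, co$time, co$event, ties = "breslow")
  cp <- survival::coxph(survival::Surv(co$time, co$event) ~ X,
                        ties = "breslow")
  bh <- survival::basehaz(cp, centered = FALSE)
  expect_equal(fit$baseline$cumhaz,
               bh$hazard[match(fit$baseline$time, bh$time)],
               tolerance = 1e-6)
})

test_that("beta is shift-invariant and scales inversely with the covariate", {
  co <- random_cohort(70, seed = 320)
  X <- cbind(x = co$x)
  fit <- cox_fit(X, co$time, co$event)
  fit_shift <- cox_fit(cbind(x = co$x + 100), co$time, co$event)
  expect_equal(unname(fit$beta), unname(fit_shift$beta), tolerance = 1e-6)
  fit_scale <- cox_fit(cbind(x = co$x * 4), co$time, co$event)
  expect_equal(unname(fit$beta), unname(fit_scale$beta) * 4, tolerance = 1e-6)
  expect_equal(unname(fit$beta / fit$se),
               unname(fit_scale$beta / fit_scale$se), tolerance = 1e-6)
})

test_that("LR, Wald and score statistics agree closely at large n", {
  coh <- generate_cohort(cohort_config(n_patients = 2000L, n_genes = 200L,
                                       seed = 31))
  fit <- fit_cox_model(coh$clinical, coh$truth$score)
  stats3 <- c(fit$lr_test$statistic, fit$wald_test$statistic,
              fit$score_test$statistic)
  expect_lt(diff(range(stats3)) / mean(stats3), 0.05)
})

test_that("errors are raised for degenerate inputs", {
  co <- random_cohort(30, seed = 330)
  X <- cbind(a = co$x, b = 2 * co$x)
  expect_error(cox_fit(X, co$time, co$event), "linearly dependent")
  expect_error(cox_fit(cbind(x = co$x), co$time, rep(0, 30)), "no events")
})

test_that("the 13-term interaction design has the published structure", {
  coh <- generate_cohort(small_config(seed = 17))
  X <- build_design(coh$clinical, coh$truth$score, luminal_dss_formula())
  expect_equal(ncol(X), 13L)
  expect_setequal(colnames(X), names(metabric_dss_coefficients()))
  # interaction columns are products of their parents
  expect_equal(unname(X[, "quartileQ3:pam50lumB"]),
               unname(X[, "quartileQ3"] * X[, "pam50lumB"]))
  # no-interaction formula drops to 10 marginal columns
  X0 <- build_design(coh$clinical, coh$truth$score,
                     "pam50 + grade + tumour_size + positive_lymph_nodes +
                      age_at_diagnosis + her2_status + quartile")
  expect_equal(ncol(X0), 10L)
  expect_error(build_design(coh$clinical, coh$truth$score, "nonexistent + pam50"),
               "unknown variable")
})

test_that("reparametrizing the reference level is an involution preserving the fit", {
  coh <- generate_cohort(small_config(seed = 18, n = 400L))
  fit <- fit_cox_model(coh$clinical, coh$truth$score)
  fit_b <- reparametrize_reference(coh$clinical, coh$truth$score,
                                   new_reference = list(pam50 = "lumB"))
  fit_back <- reparametrize_reference(coh$clinical, coh$truth$score,
                                      new_reference = list(pam50 = "lumA"))
  expect_equal(fit$beta, fit_back$beta, tolerance = 1e-8)
  expect_equal(unname(fit$loglik["fitted"]), unname(fit_b$loglik["fitted"]),
               tolerance = 1e-8)
  # within-lumB Q4 contrast from the original fit equals the Q4 main effect
  # under the lumB reference
  ctr <- cox_contrast(fit, c(quartileQ4 = 1, "quartileQ4:pam50lumB" = 1))
  expect_equal(ctr$estimate, unname(fit_b$beta["quartileQ4"]),
               tolerance = 1e-6)
  expect_equal(ctr$se, unname(fit_b$se["quartileQ4"]), tolerance = 1e-6)
})

test_that("adjusted survival curves reduce to the baseline at the reference profile", {
  coh <- generate_cohort(small_config(seed = 19, n = 300L))
  fit <- fit_cox_model(coh$clinical, coh$truth$score)
  ref_profile <- list(pam50 = "lumA", grade = "1", tumour_size = 0,
                      positive_lymph_nodes = 0, age_at_diagnosis = 0,
                      her2_status = "negative", quartile = "Q1")
  cur <- adjusted_survival_curves(fit, list(ref = ref_profile))$ref
  expect_equal(cur$surv, exp(-fit$baseline$cumhaz), tolerance = 1e-12)
  expect_equal(unique(cur$lp), 0)
})

test_that("log(-log) of any adjusted curve differs from baseline by its linear predictor", {
  coh <- generate_cohort(small_config(seed = 20, n = 300L))
  fit <- fit_cox_model(coh$clinical, coh$truth$score)
  prof <- covariate_profile(coh$clinical, coh$truth$score)
  prof$quartile <- "Q4"; prof$pam50 <- "lumB"
  cur <- adjusted_survival_curves(fit, list(p = prof))$p
  base <- exp(-fit$baseline$cumhaz)
  ok <- base < 1 & base > 0 & cur$surv > 0
  gap <- log(-log(cur$surv[ok])) - log(-log(base[ok]))
  expect_equal(gap, rep(cur$lp[1], sum(ok)), tolerance = 1e-9)
  # a profile missing a covariate is rejected
  prof$grade <- NULL
  expect_error(adjusted_survival_curves(fit, list(p = prof)), "missing covariate")
})

test_that("the summary table links beta, HR and CI consistently", {
  coh <- generate_cohort(small_config(seed = 21, n = 300L))
  fit <- fit_cox_model(coh$clinical, coh$truth$score)
  tab <- cox_summary_table(fit)
  expect_equal(tab$hr, exp(tab$beta), tolerance = 1e-12)
  expect_true(all(tab$ci_lower < tab$hr & tab$hr < tab$ci_upper))
  expect_gte(fit$lr_test$statistic, 0)
  expect_equal(fit$lr_test$statistic,
               2 * unname(fit$loglik["fitted"] - fit$loglik["null"]),
               tolerance = 1e-10)
})
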