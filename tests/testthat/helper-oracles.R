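# Independent brute-force oracles and small random fixtures used across the
# suite. These deliberately re-derive each quantity by direct enumeration,
# separate from the package's own code paths.

# direct product-limit enumeration
km_oracle <- function(time, event) {
  tt <- sort(unique(time))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    deaths <- sum(time == tt[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# a small random survival cohort with continuous (tie-free) times
random_cohort <- function(n, seed, p_censor = 0.3, groups = 2) {
  set.seed(seed)
  time <- rexp(n, rate = 0.1) + runif(n) * 1e-4
  event <- as.integer(runif(n) > p_censor)
  group <- factor(sample(letters[seq_len(groups)], n, replace = TRUE))
  x <- rnorm(n)
  list(time = time, event = event, group = group, x = x)
}

# fine grid search over the (Breslow or Efron) Cox partial likelihood for a
# single covariate, using a direct risk-set product definition
cox_partial_loglik_oracle <- function(beta, x, time, event, ties = "efron") {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    s0 <- sum(exp(beta * x[R]))
    s0d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      f <- if (ties == "efron") l / d else 0
      ll <- ll - log(s0 - f * s0d)
    }
  }
  ll
}

# Pearson chi-square by direct O/E summation
chisq_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Kruskal-Wallis with midranks and tie correction, by hand
kw_oracle <- function(values, group) {
  r <- rank(values)
  n <- length(values)
  groups <- split(r, group)
  H <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) length(g) * (mean(g) - (n + 1) / 2)^2,
               numeric(1)))
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H / correction
}

# exhaustive two-sided Fisher p for a 2 x 3 table by enumerating all tables
# with the observed margins
fisher_2x3_enum_oracle <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  prob_tab <- function(a, b, c2) {
    d <- rs[1] - a - b
    e <- cs[1] - a; f <- cs[2] - b; g <- cs[3] - d
    if (d < 0 || e < 0 || f < 0 || g < 0) return(NA_real_)
    exp(lfactorial(rs[1]) + lfactorial(rs[2]) +
        lfactorial(cs[1]) + lfactorial(cs[2]) + lfactorial(cs[3]) -
        lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(d) -
        lfactorial(e) - lfactorial(f) - lfactorial(g))
  }
  p_obs <- prob_tab(m[1, 1], m[1, 2], NULL)
  total <- 0
  for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[1] - a, cs[2])) {
    p <- prob_tab(a, b, NULL)
    if (!is.na(p) && p <= p_obs + 1e-12) total <- total + p
  }
  total
}

# tiny test cohort config: small gene panel, fast to simulate
small_config <- function(seed, n = 200L, genes = 120L, ...) {
  cohort_config(n_patients = n, n_genes = genes, seed = seed, ...)
}

# published coefficient table fixture used to exercise the rendered-report
# arithmetic from stored coefficients
published_cox_fit <- function() {
  beta <- metabric_dss_coefficients()
  se <- metabric_dss_se()
  p <- length(beta)
  V <- diag(se^2)
  z975 <- 1.959964
  structure(list(terms = names(beta), beta = beta, se = se, var = V,
                 hr = exp(beta),
                 ci95 = cbind(lower = exp(beta - z975 * se),
                              upper = exp(beta + z975 * se)),
                 loglik = c(null = NA_real_, fitted = NA_real_),
                 lr_test = list(statistic = NA, df = p, p_value = 1e-17),
                 wald_test = list(statistic = NA, df = p, p_value = 1e-17),
                 score_test = list(statistic = NA, df = p, p_value = 1e-17),
                 ties = "efron", n = 1175L, n_event = NA_integer_,
                 baseline = data.frame(time = numeric(0), n_event = integer(0),
                                       cumhaz = numeric(0)),
                 iterations = 0L,
                 model = list()),
            class = "cna_cox")
}
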