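test_that("chi-square statistic matches closed forms and the O/E oracle", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  m <- matrix(c(20, 5, 5, 20), 2)   # n(ad-bc)^2/(r1 r2 c1 c2) = 50*375^2/390625
  expect_equal(chi_square_test(m)$statistic, 18, tolerance = 1e-12)
  expect_equal(chi_square_test(m)$df, 1L)

  set.seed(5)
  r34 <- matrix(rpois(12, 12) + 1, 3, 4)
  expect_equal(chi_square_test(r34)$statistic, chisq_oracle(r34),
               tolerance = 1e-12)
  # permutation invariance
  expect_equal(chi_square_test(r34[c(2, 1, 3), c(4, 1, 3, 2)])$statistic,
               chi_square_test(r34)$statistic, tolerance = 1e-12)

  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)),
               "zero row/column margin")
})

test_that("Fisher exact p for a diagonal 2x2 equals the hypergeometric sum", {
  res <- fisher_exact_test(matrix(c(5, 0, 0, 5), 2))
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_test(matrix(c(0, 0, 2, 3), 2))$p_value, 1)
})

test_that("Monte-Carlo Fisher p converges to the enumerated p", {
  m <- matrix(c(6, 2, 1, 3, 2, 7), nrow = 2, byrow = TRUE)
  p_exact <- fisher_2x3_enum_oracle(m)
  res <- fisher_exact_test(m, mc_reps = 20000L, seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-4)
  # more replicates bring it closer on the same table
  res_hi <- fisher_exact_test(m, mc_reps = 100000L, seed = 7)
  expect_lt(abs(res_hi$p_value - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e5) + 1e-5)
})

test_that("Kruskal-Wallis matches hand computation, is label-invariant, handles ties", {
  res <- kruskal_wallis_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)

  set.seed(6)
  v <- rnorm(40); g <- sample(c("x", "y", "z"), 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(kruskal_wallis_test(v[perm], g[perm])$statistic,
               kruskal_wallis_test(v, g)$statistic, tolerance = 1e-12)

  vt <- c(1, 1, 2, 2, 2, 3, 4, 4)
  gt <- c("a", "a", "a", "b", "b", "b", "b", "a")
  expect_equal(kruskal_wallis_test(vt, gt)$statistic, kw_oracle(vt, gt),
               tolerance = 1e-12)

  expect_warning(res0 <- kruskal_wallis_test(rep(2, 6), rep(c("a", "b"), 3)),
                 "identical")
  expect_equal(res0$p_value, 1)
})

test_that("survival screening selects everything at alpha 1 and nothing at alpha 0", {
  coh <- generate_cohort(small_config(seed = 23, n = 250L))
  rep1 <- suppressWarnings(screen_survival_variables(coh$clinical, "os", alpha = 1))
  expect_true(all(rep1$selected))
  rep0 <- suppressWarnings(screen_survival_variables(coh$clinical, "os", alpha = 0))
  expect_false(any(rep0$selected))
  expect_true(all(rep1$p_value >= 0 & rep1$p_value <= 1))
})

test_that("screening holds its false-selection rate and detects strong effects", {
  set.seed(24)
  reps <- 200L
  false_hits <- 0L
  for (i in seq_len(reps)) {
    n <- 150L
    t_ev <- rexp(n, 0.05)
    cens <- runif(n, 0, 40)
    df <- data.frame(patient_id = as.character(seq_len(n)),
                     os_months = pmin(t_ev, cens),
                     os_event = as.integer(t_ev <= cens),
                     dss_months = pmin(t_ev, cens), dss_event = 0L,
                     pam50 = "lumA", grade = "2", tumour_size = 20,
                     positive_lymph_nodes = 0, age_at_diagnosis = 60,
                     her2_status = "negative",
                     noise = rnorm(n), stringsAsFactors = FALSE)
    cl <- as_clinical_table(df)
    rep_i <- suppressWarnings(
      screen_survival_variables(cl, "os", variables = "noise"))
    if (rep_i$selected[1]) false_hits <- false_hits + 1L
  }
  rate <- false_hits / reps
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))

  # a log-hazard-1 covariate at n = 500 is selected essentially always
  hits <- 0L
  for (i in 1:60) {
    n <- 500L
    x <- rnorm(n)
    t_ev <- rexp(n, 0.05 * exp(1.0 * x))
    cens <- runif(n, 0, 40)
    df <- data.frame(patient_id = as.character(seq_len(n)),
                     os_months = pmin(t_ev, cens),
                     os_event = as.integer(t_ev <= cens),
                     dss_months = pmin(t_ev, cens), dss_event = 0L,
                     pam50 = "lumA", grade = "2", tumour_size = 20,
                     positive_lymph_nodes = 0, age_at_diagnosis = 60,
                     her2_status = "negative",
                     marker = x, stringsAsFactors = FALSE)
    cl <- as_clinical_table(df)
    rep_i <- suppressWarnings(
      screen_survival_variables(cl, "os", variables = "marker"))
    if (rep_i$selected[1]) hits <- hits + 1L
  }
  expect_gt(hits / 60, 0.95)
})

test_that("confounder screening routes small expected cells to Fisher", {
  coh <- generate_cohort(small_config(seed = 25, n = 240L))
  cl <- coh$clinical
  # rare categorical variable -> expected cells < 5 in the 4 x 2 table
  df <- as.data.frame(cl)
  df$rare_marker <- c(rep("present", 12), rep("absent", nrow(df) - 12))
  cl2 <- as_clinical_table(df)
  rep2 <- suppressWarnings(
    screen_confounders(cl2, coh$truth$score, variables = "rare_marker"))
  expect_match(rep2$test[1], "Fisher")
  # a balanced variable uses chi-square
  df$balanced <- rep(c("u", "v"), length.out = nrow(df))
  cl3 <- as_clinical_table(df)
  rep3 <- suppressWarnings(
    screen_confounders(cl3, coh$truth$score, variables = "balanced"))
  expect_equal(rep3$test[1], "chi-square")
  # the CNA score itself is perfectly associated with its own quartiles
  rep4 <- suppressWarnings(
    screen_confounders(cl, coh$truth$score, variables = "cna_score"))
  expect_lt(rep4$p_value[1], 1e-10)
})

test_that("confounder screening holds its size for an independent variable", {
  set.seed(26)
  coh <- generate_cohort(small_config(seed = 26, n = 200L))
  reps <- 200L
  hits <- 0L
  for (i in seq_len(reps)) {
    df <- as.data.frame(coh$clinical)
    df$indep <- rnorm(nrow(df))
    cl <- as_clinical_table(df)
    rep_i <- suppressWarnings(
      screen_confounders(cl, coh$truth$score, variables = "indep"))
    if (rep_i$selected[1]) hits <- hits + 1L
  }
  rate <- hits / reps
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
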