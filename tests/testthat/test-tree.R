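# survival data with an optional hazard change-point in a continuous score
sim_tree_cohort <- function(n, score_cut = NULL, loghr = 0, rate = 0.04,
                            cens_max = 60, score_max = 100) {
  score <- sample(seq_len(score_max), n, replace = TRUE)
  lp <- if (is.null(score_cut)) rep(0, n) else loghr * (score > score_cut)
  t_ev <- rexp(n, rate * exp(lp))
  cens <- runif(n, 0, cens_max)
  list(score = score, time = pmin(t_ev, cens),
       event = as.integer(t_ev <= cens))
}

test_that("a constant variable yields no split", {
  set.seed(51)
  co <- sim_tree_cohort(100)
  expect_null(best_split(co$time, co$event, rep(3, 100)))
})

test_that("the selected cut maximises the statistic over an exhaustive scan", {
  set.seed(52)
  co <- sim_tree_cohort(80, score_cut = 50, loghr = 1)
  sp <- best_split(co$time, co$event, co$score, min_node = 10)
  vals <- sort(unique(co$score))
  cuts <- (vals[-1] + vals[-length(vals)]) / 2
  cuts <- cuts[vapply(cuts, function(c)
    sum(co$score <= c) >= 10 && sum(co$score > c) >= 10, logical(1))]
  stats <- vapply(cuts, function(c)
    logrank_test(co$time, co$event,
                 factor(co$score <= c))$statistic, numeric(1))
  expect_equal(sp$statistic, max(stats), tolerance = 1e-8)
  expect_equal(sp$cut, cuts[which.max(stats)])
  expect_equal(sp$n_candidates, length(cuts))
  expect_equal(sp$p_adjusted,
               min(1, length(cuts) *
                     pchisq(max(stats), 1, lower.tail = FALSE)))
})

test_that("ordinal quartile splits respect the ordering (3 candidates only)", {
  set.seed(53)
  n <- 200
  q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
              levels = paste0("Q", 1:4), ordered = TRUE)
  t_ev <- rexp(n, 0.04 * exp(0.8 * (q %in% c("Q3", "Q4"))))
  cens <- runif(n, 0, 60)
  sp <- best_split(pmin(t_ev, cens), as.integer(t_ev <= cens), q,
                   min_node = 20)
  expect_equal(sp$n_candidates, 3L)
  expect_true(identical(sp$left_levels, c("Q1", "Q2")) ||
              identical(sp$left_levels, "Q1") ||
              identical(sp$left_levels, c("Q1", "Q2", "Q3")))
})

test_that("a true hazard change-point is recovered", {
  set.seed(5)
  reps <- 100L
  hits <- 0L
  for (i in seq_len(reps)) {
    co <- sim_tree_cohort(400, score_cut = 50, loghr = 1.2)
    sp <- best_split(co$time, co$event, co$score, min_node = 20)
    # flanking distinct observed values around the true change-point
    lo <- max(co$score[co$score <= 50])
    hi <- min(co$score[co$score > 50])
    if (!is.null(sp) && sp$cut >= lo - 3 && sp$cut <= hi + 3) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.90)
})

test_that("the tree keeps its size under the null and finds strong binary effects", {
  set.seed(54)
  reps <- 200L
  splits <- 0L
  for (i in seq_len(reps)) {
    n <- 150L
    co <- sim_tree_cohort(n)
    df <- data.frame(patient_id = as.character(seq_len(n)),
                     os_months = co$time, os_event = co$event,
                     dss_months = co$time, dss_event = co$event,
                     pam50 = sample(c("lumA", "lumB"), n, TRUE),
                     grade = "2", tumour_size = 20,
                     positive_lymph_nodes = 0, age_at_diagnosis = 60,
                     her2_status = "negative",
                     biomarker = rnorm(n), stringsAsFactors = FALSE)
    cl <- as_clinical_table(df)
    tr <- fit_survival_tree(cl, predictors = c("pam50", "biomarker"),
                            outcome = "os")
    if (!is.null(tr$nodes[[1]]$children)) splits <- splits + 1L
  }
  # Bonferroni-adjusted splitting is conservative: at most ~alpha
  expect_lte(splits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))

  # single strong binary predictor -> depth-1 tree splitting on it
  hits <- 0L
  for (i in 1:30) {
    n <- 600L
    grp <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.04 * exp(1.5 * grp))
    cens <- runif(n, 0, 60)
    df <- data.frame(patient_id = as.character(seq_len(n)),
                     os_months = pmin(t_ev, cens),
                     os_event = as.integer(t_ev <= cens),
                     dss_months = pmin(t_ev, cens),
                     dss_event = as.integer(t_ev <= cens),
                     pam50 = ifelse(grp == 1, "lumB", "lumA"),
                     grade = "2", tumour_size = 20,
                     positive_lymph_nodes = 0, age_at_diagnosis = 60,
                     her2_status = "negative", stringsAsFactors = FALSE)
    cl <- as_clinical_table(df)
    tr <- fit_survival_tree(cl, predictors = "pam50", outcome = "os")
    root <- tr$nodes[[1]]
    if (!is.null(root$children) && root$split$variable == "pam50")
      hits <- hits + 1L
  }
  expect_gt(hits / 30, 0.95)
})

test_that("tree leaves partition the cohort and parameters act monotonically", {
  coh <- generate_cohort(small_config(seed = 55, n = 400L))
  tr <- fit_survival_tree(coh$clinical, coh$truth$score,
                          predictors = c("pam50", "cna_score",
                                         "positive_lymph_nodes"),
                          outcome = "dss")
  leaves <- tree_leaves(tr)
  ids <- unlist(lapply(leaves, `[[`, "patient_id"))
  expect_equal(sort(ids), sort(coh$clinical$patient_id))
  expect_equal(sum(vapply(leaves, `[[`, integer(1), "n")), tr$n)

  depth <- function(t) max(vapply(t$nodes, `[[`, integer(1), "depth"))
  alphas <- c(0.001, 0.05, 0.5)
  depths <- vapply(alphas, function(a)
    depth(fit_survival_tree(coh$clinical, coh$truth$score,
                            predictors = c("pam50", "cna_score"),
                            outcome = "dss", alpha = a)), integer(1))
  expect_true(all(diff(depths) >= 0))

  leaf_counts <- vapply(c(20L, 60L, 150L), function(mn)
    length(tree_leaves(fit_survival_tree(coh$clinical, coh$truth$score,
                                         predictors = c("pam50", "cna_score"),
                                         outcome = "dss", min_node = mn))),
    integer(1))
  expect_true(all(diff(leaf_counts) <= 0))
})

test_that("quartile trees recover the Q1-Q2 versus Q3-Q4 partition under that signal", {
  set.seed(56)
  hits <- 0L
  for (i in 1:20) {
    n <- 500L
    q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
                levels = paste0("Q", 1:4), ordered = TRUE)
    t_ev <- rexp(n, 0.04 * exp(1.0 * (q %in% c("Q3", "Q4"))))
    cens <- runif(n, 0, 60)
    score <- data.frame(patient_id = as.character(seq_len(n)),
                        cna_score = as.integer(q) * 100 + sample(0:49, n, TRUE),
                        quartile = q, stringsAsFactors = FALSE)
    class(score) <- c("score_table", "data.frame")
    df <- data.frame(patient_id = score$patient_id,
                     os_months = pmin(t_ev, cens),
                     os_event = as.integer(t_ev <= cens),
                     dss_months = pmin(t_ev, cens),
                     dss_event = as.integer(t_ev <= cens),
                     pam50 = "lumA", grade = "2", tumour_size = 20,
                     positive_lymph_nodes = 0, age_at_diagnosis = 60,
                     her2_status = "negative", stringsAsFactors = FALSE)
    cl <- as_clinical_table(df)
    tr <- fit_survival_tree_quartile(cl, score, outcome = "dss")
    root <- tr$nodes[[1]]
    if (!is.null(root$children) &&
        identical(root$split$left_levels, c("Q1", "Q2"))) hits <- hits + 1L
  }
  expect_gt(hits / 20, 0.8)
})

test_that("null quartile trees stay root-only about 95% of the time", {
  set.seed(57)
  reps <- 200L
  splits <- 0L
  for (i in seq_len(reps)) {
    n <- 160L
    q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
                levels = paste0("Q", 1:4), ordered = TRUE)
    t_ev <- rexp(n, 0.04)
    cens <- runif(n, 0, 60)
    score <- data.frame(patient_id = as.character(seq_len(n)),
                        cna_score = as.integer(q), quartile = q,
                        stringsAsFactors = FALSE)
    class(score) <- c("score_table", "data.frame")
    df <- data.frame(patient_id = score$patient_id,
                     os_months = pmin(t_ev, cens),
                     os_event = as.integer(t_ev <= cens),
                     dss_months = pmin(t_ev, cens),
                     dss_event = as.integer(t_ev <= cens),
                     pam50 = "lumA", grade = "2", tumour_size = 20,
                     positive_lymph_nodes = 0, age_at_diagnosis = 60,
                     her2_status = "negative", stringsAsFactors = FALSE)
    cl <- as_clinical_table(df)
    tr <- fit_survival_tree_quartile(cl, score, outcome = "dss")
    if (!is.null(tr$nodes[[1]]$children)) splits <- splits + 1L
  }
  expect_lte(splits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
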