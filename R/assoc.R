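# Confounder association battery: chi-square and Fisher tests for
# categorical-by-categorical associations, Kruskal-Wallis for continuous
# variables across CNA quartiles, and the two screening drivers.

as_count_table <- function(x) {
  m <- as.matrix(x)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("contingency table must hold non-negative integer counts")
  storage.mode(m) <- "integer"
  m
}

#' Pearson chi-square test of independence
#'
#' Classic Sigma (O-E)^2 / E statistic on an r x c count table, without
#' continuity correction, compared to chi-square on (r-1)(c-1) df.
#'
#' @param counts Count matrix (rows x columns).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(counts) {
  m <- as_count_table(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row/column margin; collapse empty categories before testing")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Fisher's exact test (2x2 exact, r x c by Monte Carlo)
#'
#' For a 2x2 table the two-sided p-value sums the hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. Larger tables use Monte-Carlo sampling of tables
#' with fixed margins and the (1 + hits)/(1 + reps) estimate.
#'
#' @param counts Count matrix.
#' @param mc_reps Monte-Carlo replicates for tables larger than 2x2.
#' @param seed Seed for the Monte-Carlo sampler (recorded in the result).
#' @return List with `p_value`, `method`, and for Monte Carlo the `mc_reps`
#'   and `seed` used.
#' @export
fisher_exact_test <- function(counts, mc_reps = 10000L, seed = 1L) {
  m <- as_count_table(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(p_value = 1, method = "degenerate margin"))
  if (nrow(m) == 2L && ncol(m) == 2L) {
    ht <- stats::fisher.test(m)
    return(list(p_value = unname(ht$p.value), method = "exact"))
  }
  p <- withr_seed(seed, {
    ht <- stats::fisher.test(m, simulate.p.value = TRUE, B = mc_reps)
    unname(ht$p.value)
  })
  list(p_value = p, method = "monte-carlo", mc_reps = mc_reps, seed = seed)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Kruskal-Wallis rank test
#'
#' Rank-based test for location differences of a continuous variable across
#' k groups, with the standard tie correction; chi-square reference on k-1
#' df. If every value is identical the statistic is undefined and p = 1 is
#' reported with a warning.
#'
#' @param values Numeric vector.
#' @param group Group labels.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_test <- function(values, group) {
  group <- factor(group)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2L) stop("Kruskal-Wallis needs at least 2 groups")
  if (length(values) < 2L) stop("Kruskal-Wallis needs at least 2 observations")
  if (length(unique(values)) == 1L) {
    warning("all values identical; Kruskal-Wallis statistic undefined, reporting p = 1")
    return(list(statistic = NA_real_, df = nlevels(group) - 1L, p_value = 1))
  }
  ht <- stats::kruskal.test(values, group)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

variable_roles <- function(clinical, variables = NULL) {
  df <- as.data.frame(clinical)
  reserved <- c("patient_id", "os_months", "os_event", "dss_months", "dss_event")
  if (is.null(variables))
    variables <- setdiff(colnames(df), reserved)
  unknown <- setdiff(variables, colnames(df))
  if (length(unknown) > 0L)
    stop("unknown clinical variable(s): ", paste(unknown, collapse = ", "))
  vapply(variables, function(v)
    if (is.numeric(df[[v]])) "continuous" else "categorical", character(1))
}

#' Screen clinical variables for association with a survival outcome
#'
#' Each candidate variable is tested marginally against the chosen outcome:
#' categorical variables by the k-group log-rank test, continuous variables
#' by the Wald test of a univariate Cox model. A variable is selected when
#' its p-value falls below `alpha`. Variables with a single observed level
#' are skipped with a warning.
#'
#' @param clinical A `clinical_table`.
#' @param outcome `"os"` or `"dss"`.
#' @param alpha Selection threshold (default 0.05).
#' @param variables Character vector of variables to screen; defaults to all
#'   non-outcome columns.
#' @return Data frame of class `screening_report`: `variable`, `type`,
#'   `test`, `statistic`, `p_value`, `selected`.
#' @export
screen_survival_variables <- function(clinical, outcome = c("os", "dss"),
                                      alpha = 0.05, variables = NULL) {
  outcome <- match.arg(tolower(outcome), c("os", "dss"))
  y <- survival_outcome(clinical, outcome)
  roles <- variable_roles(clinical, variables)
  df <- as.data.frame(clinical)
  rows <- lapply(names(roles), function(v) {
    vals <- df[[v]]
    keep <- !is.na(vals) & !is.na(y$time) & !is.na(y$event)
    res <- tryCatch({
      if (roles[[v]] == "categorical") {
        gv <- droplevels(factor(vals[keep]))
        if (nlevels(gv) < 2L) stop("single observed level")
        lr <- logrank_test(y$time[keep], y$event[keep], gv)
        list(test = "log-rank", statistic = lr$statistic, p = lr$p_value)
      } else {
        x <- matrix(as.numeric(vals[keep]), ncol = 1L, dimnames = list(NULL, v))
        if (stats::sd(x) == 0) stop("single observed level")
        cf <- cox_fit(x, y$time[keep], y$event[keep])
        z <- cf$beta / cf$se
        list(test = "univariate Cox (Wald)", statistic = unname(z^2),
             p = unname(2 * stats::pnorm(-abs(z))))
      }
    }, error = function(e) {
      warning("skipping '", v, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) return(NULL)
    data.frame(variable = v, type = roles[[v]], test = res$test,
               statistic = res$statistic, p_value = res$p,
               selected = res$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "outcome") <- outcome
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_report", "data.frame")
  out
}

#' Screen variables for association with CNA quartile (confounding)
#'
#' Tests each variable against the CNA quartile label: categorical variables
#' by the chi-square test, routed to Fisher's exact test whenever any
#' expected cell count is below 5; continuous variables by Kruskal-Wallis.
#'
#' @param clinical A `clinical_table`.
#' @param score A `score_table` with quartile labels.
#' @param alpha Selection threshold.
#' @param variables Variables to test; defaults to all non-outcome columns.
#' @param mc_reps,seed Monte-Carlo settings for r x c Fisher tests.
#' @return A `screening_report` data frame.
#' @export
screen_confounders <- function(clinical, score, alpha = 0.05,
                               variables = NULL, mc_reps = 10000L, seed = 1L) {
  df <- as.data.frame(clinical)
  idx <- match(df$patient_id, score$patient_id)
  if (anyNA(idx)) stop("score table lacks some clinical patients")
  quart <- score$quartile[idx]
  df$cna_score <- score$cna_score[idx]
  roles <- variable_roles(df, variables %||%
                            setdiff(colnames(df), c("patient_id", "os_months",
                                                    "os_event", "dss_months",
                                                    "dss_event")))
  rows <- lapply(names(roles), function(v) {
    vals <- df[[v]]
    keep <- !is.na(vals) & !is.na(quart)
    res <- tryCatch({
      if (roles[[v]] == "categorical") {
        gv <- droplevels(factor(vals[keep]))
        if (nlevels(gv) < 2L) stop("single observed level")
        tab <- table(droplevels(factor(quart[keep])), gv)
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          ft <- fisher_exact_test(tab, mc_reps = mc_reps, seed = seed)
          list(test = paste0("Fisher (", ft$method, ")"),
               statistic = NA_real_, p = ft$p_value)
        } else {
          ct <- chi_square_test(tab)
          list(test = "chi-square", statistic = ct$statistic, p = ct$p_value)
        }
      } else {
        kw <- kruskal_wallis_test(as.numeric(vals[keep]),
                                  droplevels(factor(quart[keep])))
        list(test = "Kruskal-Wallis", statistic = kw$statistic, p = kw$p_value)
      }
    }, error = function(e) {
      warning("skipping '", v, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) return(NULL)
    data.frame(variable = v, type = roles[[v]], test = res$test,
               statistic = res$statistic, p_value = res$p,
               selected = res$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_report", "data.frame")
  out
}

#' Write a screening report
#'
#' @param report A `screening_report`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
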