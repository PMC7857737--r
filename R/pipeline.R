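# End-to-end orchestration: score -> quartiles -> KM/log-rank -> screening
# -> Cox -> PH diagnostics -> survival tree -> crosstab, with all artifacts
# written as tab-delimited tables or JSON and a rendered markdown report.

#' Pipeline configuration
#'
#' Exactly one of `paths` (input files) or `synth` (a [cohort_config()])
#' must be supplied.
#'
#' @param paths Named list with `cna`, `clinical` and optionally
#'   `quantiles` file paths.
#' @param synth A `cohort_config` to generate the cohort instead of reading
#'   files.
#' @param outcome `"os"`, `"dss"` or `"both"`.
#' @param formula Cox model formula string.
#' @param alpha Screening significance threshold.
#' @param tree_alpha,min_node Survival-tree parameters.
#' @param tree_predictors Predictors offered to the survival tree.
#' @param outdir Output directory.
#' @param seed Seed recorded in the run log and used for Monte-Carlo Fisher
#'   tests.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, synth = NULL,
                            outcome = c("both", "os", "dss"),
                            formula = luminal_dss_formula(),
                            alpha = 0.05, tree_alpha = 0.05, min_node = 20L,
                            tree_predictors = c("pam50", "grade",
                                                "tumour_size",
                                                "positive_lymph_nodes",
                                                "age_at_diagnosis",
                                                "her2_status", "cna_score"),
                            outdir, seed = 1L) {
  if (is.null(paths) == is.null(synth))
    stop("supply exactly one of 'paths' or 'synth'")
  if (!is.null(paths) && !all(c("cna", "clinical") %in% names(paths)))
    stop("'paths' needs at least 'cna' and 'clinical'")
  structure(list(paths = paths, synth = synth,
                 outcome = match.arg(outcome), formula = formula,
                 alpha = alpha, tree_alpha = tree_alpha,
                 min_node = as.integer(min_node),
                 tree_predictors = tree_predictors,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full CNA-burden survival pipeline
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the result bundle: scores, per-quartile KM curves and
#'   log-rank tests, screening reports, Cox fits with diagnostics, survival
#'   trees, the quartile-by-quantile crosstab (when labels are available)
#'   and the paths of all written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  labels <- NULL
  if (!is.null(config$synth)) {
    cohort <- stage("simulate", generate_cohort(config$synth))
    cna <- cohort$cna; clinical <- cohort$clinical; labels <- cohort$labels
  } else {
    cna <- stage("read CNA", read_cna_matrix(config$paths$cna))
    clinical <- stage("read clinical", read_clinical(config$paths$clinical))
    if (!is.null(config$paths$quantiles))
      labels <- stage("read quantiles",
                      read_quantile_labels(config$paths$quantiles))
  }
  outcomes <- if (config$outcome == "both") c("os", "dss") else config$outcome

  score <- stage("CNA scoring", cna_score_table(cna))
  write_screening <- function(df, f) write_screening_report(df, file.path(config$outdir, f))
  utils::write.table(as.data.frame(score),
                     file.path(config$outdir, "cna_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(thresholds = attr(score, "thresholds"),
                            quartile_sizes = as.list(table(score$quartile))),
                       file.path(config$outdir, "quartile_thresholds.json"),
                       auto_unbox = TRUE, digits = NA)

  idx <- match(clinical$patient_id, score$patient_id)
  quart <- score$quartile[idx]
  risk_times <- seq(0, 300, by = 60)
  per_outcome <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    y <- survival_outcome(clinical, oc)
    km_by_q <- lapply(stats::setNames(levels(quart), levels(quart)), function(q) {
      sel <- quart == q
      km_estimate(y$time[sel], y$event[sel])
    })
    km_tab <- do.call(rbind, lapply(names(km_by_q), function(q)
      data.frame(quartile = q, as.data.frame(km_by_q[[q]]))))
    utils::write.table(km_tab,
                       file.path(config$outdir, paste0("km_", oc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    risk_tab <- do.call(rbind, lapply(levels(quart), function(q) {
      sel <- quart == q
      data.frame(quartile = q, time = risk_times,
                 n_risk = n_at_risk(y$time[sel], y$event[sel], risk_times))
    }))
    utils::write.table(risk_tab,
                       file.path(config$outdir, paste0("risk_table_", oc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lr <- stage(paste("log-rank", oc), logrank_test(y$time, y$event, quart))
    screening <- stage(paste("screening", oc),
                       suppressWarnings(screen_survival_variables(
                         clinical, oc, alpha = config$alpha)))
    write_screening(screening, paste0("screening_", oc, ".tsv"))
    fit <- stage(paste("Cox", oc),
                 fit_cox_model(clinical, score, config$formula, outcome = oc))
    write_cox_json(fit, file.path(config$outdir, paste0("cox_", oc, ".json")))
    writeLines(render_cox_table(fit),
               file.path(config$outdir, paste0("cox_table_", oc, ".txt")))
    ph <- stage(paste("PH diagnostics", oc), ph_diagnostics(fit))
    utils::write.table(ph$table,
                       file.path(config$outdir, paste0("ph_", oc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tree <- stage(paste("survival tree", oc),
                  fit_survival_tree(clinical, score,
                                    predictors = config$tree_predictors,
                                    outcome = oc,
                                    alpha = config$tree_alpha,
                                    min_node = config$min_node))
    write_tree_json(tree, file.path(config$outdir, paste0("tree_", oc, ".json")))
    writeLines(utils::capture.output(print(tree)),
               file.path(config$outdir, paste0("tree_", oc, ".txt")))
    medians <- vapply(km_by_q, median_survival, numeric(1))
    list(outcome = oc, km = km_by_q, medians = medians, logrank = lr,
         screening = screening, cox = fit, ph = ph, tree = tree)
  })

  confounders <- stage("confounder screening",
                       suppressWarnings(screen_confounders(
                         clinical, score, alpha = config$alpha,
                         seed = config$seed)))
  write_screening(confounders, "screening_confounders.tsv")

  ct <- overlap <- NULL
  if (!is.null(labels)) {
    ct <- stage("crosstab", crosstab(score, labels))
    write_crosstab(ct, file.path(config$outdir, "crosstab.tsv"))
    overlap <- high_risk_overlap(ct)
  }

  run_log <- list(seed = config$seed,
                  package_version = as.character(utils::packageVersion("lumcna")),
                  r_version = R.version.string,
                  n_patients = nrow(clinical),
                  n_genes = nrow(cna$calls),
                  formula = config$formula,
                  quartile_thresholds = attr(score, "thresholds"),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(run_log, file.path(config$outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  bundle <- structure(list(score = score, outcomes = per_outcome,
                           confounders = confounders, crosstab = ct,
                           overlap = overlap, config = config,
                           outdir = config$outdir),
                      class = "pipeline_bundle")
  writeLines(render_report(bundle), file.path(config$outdir, "report.md"))
  invisible(bundle)
}

#' Render a Cox fit as an aligned text table
#'
#' Columns Beta / SE / HR / 95% CI / P-value with significance codes
#' (legend: 0(***) 0.001(**) 0.01(*) 0.05(.) 0.1()); p-values below 0.001
#' are displayed as "<0.001", while the stored values keep full precision.
#'
#' @param fit A `cna_cox` fit.
#' @return Character vector of table lines.
#' @export
render_cox_table <- function(fit) {
  tab <- cox_summary_table(fit)
  fmt_p <- ifelse(tab$p_value < 0.001, "<0.001",
                  formatC(tab$p_value, digits = 3, format = "f"))
  lines <- sprintf("%-28s %8.3f %7.3f %7.3f  (%.3f-%.3f)  %7s %-3s",
                   tab$term, tab$beta, tab$se, tab$hr,
                   tab$ci_lower, tab$ci_upper, fmt_p, tab$signif)
  header <- sprintf("%-28s %8s %7s %7s  %13s  %7s %s",
                    "Term", "Beta", "SE", "HR", "95% CI", "P-value", "")
  fmt_test <- function(name, t)
    sprintf("%s p-value: %s", name,
            ifelse(t$p_value < 2e-16, "<2e-16",
                   formatC(t$p_value, digits = 3, format = "g")))
  c(header, strrep("-", nchar(header)), lines,
    strrep("-", nchar(header)),
    fmt_test("Likelihood Ratio Test", fit$lr_test),
    fmt_test("Wald Test", fit$wald_test),
    fmt_test("Score (logrank) Test", fit$score_test),
    "Significance codes: 0(***) 0.001(**) 0.01(*) 0.05(.) 0.1()")
}

#' Render the pipeline report
#'
#' Human-readable markdown summary: quartile thresholds and sizes, median
#' survival per quartile (with a "not reached" sentinel where the curve
#' never falls to 0.5), log-rank tests, the Cox coefficient tables, survival
#' trees and, when expression-quantile labels were supplied, the high-risk
#' overlap fraction. Rendering is idempotent: every number is read from the
#' bundle.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  thr <- attr(bundle$score, "thresholds")
  out <- c("# CNA-burden survival analysis report", "",
           sprintf("Patients: %d; quartile thresholds: %s",
                   nrow(bundle$score), paste(thr, collapse = " / ")),
           sprintf("Quartile sizes: %s",
                   paste(sprintf("%s=%d", names(table(bundle$score$quartile)),
                                 as.integer(table(bundle$score$quartile))),
                         collapse = ", ")), "")
  for (oc in bundle$outcomes) {
    out <- c(out, sprintf("## Outcome %s", toupper(oc$outcome)), "",
             "Median survival (months) by CNA quartile:", "")
    meds <- vapply(names(oc$medians), function(q) {
      m <- oc$medians[[q]]
      sprintf("- %s: %s", q, if (is.na(m)) "not reached" else format(m))
    }, character(1))
    lr_p <- oc$logrank$p_value
    out <- c(out, meds, "",
             sprintf("Log-rank across quartiles: chi-square %.3f on %d df, p %s",
                     oc$logrank$statistic, oc$logrank$df,
                     if (lr_p < 1e-4) "< 0.0001" else sprintf("= %.4g", lr_p)),
             "",
             sprintf("Variables selected by screening: %d of %d",
                     sum(oc$screening$selected), nrow(oc$screening)),
             "", "### Multivariable Cox model", "", "```",
             render_cox_table(oc$cox), "```", "",
             sprintf("Global PH test: p = %.4g",
                     oc$ph$table$p_value[oc$ph$table$term == "GLOBAL"]),
             "", "### Survival tree", "", "```",
             utils::capture.output(print(oc$tree)), "```", "")
  }
  if (!is.null(bundle$crosstab)) {
    out <- c(out, "## Expression-quantile stratification", "",
             sprintf("Intersection size: %d", bundle$crosstab$n), "",
             "```", utils::capture.output(print(bundle$crosstab)), "```", "",
             sprintf("High-risk overlap {Q3,Q4} x {q2,q3,q4}: %d patients (%.1f%%)",
                     bundle$overlap$count, 100 * bundle$overlap$fraction), "")
  }
  out
}
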