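# Published reference values from the METABRIC luminal analysis, kept in one
# place: the multivariable Cox coefficients (used as the true effects of the
# synthetic cohort generator) and headline numbers that can only be checked
# against the real cBioPortal brca_metabric download.

#' Published METABRIC luminal DSS Cox coefficients
#'
#' The log-hazard coefficients of the final multivariable disease-specific
#' survival model on the METABRIC luminal cohort (n = 1175): PAM50 subtype,
#' histological grade, tumour size (mm), positive lymph nodes (count), age
#' at diagnosis (years), HER2 status, CNA quartile, and quartile-by-subtype
#' interactions. Term names match the columns produced by [build_design()]
#' with [luminal_dss_formula()] and the default reference levels (lumA,
#' grade 1, HER2-negative, Q1).
#'
#' @return Named numeric vector of 13 coefficients.
#' @export
metabric_dss_coefficients <- function() {
  c(pam50lumB = 1.069,
    grade2 = 0.381,
    grade3 = 0.528,
    tumour_size = 0.015,
    positive_lymph_nodes = 0.050,
    age_at_diagnosis = 0.018,
    her2_statuspositive = 0.541,
    quartileQ2 = 0.315,
    quartileQ3 = 0.767,
    quartileQ4 = 0.839,
    "quartileQ2:pam50lumB" = -0.764,
    "quartileQ3:pam50lumB" = -0.730,
    "quartileQ4:pam50lumB" = -0.909)
}

#' Published standard errors of the METABRIC DSS coefficients
#'
#' @return Named numeric vector aligned with
#'   [metabric_dss_coefficients()].
#' @export
metabric_dss_se <- function() {
  c(pam50lumB = 0.299,
    grade2 = 0.254,
    grade3 = 0.262,
    tumour_size = 0.003,
    positive_lymph_nodes = 0.008,
    age_at_diagnosis = 0.005,
    her2_statuspositive = 0.202,
    quartileQ2 = 0.256,
    quartileQ3 = 0.247,
    quartileQ4 = 0.272,
    "quartileQ2:pam50lumB" = 0.395,
    "quartileQ3:pam50lumB" = 0.364,
    "quartileQ4:pam50lumB" = 0.370)
}

#' Published two-way table of CNA quartiles by expression quantiles
#'
#' Patient counts for the 666 luminal A cases shared between the METABRIC
#' CNA analysis and the published expression-quantile classification, rows
#' q1-q4 (expression quantile), columns Q1-Q4 (CNA quartile).
#'
#' @return A `cna_crosstab`.
#' @export
metabric_quartile_quantile_table <- function() {
  crosstab_from_counts(matrix(
    c(111, 62, 56, 19,
       76, 88, 50, 34,
       30, 40, 41, 32,
        4,  7, 10,  6),
    nrow = 4L, byrow = TRUE))
}

#' Reference checks that require the real METABRIC download
#'
#' Headline numbers of the original METABRIC luminal analysis that depend on
#' the full cBioPortal `brca_metabric` study and therefore cannot be
#' recomputed from synthetic cohorts: quartile thresholds, median survival
#' times, the log-rank significance bound, and the survival-tree CNA Score
#' cut-off (the last is approximate here because this package uses
#' Bonferroni-adjusted maximally selected log-rank splits rather than the
#' original permutation-based conditional-inference machinery). Each row is
#' flagged `requires_external_data` so integration tooling can route them to
#' a run against the real data.
#'
#' @return Data frame with `check`, `value`, `comparison`,
#'   `requires_external_data`, `approximate`.
#' @export
metabric_reference_checks <- function() {
  data.frame(
    check = c("quartile_threshold_1", "quartile_threshold_2",
              "quartile_threshold_3",
              "median_os_Q4_months", "median_os_Q3_months",
              "median_os_Q2_months", "median_os_Q1_months",
              "median_dss_Q4_months", "median_dss_Q3_months",
              "median_dss_Q2_months",
              "logrank_os_p", "logrank_dss_p",
              "tree_cna_score_cut", "tree_cut_p",
              "n_luminal", "n_lumA_shared_with_expression_quantiles",
              "n_screened_selected_os", "n_screened_selected_dss"),
    value = c(3335, 5547, 8064,
              124.2, 152.33, 173.03, 191,
              211.13, 282.57, 285.7,
              1e-4, 1e-4,
              5882, 0.006,
              1175, 666, 19, 18),
    comparison = c("approx", "approx", "approx",
                   "equal", "equal", "equal", "equal",
                   "equal", "equal", "equal",
                   "less_than", "less_than",
                   "approx", "approx",
                   "equal", "equal", "equal", "equal"),
    requires_external_data = TRUE,
    approximate = c(TRUE, TRUE, TRUE,
                    FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE,
                    FALSE, FALSE,
                    TRUE, TRUE,
                    FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}
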