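# Treatment-coded design construction for the Cox model, driven by a small
# formula string ("+" separated terms, ":" for pairwise interactions), with
# declared reference levels (lumA, grade 1, HER2-negative, CNA Q1).

default_references <- function() {
  list(pam50 = "lumA", grade = "1", her2_status = "negative", quartile = "Q1")
}

parse_model_formula <- function(formula) {
  terms <- trimws(strsplit(formula, "+", fixed = TRUE)[[1L]])
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("empty model formula")
  lapply(terms, function(tm) {
    vars <- trimws(strsplit(tm, ":", fixed = TRUE)[[1L]])
    if (length(vars) > 2L)
      stop("only pairwise interactions are supported: ", tm)
    vars
  })
}

encode_variable <- function(values, var, reference = NULL) {
  if (is.numeric(values)) {
    m <- matrix(as.numeric(values), ncol = 1L,
                dimnames = list(NULL, var))
    return(list(type = "numeric", columns = m, levels = NULL, reference = NULL))
  }
  f <- if (is.factor(values)) factor(values, ordered = FALSE) else factor(as.character(values))
  lev <- levels(f)
  if (length(lev) < 2L)
    stop("variable '", var, "' has a single observed level")
  ref <- if (!is.null(reference)) reference else lev[1L]
  if (!ref %in% lev)
    stop("reference level '", ref, "' not a level of '", var, "'")
  lev <- c(ref, setdiff(lev, ref))
  f <- factor(f, levels = lev)
  cols <- lev[-1L]
  m <- vapply(cols, function(l) as.numeric(f == l), numeric(length(f)))
  m <- matrix(m, ncol = length(cols),
              dimnames = list(NULL, paste0(var, cols)))
  list(type = "factor", columns = m, levels = lev, reference = ref)
}

#' Build a Cox design matrix from clinical data and CNA quartiles
#'
#' Treatment (dummy) coding with declared reference levels; an interaction
#' term contributes the elementwise products of the two marginal dummy sets.
#' The all-reference patient maps to the all-zero design row, so the model's
#' baseline hazard describes that profile.
#'
#' @param clinical A `clinical_table`.
#' @param score Optional `score_table`; when supplied its `quartile` column
#'   is joined by `patient_id` and made available to the formula.
#' @param formula Model formula string, e.g.
#'   `"pam50 + grade + tumour_size + quartile + quartile:pam50"`.
#' @param references Named list of reference levels overriding the defaults
#'   (lumA, grade 1, HER2-negative, Q1).
#' @return Numeric design matrix; attributes `term_info` (per-variable coding
#'   metadata), `formula`, `patient_id`.
#' @export
build_design <- function(clinical, score = NULL, formula, references = NULL) {
  refs <- utils::modifyList(default_references(), as.list(references %||% list()))
  df <- as.data.frame(clinical)
  if (!is.null(score)) {
    idx <- match(df$patient_id, score$patient_id)
    if (anyNA(idx))
      stop("score table lacks ", sum(is.na(idx)), " patient(s) from the clinical table")
    df$cna_score <- score$cna_score[idx]
    df$quartile <- factor(as.character(score$quartile[idx]),
                          levels = levels(score$quartile))
  }
  terms <- parse_model_formula(formula)
  vars <- unique(unlist(terms))
  missing_vars <- setdiff(vars, colnames(df))
  if (length(missing_vars) > 0L)
    stop("formula references unknown variable(s): ",
         paste(missing_vars, collapse = ", "))
  enc <- lapply(stats::setNames(vars, vars), function(v)
    encode_variable(df[[v]], v, refs[[v]]))
  blocks <- lapply(terms, function(tm) {
    if (length(tm) == 1L) return(enc[[tm]]$columns)
    a <- enc[[tm[1L]]]$columns; b <- enc[[tm[2L]]]$columns
    out <- matrix(0, nrow = nrow(a), ncol = ncol(a) * ncol(b))
    nm <- character(ncol(a) * ncol(b))
    k <- 0L
    for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
      k <- k + 1L
      out[, k] <- a[, i] * b[, j]
      nm[k] <- paste0(colnames(a)[i], ":", colnames(b)[j])
    }
    colnames(out) <- nm
    out
  })
  X <- do.call(cbind, blocks)
  if (anyNA(X))
    stop("design matrix contains missing values; complete cases are required")
  attr(X, "term_info") <- lapply(enc, function(e)
    e[c("type", "levels", "reference")])
  attr(X, "formula") <- formula
  attr(X, "terms_parsed") <- terms
  attr(X, "patient_id") <- df$patient_id
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a (time, event) outcome pair from a clinical table
#'
#' @param clinical A `clinical_table`.
#' @param outcome `"os"` (overall survival) or `"dss"` (disease-specific
#'   survival; deaths from other causes are censored at time of death).
#' @return List with `time` and `event`.
#' @export
survival_outcome <- function(clinical, outcome = c("os", "dss")) {
  outcome <- match.arg(tolower(outcome), c("os", "dss"))
  if (outcome == "os")
    list(time = clinical$os_months, event = clinical$os_event)
  else
    list(time = clinical$dss_months, event = clinical$dss_event)
}

#' Median/mode covariate profile
#'
#' Profile used to adjust survival curves: quantitative covariates fixed at
#' their median, categorical covariates at their mode.
#'
#' @param clinical A `clinical_table`.
#' @param score Optional `score_table` contributing `quartile`/`cna_score`.
#' @return Named list mapping variable names to a single value each.
#' @export
covariate_profile <- function(clinical, score = NULL) {
  df <- as.data.frame(clinical)
  if (!is.null(score)) {
    idx <- match(df$patient_id, score$patient_id)
    df$cna_score <- score$cna_score[idx]
    df$quartile <- score$quartile[idx]
  }
  prof <- lapply(df, function(v) {
    if (is.numeric(v)) stats::median(v, na.rm = TRUE)
    else names(which.max(table(v)))
  })
  prof$patient_id <- NULL
  prof
}

# Design row for a single covariate profile, using the coding metadata of a
# fitted design (same columns, same references).
design_row <- function(term_info, terms_parsed, profile) {
  enc1 <- lapply(stats::setNames(names(term_info), names(term_info)), function(v) {
    info <- term_info[[v]]
    if (!v %in% names(profile))
      stop("profile is missing covariate '", v, "'")
    val <- profile[[v]]
    if (info$type == "numeric") {
      m <- matrix(as.numeric(val), ncol = 1L, dimnames = list(NULL, v))
    } else {
      if (!as.character(val) %in% info$levels)
        stop("profile value '", val, "' is not a level of '", v, "'")
      cols <- info$levels[-1L]
      m <- matrix(as.numeric(cols == as.character(val)), nrow = 1L,
                  dimnames = list(NULL, paste0(v, cols)))
    }
    m
  })
  blocks <- lapply(terms_parsed, function(tm) {
    if (length(tm) == 1L) return(enc1[[tm]])
    a <- enc1[[tm[1L]]]; b <- enc1[[tm[2L]]]
    out <- matrix(0, nrow = 1L, ncol = ncol(a) * ncol(b))
    nm <- character(ncol(out)); k <- 0L
    for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
      k <- k + 1L
      out[, k] <- a[, i] * b[, j]
      nm[k] <- paste0(colnames(a)[i], ":", colnames(b)[j])
    }
    colnames(out) <- nm
    out
  })
  do.call(cbind, blocks)
}
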