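# Readers and writers for the three tabular inputs: a discrete gene-by-sample
# CNA call matrix (cBioPortal data_CNA dialect), a clinical annotation table,
# and per-patient expression-quantile labels.

#' Read a discrete CNA call matrix
#'
#' Parses a tab-delimited gene-by-sample copy-number call file in the
#' cBioPortal `data_CNA` dialect: the first two columns hold the gene symbol
#' and a numeric gene id, and every remaining column is one sample. Calls are
#' discrete: homozygous deletion (-2), hemizygous deletion (-1), diploid (0),
#' single-copy gain (+1) and high-level amplification (+2). Missing cells
#' (empty or `NA`) are kept as `NA` and counted; duplicate gene symbols are
#' retained as distinct rows keyed by (symbol, id) so that burden scores are
#' not silently altered by deduplication.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return An object of class `cna_matrix`: a list with `genes` (data frame
#'   of `symbol` and `gene_id`), `calls` (integer matrix, genes x patients,
#'   entries in -2..2 or `NA`), `patient_ids`, and `n_missing`.
#' @export
read_cna_matrix <- function(path) {
  if (!file.exists(path)) stop("CNA file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (ncol(raw) < 3L)
    stop("malformed CNA header: expected gene symbol, gene id and at least one sample column")
  patient_ids <- colnames(raw)[-(1:2)]
  if (anyDuplicated(patient_ids))
    stop("duplicate patient ids in CNA header: ",
         paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "))
  genes <- data.frame(symbol = raw[[1L]], gene_id = raw[[2L]],
                      stringsAsFactors = FALSE)
  calls <- as.matrix(raw[, -(1:2), drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(calls), nrow = nrow(calls)))
  bad <- which(!is.na(calls) & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-integer CNA call '", calls[bad[1L, , drop = FALSE]],
         "' for gene ", genes$symbol[bad[1L, 1L]],
         ", sample ", patient_ids[bad[1L, 2L]])
  out_of_range <- which(!is.na(num) & (num != round(num) | num < -2 | num > 2),
                        arr.ind = TRUE)
  if (nrow(out_of_range) > 0L)
    stop("CNA call out of range {-2,...,2}: value ", num[out_of_range[1L, , drop = FALSE]],
         " for gene ", genes$symbol[out_of_range[1L, 1L]],
         ", sample ", patient_ids[out_of_range[1L, 2L]])
  storage.mode(num) <- "integer"
  dimnames(num) <- list(NULL, patient_ids)
  n_missing <- sum(is.na(num))
  if (n_missing > 0L)
    warning(n_missing, " missing CNA call(s); they contribute 0 to burden scores")
  new_cna_matrix(genes, num)
}

new_cna_matrix <- function(genes, calls) {
  stopifnot(nrow(genes) == nrow(calls))
  structure(list(genes = genes, calls = calls,
                 patient_ids = colnames(calls),
                 n_missing = sum(is.na(calls))),
            class = "cna_matrix")
}

#' Write a CNA call matrix in the data_CNA dialect
#'
#' @param x A `cna_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cna_matrix <- function(x, path) {
  stopifnot(inherits(x, "cna_matrix"))
  out <- data.frame(Hugo_Symbol = x$genes$symbol,
                    Entrez_Gene_Id = x$genes$gene_id,
                    x$calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat("CNA call matrix:", nrow(x$calls), "genes x", ncol(x$calls),
      "patients;", x$n_missing, "missing call(s)\n")
  invisible(x)
}

#' Declare the clinical-table schema
#'
#' The schema lists required columns, their types, and the allowed level sets
#' of the categorical covariates used downstream (PAM50 subtype, histological
#' grade, HER2 status). It can be loaded from a YAML file to accommodate
#' cohorts with recoded levels.
#'
#' @param yaml_path Optional YAML file with elements `required`, `levels`.
#' @return A list with `required` (character) and `levels` (named list).
#' @export
clinical_schema <- function(yaml_path = NULL) {
  schema <- list(
    required = c("patient_id", "os_months", "os_event", "dss_months",
                 "dss_event", "pam50", "grade", "tumour_size",
                 "positive_lymph_nodes", "age_at_diagnosis", "her2_status"),
    levels = list(pam50 = c("lumA", "lumB"),
                  grade = c("1", "2", "3"),
                  her2_status = c("negative", "positive"))
  )
  if (!is.null(yaml_path)) {
    user <- yaml::read_yaml(yaml_path)
    if (!is.null(user$required)) schema$required <- as.character(user$required)
    if (!is.null(user$levels)) schema$levels <- lapply(user$levels, as.character)
  }
  schema
}

#' Read a clinical annotation table
#'
#' Reads a tab-delimited per-patient table carrying overall-survival (OS) and
#' disease-specific-survival (DSS) time/event pairs in months plus the
#' clinical covariates. Columns beyond the schema are preserved as extra
#' variables so arbitrary cohort annotations can enter the screening battery.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param schema Schema as returned by [clinical_schema()].
#' @return A data frame of class `clinical_table`; categorical schema columns
#'   are factors with declared levels, and extra column names are recorded in
#'   `attr(, "extra_variables")`.
#' @export
read_clinical <- function(path, schema = clinical_schema()) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(schema$required, colnames(raw))
  if (length(missing_cols) > 0L)
    stop("clinical table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_clinical_table(raw, schema)
}

#' Coerce a data frame to a validated clinical table
#'
#' @param df Data frame with at least the schema's required columns.
#' @param schema Schema as returned by [clinical_schema()].
#' @return A `clinical_table`.
#' @export
as_clinical_table <- function(df, schema = clinical_schema()) {
  missing_cols <- setdiff(schema$required, colnames(df))
  if (length(missing_cols) > 0L)
    stop("clinical table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient ids in clinical table")
  for (v in c("os_months", "dss_months")) {
    df[[v]] <- as.numeric(df[[v]])
    neg <- which(!is.na(df[[v]]) & df[[v]] < 0)
    if (length(neg) > 0L)
      stop("negative ", v, " at row ", neg[1L])
  }
  for (v in c("os_event", "dss_event")) {
    df[[v]] <- as.integer(df[[v]])
    bad <- which(!is.na(df[[v]]) & !df[[v]] %in% c(0L, 1L))
    if (length(bad) > 0L)
      stop(v, " must be 0/1; offending row ", bad[1L])
  }
  for (v in names(schema$levels)) {
    vals <- as.character(df[[v]])
    bad <- which(!is.na(vals) & !vals %in% schema$levels[[v]])
    if (length(bad) > 0L)
      stop("value '", vals[bad[1L]], "' for ", v, " at row ", bad[1L],
           " not in declared levels {", paste(schema$levels[[v]], collapse = ", "), "}")
    df[[v]] <- factor(vals, levels = schema$levels[[v]])
  }
  for (v in c("tumour_size", "positive_lymph_nodes", "age_at_diagnosis"))
    df[[v]] <- as.numeric(df[[v]])
  attr(df, "extra_variables") <- setdiff(colnames(df), schema$required)
  attr(df, "schema") <- schema
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table
#'
#' @param x A `clinical_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read per-patient expression-quantile labels
#'
#' Reads the two-column file of published expression-based quantile labels
#' (q1 lowest to q4 highest proliferation-gene expression), consumed as given.
#'
#' @param path Path to a tab-delimited two-column file with a header row.
#' @return A data frame with `patient_id` and `tish_quantile` (factor q1-q4).
#' @export
read_quantile_labels <- function(path) {
  if (!file.exists(path)) stop("quantile label file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 2L)
    stop("expected a two-column file (patient id, quantile label); got ",
         ncol(raw), " columns")
  colnames(raw) <- c("patient_id", "tish_quantile")
  as_quantile_labels(raw)
}

#' Coerce a data frame to validated quantile labels
#'
#' @param df Data frame with columns `patient_id`, `tish_quantile`.
#' @return Validated label table.
#' @export
as_quantile_labels <- function(df) {
  stopifnot(all(c("patient_id", "tish_quantile") %in% colnames(df)))
  df$patient_id <- as.character(df$patient_id)
  lab <- as.character(df$tish_quantile)
  bad <- which(!is.na(lab) & !lab %in% paste0("q", 1:4))
  if (length(bad) > 0L)
    stop("unknown expression-quantile label '", lab[bad[1L]],
         "' at row ", bad[1L], " (allowed: q1, q2, q3, q4)")
  df$tish_quantile <- factor(lab, levels = paste0("q", 1:4))
  class(df) <- c("quantile_labels", "data.frame")
  df
}

#' Write quantile labels
#'
#' @param x Label table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantile_labels <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Join quantile labels onto a clinical table
#'
#' Keeps only patients present in both tables and reports the intersection
#' size; patients present on one side only are dropped and counted.
#'
#' @param clinical A `clinical_table`.
#' @param labels A `quantile_labels` table.
#' @return The joined `clinical_table` with a `tish_quantile` column;
#'   `attr(, "n_intersection")` holds the intersection size.
#' @export
join_quantile_labels <- function(clinical, labels) {
  shared <- intersect(clinical$patient_id, labels$patient_id)
  if (length(shared) == 0L) stop("no shared patient ids between tables")
  dropped <- (nrow(clinical) - length(shared)) + (nrow(labels) - length(shared))
  message("quantile-label join: ", length(shared), " shared patient(s), ",
          dropped, " dropped")
  out <- clinical[match(shared, clinical$patient_id), , drop = FALSE]
  out$tish_quantile <- labels$tish_quantile[match(shared, labels$patient_id)]
  rownames(out) <- NULL
  attr(out, "n_intersection") <- length(shared)
  attr(out, "extra_variables") <- union(attr(clinical, "extra_variables"), "tish_quantile")
  attr(out, "schema") <- attr(clinical, "schema")
  class(out) <- class(clinical)
  out
}
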