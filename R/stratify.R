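# Cross-stratification of CNA quartiles against published expression
# quantiles: the two-way count table over the patient-id intersection and
# block summaries of the high-risk overlap.

#' Cross-tabulate CNA quartiles against expression quantiles
#'
#' Counts patients over the id intersection of a score table and a quantile
#' label table, optionally restricted to a clinical subset (e.g. luminal A
#' cases). Rows are expression quantiles q1-q4, columns CNA quartiles Q1-Q4.
#' Patients present in only one table are dropped and counted.
#'
#' @param score A `score_table`.
#' @param labels A `quantile_labels` table.
#' @param subset Optional character vector of patient ids to restrict to.
#' @return Object of class `cna_crosstab`: list with `counts` (4 x 4 integer
#'   matrix), `n` (grand total = intersection size after subsetting),
#'   `n_dropped`.
#' @export
crosstab <- function(score, labels, subset = NULL) {
  if (nrow(score) == 0L || nrow(labels) == 0L)
    stop("empty input table")
  shared <- intersect(score$patient_id, labels$patient_id)
  if (!is.null(subset)) shared <- intersect(shared, subset)
  if (length(shared) == 0L)
    stop("no shared patient ids between score and label tables")
  n_dropped <- (nrow(score) - length(shared)) + (nrow(labels) - length(shared))
  q <- score$quartile[match(shared, score$patient_id)]
  tq <- labels$tish_quantile[match(shared, labels$patient_id)]
  counts <- table(factor(tq, levels = paste0("q", 1:4)),
                  factor(q, levels = paste0("Q", 1:4)))
  counts <- matrix(as.integer(counts), nrow = 4L,
                   dimnames = list(paste0("q", 1:4), paste0("Q", 1:4)))
  new_crosstab(counts, n_dropped = n_dropped)
}

new_crosstab <- function(counts, n_dropped = 0L) {
  structure(list(counts = counts, n = sum(counts), n_dropped = n_dropped),
            class = "cna_crosstab")
}

#' Build a crosstab from printed counts
#'
#' Constructs a `cna_crosstab` directly from a 4 x 4 count matrix (rows
#' q1-q4, columns Q1-Q4), e.g. a published two-way table, so its margins and
#' block overlaps can be recomputed.
#'
#' @param counts 4 x 4 non-negative integer matrix.
#' @return A `cna_crosstab`.
#' @export
crosstab_from_counts <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(4L, 4L))) stop("expected a 4 x 4 count matrix")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("q", 1:4), paste0("Q", 1:4))
  new_crosstab(m)
}

#' Margins of a crosstab
#'
#' @param ct A `cna_crosstab`.
#' @return List with `quantile` (row sums), `quartile` (column sums),
#'   `total`.
#' @export
crosstab_margins <- function(ct) {
  stopifnot(inherits(ct, "cna_crosstab"))
  list(quantile = rowSums(ct$counts),
       quartile = colSums(ct$counts),
       total = sum(ct$counts))
}

#' Count and fraction of a quartile-by-quantile block
#'
#' Summarises the overlap of chosen CNA quartiles and expression quantiles -
#' e.g. the high-genomic-instability, high-proliferation-expression block
#' {Q3, Q4} x {q2, q3, q4} - as a count and a fraction of the grand total.
#'
#' @param ct A `cna_crosstab`.
#' @param quartiles CNA quartile labels (subset of Q1-Q4).
#' @param quantiles Expression quantile labels (subset of q1-q4).
#' @return List with `count` and `fraction`.
#' @export
high_risk_overlap <- function(ct, quartiles = c("Q3", "Q4"),
                              quantiles = c("q2", "q3", "q4")) {
  stopifnot(inherits(ct, "cna_crosstab"))
  bad <- c(setdiff(quartiles, colnames(ct$counts)),
           setdiff(quantiles, rownames(ct$counts)))
  if (length(bad) > 0L)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  cnt <- sum(ct$counts[quantiles, quartiles, drop = FALSE])
  list(count = cnt, fraction = cnt / sum(ct$counts))
}

#' Write a crosstab with margins
#'
#' @param ct A `cna_crosstab`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(ct, path) {
  m <- ct$counts
  out <- rbind(cbind(m, Total = rowSums(m)),
               Total = c(colSums(m), sum(m)))
  utils::write.table(data.frame(label = rownames(out), out,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cna_crosstab <- function(x, ...) {
  cat("CNA quartile x expression quantile crosstab (n = ", x$n,
      ", dropped ", x$n_dropped, ")\n", sep = "")
  m <- x$counts
  print(rbind(cbind(m, Total = rowSums(m)),
              Total = c(colSums(m), sum(m))))
  invisible(x)
}
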