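# Per-patient CNA burden scoring and ranked-quartile segmentation.

#' Compute per-patient CNA burden scores
#'
#' The CNA Score of a patient is the sum of the absolute values of the
#' discrete copy-number calls over all genes, a first-order measure of
#' genomic instability. Missing calls contribute 0, preserving cohort size.
#'
#' @param cna A `cna_matrix`.
#' @return A data frame with `patient_id` and integer `cna_score`.
#' @export
compute_cna_scores <- function(cna) {
  stopifnot(inherits(cna, "cna_matrix"))
  if (ncol(cna$calls) == 0L) stop("CNA matrix has no patients")
  score <- colSums(abs(cna$calls), na.rm = TRUE)
  data.frame(patient_id = colnames(cna$calls),
             cna_score = as.integer(score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign ranked quartiles of CNA Score
#'
#' Thresholds are the empirical 25th/50th/75th percentiles of the score
#' distribution using the order-statistic (type-1) definition, which keeps
#' thresholds on observed integer scores. A patient falls in Q1 if
#' score <= t1, Q2 if t1 < score <= t2, Q3 if t2 < score <= t3, and Q4
#' otherwise, so ties at a threshold go to the lower quartile.
#'
#' @param scores Data frame with `patient_id` and `cna_score`, as returned by
#'   [compute_cna_scores()], or a numeric vector of scores.
#' @return A data frame with `patient_id`, `cna_score` and ordered factor
#'   `quartile` (levels Q1 < Q2 < Q3 < Q4, Q1 the reference downstream);
#'   the three thresholds are in `attr(, "thresholds")`.
#' @export
assign_quartiles <- function(scores) {
  if (is.numeric(scores))
    scores <- data.frame(patient_id = as.character(seq_along(scores)),
                         cna_score = scores, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "cna_score") %in% colnames(scores)))
  if (nrow(scores) < 4L)
    stop("quartile assignment needs at least 4 patients; got ", nrow(scores))
  thr <- stats::quantile(scores$cna_score, probs = c(0.25, 0.5, 0.75),
                         type = 1, names = FALSE)
  s <- scores$cna_score
  q <- factor(paste0("Q", 1L + (s > thr[1]) + (s > thr[2]) + (s > thr[3])),
              levels = paste0("Q", 1:4), ordered = TRUE)
  if (length(unique(thr)) < 3L)
    warning("tied quartile thresholds (", paste(thr, collapse = ", "),
            "); quartile groups are degenerate")
  out <- scores
  out$quartile <- q
  attr(out, "thresholds") <- thr
  class(out) <- c("score_table", "data.frame")
  out
}

#' Score a CNA matrix and assign quartiles in one step
#'
#' @param cna A `cna_matrix`.
#' @return A `score_table` (see [assign_quartiles()]).
#' @export
cna_score_table <- function(cna) {
  assign_quartiles(compute_cna_scores(cna))
}

#' @export
print.score_table <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat("CNA Score table:", nrow(x), "patients; quartile thresholds ",
      paste(thr, collapse = " / "), "\n")
  print(table(x$quartile))
  invisible(x)
}
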