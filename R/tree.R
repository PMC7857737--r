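# Recursive-partitioning survival trees: each split maximises the two-group
# log-rank statistic over candidate cut-points (or binary level partitions),
# with a Bonferroni adjustment over the number of candidates evaluated.

# Two-group log-rank statistics for every admissible cut of a numeric
# variable, computed jointly. Rows of the internal matrices are the distinct
# event times; columns are candidate "left" groups formed by the sorted
# order of x.
maxsel_scan_numeric <- function(time, event, x, min_node) {
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  m <- length(ut)
  if (m == 0L) return(NULL)
  ordx <- order(x)
  tx <- time[ordx]; ex <- event[ordx]; xs <- x[ordx]
  A <- outer(ut, tx, function(u, t) as.numeric(t >= u))
  B <- outer(ut, tx, "==") * rep(ex, each = m)
  N1 <- t(apply(A, 1L, cumsum))
  D1 <- t(apply(B, 1L, cumsum))
  if (m == 1L) { N1 <- matrix(N1, nrow = 1L); D1 <- matrix(D1, nrow = 1L) }
  n_j <- rowSums(A); d_j <- rowSums(B)
  # candidate cut after sorted position k: only between distinct values and
  # with both children >= min_node
  k_ok <- which(seq_len(n - 1L) >= min_node &
                (n - seq_len(n - 1L)) >= min_node &
                xs[-n] < xs[-1L])
  if (length(k_ok) == 0L) return(NULL)
  OmE <- colSums(D1[, k_ok, drop = FALSE] -
                 (d_j / n_j) * N1[, k_ok, drop = FALSE])
  vw <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  P1 <- N1[, k_ok, drop = FALSE] / n_j
  V <- colSums(vw * P1 * (1 - P1))
  stat <- ifelse(V > 0, OmE^2 / V, 0)
  best <- which.max(stat)
  k <- k_ok[best]
  list(cut = (xs[k] + xs[k + 1L]) / 2,
       statistic = stat[best],
       n_candidates = length(k_ok),
       left_is_le = TRUE)
}

# Binary level partitions of an unordered factor (<= 10 levels), scored by
# the two-group log-rank statistic via per-level event/at-risk profiles.
maxsel_scan_factor <- function(time, event, g, min_node, ordered_levels = FALSE) {
  g <- droplevels(factor(g))
  lev <- levels(g)
  k <- length(lev)
  if (k < 2L) return(NULL)
  if (k > 10L)
    stop("categorical split variable has more than 10 levels")
  ut <- sort(unique(time[event == 1]))
  m <- length(ut)
  if (m == 0L) return(NULL)
  atrisk <- vapply(lev, function(l)
    vapply(ut, function(u) sum(time >= u & g == l), numeric(1)),
    numeric(m))
  deaths <- vapply(lev, function(l)
    vapply(ut, function(u) sum(time == u & event == 1 & g == l), numeric(1)),
    numeric(m))
  if (m == 1L) { atrisk <- matrix(atrisk, nrow = 1L); deaths <- matrix(deaths, nrow = 1L) }
  n_j <- rowSums(atrisk); d_j <- rowSums(deaths)
  sizes <- table(g)
  subsets <- if (ordered_levels) {
    lapply(seq_len(k - 1L), function(i) seq_len(i))
  } else {
    # non-empty proper subsets containing level 1 (complement symmetry)
    out <- list()
    for (code in seq_len(2^(k - 1L)) - 1L) {
      members <- c(1L, which(bitwAnd(code, 2^(seq_len(k - 1L) - 1L)) > 0) + 1L)
      if (length(members) < k) out[[length(out) + 1L]] <- members
    }
    out
  }
  ok <- vapply(subsets, function(s) {
    nl <- sum(sizes[s])
    nl >= min_node && (sum(sizes) - nl) >= min_node
  }, logical(1))
  subsets <- subsets[ok]
  if (length(subsets) == 0L) return(NULL)
  vw <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  stats <- vapply(subsets, function(s) {
    n1 <- rowSums(atrisk[, s, drop = FALSE])
    d1 <- rowSums(deaths[, s, drop = FALSE])
    OmE <- sum(d1 - d_j * n1 / n_j)
    p1 <- n1 / n_j
    V <- sum(vw * p1 * (1 - p1))
    if (V > 0) OmE^2 / V else 0
  }, numeric(1))
  best <- which.max(stats)
  list(left_levels = lev[subsets[[best]]],
       statistic = stats[best],
       n_candidates = length(subsets),
       levels = lev)
}

#' Best log-rank split of one variable
#'
#' For a continuous variable, scans the midpoints between consecutive
#' distinct values (both children at least `min_node` subjects) and returns
#' the cut maximising the two-group log-rank statistic; for a categorical
#' variable, scans binary level partitions (ordered partitions only when
#' `ordered = TRUE`). The p-value of the selected split is Bonferroni
#' adjusted by the number of candidates evaluated.
#'
#' @param time,event Survival outcome.
#' @param x The candidate split variable (numeric or factor).
#' @param min_node Minimum child size.
#' @param ordered For factors: restrict to order-respecting partitions.
#' @return A list (`type`, `cut` or `left_levels`, `statistic`, `p_value`,
#'   `p_adjusted`, `n_candidates`) or `NULL` when no admissible split exists.
#' @export
best_split <- function(time, event, x, min_node = 20L, ordered = FALSE) {
  check_surv_input(time, event)
  if (length(x) != length(time)) stop("variable and outcome sizes differ")
  if (length(time) < 2L * min_node) return(NULL)
  if (is.numeric(x)) {
    sc <- maxsel_scan_numeric(time, event, x, min_node)
    if (is.null(sc)) return(NULL)
    res <- list(type = "numeric", cut = sc$cut)
  } else {
    if (is.ordered(x)) ordered <- TRUE
    sc <- maxsel_scan_factor(time, event, x, min_node, ordered_levels = ordered)
    if (is.null(sc)) return(NULL)
    res <- list(type = "categorical", left_levels = sc$left_levels,
                levels = sc$levels)
  }
  p_un <- stats::pchisq(sc$statistic, 1L, lower.tail = FALSE)
  c(res, list(statistic = sc$statistic,
              p_value = p_un,
              p_adjusted = min(1, p_un * sc$n_candidates),
              n_candidates = sc$n_candidates))
}

split_goes_left <- function(split, x) {
  if (split$type == "numeric") x <= split$cut
  else as.character(x) %in% split$left_levels
}

#' Fit a recursive-partitioning survival tree
#'
#' Recursively applies [best_split()] over the candidate predictors. At each
#' node the predictor with the smallest candidate-adjusted p-value is chosen
#' and that p-value is further Bonferroni-adjusted by the number of
#' predictors tested; splitting stops when the adjusted p-value reaches
#' `alpha` or the node is smaller than `2 * min_node`. Leaves carry their
#' Kaplan-Meier curves.
#'
#' @param clinical A `clinical_table`.
#' @param score Optional `score_table` making `cna_score` and `quartile`
#'   available as predictors.
#' @param predictors Character vector of predictor names.
#' @param outcome `"os"` or `"dss"`.
#' @param alpha Significance threshold for splitting (default 0.05).
#' @param min_node Minimum node size (default 20).
#' @return Object of class `surv_tree`.
#' @export
fit_survival_tree <- function(clinical, score = NULL, predictors,
                              outcome = "dss", alpha = 0.05, min_node = 20L) {
  if (length(predictors) == 0L) stop("empty predictor list")
  df <- as.data.frame(clinical)
  if (!is.null(score)) {
    idx <- match(df$patient_id, score$patient_id)
    if (anyNA(idx)) stop("score table lacks some clinical patients")
    df$cna_score <- as.numeric(score$cna_score[idx])
    df$quartile <- score$quartile[idx]
  }
  unknown <- setdiff(predictors, colnames(df))
  if (length(unknown) > 0L)
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
  y <- survival_outcome(clinical, outcome)
  keep <- stats::complete.cases(df[, predictors, drop = FALSE]) &
    !is.na(y$time) & !is.na(y$event)
  df <- df[keep, , drop = FALSE]
  time <- y$time[keep]; event <- y$event[keep]
  nodes <- list()
  grow <- function(rows, depth) {
    id <- length(nodes) + 1L
    node <- list(id = id, depth = depth, n = length(rows),
                 patient_id = df$patient_id[rows],
                 split = NULL, children = NULL)
    nodes[[id]] <<- node
    if (length(rows) >= 2L * min_node) {
      cand <- lapply(predictors, function(v)
        best_split(time[rows], event[rows], df[[v]][rows], min_node = min_node))
      names(cand) <- predictors
      cand <- Filter(Negate(is.null), cand)
      if (length(cand) > 0L) {
        padj <- vapply(cand, `[[`, numeric(1), "p_adjusted")
        best <- names(cand)[which.min(padj)]
        sp <- cand[[best]]
        p_node <- min(1, sp$p_adjusted * length(cand))
        if (p_node < alpha) {
          sp$variable <- best
          sp$p_node <- p_node
          left <- rows[split_goes_left(sp, df[[best]][rows])]
          right <- setdiff(rows, left)
          lid <- grow(left, depth + 1L)
          rid <- grow(right, depth + 1L)
          nodes[[id]]$split <<- sp
          nodes[[id]]$children <<- c(lid, rid)
        }
      }
    }
    if (is.null(nodes[[id]]$children)) {
      km <- km_estimate(time[rows], event[rows])
      nodes[[id]]$km <<- km
      nodes[[id]]$median <<- median_survival(km)
      nodes[[id]]$n_event <<- sum(event[rows])
    }
    id
  }
  grow(seq_along(time), 0L)
  structure(list(nodes = nodes, predictors = predictors, outcome = outcome,
                 alpha = alpha, min_node = min_node, n = length(time)),
            class = "surv_tree")
}

#' Survival tree over ordinal CNA quartiles
#'
#' As [fit_survival_tree()] with the CNA quartile as an ordinal predictor:
#' only the order-respecting partitions Q1 | Q2-Q4, Q1-Q2 | Q3-Q4 and
#' Q1-Q3 | Q4 are candidate splits.
#'
#' @inheritParams fit_survival_tree
#' @param extra_predictors Additional clinical predictors alongside
#'   `quartile`.
#' @return A `surv_tree`.
#' @export
fit_survival_tree_quartile <- function(clinical, score,
                                       extra_predictors = character(0),
                                       outcome = "dss", alpha = 0.05,
                                       min_node = 20L) {
  fit_survival_tree(clinical, score,
                    predictors = c("quartile", extra_predictors),
                    outcome = outcome, alpha = alpha, min_node = min_node)
}

#' Leaf nodes of a survival tree
#'
#' @param tree A `surv_tree`.
#' @return List of leaf node records.
#' @export
tree_leaves <- function(tree) {
  Filter(function(nd) is.null(nd$children), tree$nodes)
}

format_split <- function(sp) {
  if (sp$type == "numeric")
    paste0(sp$variable, " <= ", format(sp$cut, digits = 6))
  else
    paste0(sp$variable, " in {", paste(sp$left_levels, collapse = ","), "}")
}

#' @export
print.surv_tree <- function(x, ...) {
  cat("Survival tree (", x$outcome, ", alpha = ", x$alpha,
      ", min node = ", x$min_node, "): n = ", x$n, "\n", sep = "")
  if (is.null(x$nodes[[1L]]$children)) {
    cat("  root only - no significant partition\n")
    return(invisible(x))
  }
  show <- function(id, indent, branch) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (is.null(nd$children)) {
      med <- if (is.na(nd$median)) "not reached" else format(nd$median)
      cat(pad, branch, "leaf: n = ", nd$n, ", events = ", nd$n_event,
          ", median = ", med, "\n", sep = "")
    } else {
      sp <- nd$split
      cat(pad, branch, format_split(sp), "  (p = ",
          format.pval(sp$p_node, digits = 3), ")\n", sep = "")
      show(nd$children[1L], indent + 1L, "[yes] ")
      show(nd$children[2L], indent + 1L, "[no]  ")
    }
  }
  show(1L, 0L, "")
  invisible(x)
}

#' Serialize a survival tree to JSON
#'
#' @param tree A `surv_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, depth = nd$depth, n = nd$n)
    if (!is.null(nd$split)) {
      sp <- nd$split
      out$split <- list(variable = sp$variable, type = sp$type,
                        statistic = sp$statistic,
                        p_adjusted = sp$p_adjusted, p_node = sp$p_node)
      if (sp$type == "numeric") out$split$cut <- sp$cut
      else out$split$left_levels <- sp$left_levels
      out$children <- nd$children
    } else {
      out$n_event <- nd$n_event
      out$median <- if (is.na(nd$median)) "not reached" else nd$median
    }
    out
  })
  jsonlite::write_json(list(outcome = tree$outcome, alpha = tree$alpha,
                            min_node = tree$min_node, n = tree$n,
                            nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
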