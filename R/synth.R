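# Synthetic METABRIC-like luminal cohort generator. Survival times follow a
# proportional-hazards model whose true log-hazard coefficients default to
# the published METABRIC luminal DSS estimates; CNA calls are drawn with
# subtype-dependent alteration burden so luminal B patients carry
# stochastically higher CNA Scores; censoring is administrative with uniform
# entry into the follow-up window.

# deterministic substream seeds derived from one global seed, so the CNA,
# covariate, event-time, censoring and label components can be varied
# independently
substream_seed <- function(seed, stream) {
  offsets <- c(subtype = 1L, cna = 2L, covariates = 3L, times = 4L,
               censoring = 5L, dss = 6L, quantiles = 7L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  as.integer((as.numeric(seed) * 131L + offsets[[stream]] * 10007) %% 2147483647)
}

#' Configuration of the synthetic luminal cohort
#'
#' Defaults emulate the METABRIC luminal cohort: n = 1175 patients, a
#' follow-up window of 337 months, true Cox coefficients equal to the
#' published DSS estimates, and per-patient gene-alteration rates drawn from
#' subtype-specific Beta distributions (luminal B higher on average, with
#' broad overlap) so that CNA quartiles and PAM50 subtype are associated but
#' not collinear.
#'
#' @param n_patients Cohort size.
#' @param n_genes Number of genes in the simulated CNA matrix.
#' @param p_lumB Probability a patient is luminal B.
#' @param alteration_rate List with, per subtype, either Beta(shape1,
#'   shape2) parameters for the per-patient probability that a gene carries
#'   a non-zero call, or a single fixed rate in \[0, 1\].
#' @param call_weights Category weights over calls -2, -1, +1, +2 given a
#'   gene is altered.
#' @param coefficients Named true log-hazard coefficients; names must match
#'   the design columns of [luminal_dss_formula()].
#' @param baseline List: `dist` ("exponential" or "weibull"), `rate` (per
#'   month) and, for Weibull, `shape`.
#' @param p_disease_death Probability a death is disease-specific (DSS
#'   events are thinned from deaths; other deaths are censored for DSS at
#'   the death time).
#' @param censor_window Administrative follow-up window in months: no
#'   observed time can exceed it.
#' @param entry_window Accrual period in months: patients enter uniformly
#'   over the first `entry_window` months and are administratively censored
#'   at `censor_window`, so censoring times are uniform on
#'   `[censor_window - entry_window, censor_window]`.
#' @param covariates List of marginal parameters for grade, tumour size
#'   (lognormal, mm), positive lymph nodes (negative binomial), age at
#'   diagnosis (truncated normal, years) and HER2 status.
#' @param quantile_model Ordered-logit parameters linking the expression
#'   quantile label to the standardized CNA Score (slope > 0 makes high-score
#'   patients more likely to carry high quantile labels) and the marginal
#'   label distribution.
#' @param seed Global seed; substreams are derived per component.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1175L,
                          n_genes = 1000L,
                          p_lumB = 0.4,
                          alteration_rate = list(lumA = c(2.0, 5.0),
                                                 lumB = c(3.0, 4.0)),
                          call_weights = c(`-2` = 0.15, `-1` = 0.35,
                                           `1` = 0.35, `2` = 0.15),
                          coefficients = metabric_dss_coefficients(),
                          baseline = list(dist = "exponential", rate = 2.6e-4),
                          p_disease_death = 0.7,
                          censor_window = 337,
                          entry_window = 285,
                          covariates = list(grade_probs = c(0.15, 0.45, 0.40),
                                            size_meanlog = log(23),
                                            size_sdlog = 0.5,
                                            nodes_mu = 2, nodes_size = 0.8,
                                            age_mean = 61, age_sd = 13,
                                            age_range = c(25, 96),
                                            p_her2 = 0.1),
                          quantile_model = list(slope = 1.5,
                                                marginal = c(0.372, 0.372,
                                                             0.215, 0.041)),
                          seed = 1L) {
  probs <- c(p_lumB, p_disease_death, covariates$p_her2,
             covariates$grade_probs, call_weights,
             quantile_model$marginal)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(call_weights) - 1) > 1e-8)
    stop("call weights must sum to 1")
  if (abs(sum(covariates$grade_probs) - 1) > 1e-8)
    stop("grade probabilities must sum to 1")
  if (abs(sum(quantile_model$marginal) - 1) > 1e-8)
    stop("quantile marginal must sum to 1")
  if (n_patients < 4L) stop("need at least 4 patients")
  if (baseline$rate <= 0) stop("baseline rate must be positive")
  if (entry_window <= 0 || entry_window > censor_window)
    stop("entry window must lie in (0, censor_window]")
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes), p_lumB = p_lumB,
                 alteration_rate = alteration_rate,
                 call_weights = call_weights,
                 coefficients = coefficients, baseline = baseline,
                 p_disease_death = p_disease_death,
                 censor_window = censor_window,
                 entry_window = entry_window, covariates = covariates,
                 quantile_model = quantile_model, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Load a cohort configuration from YAML
#'
#' Any field of [cohort_config()] may be overridden; omitted fields keep
#' their defaults.
#'
#' @param path YAML file.
#' @return A `cohort_config`.
#' @export
cohort_config_from_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- formals(cohort_config)
  known <- names(defaults)
  unknown <- setdiff(names(user), known)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(user$call_weights)) user$call_weights <- unlist(user$call_weights)
  if (!is.null(user$coefficients)) user$coefficients <- unlist(user$coefficients)
  do.call(cohort_config, user)
}

draw_subtypes <- function(config) {
  withr_seed(substream_seed(config$seed, "subtype"), {
    factor(ifelse(stats::runif(config$n_patients) < config$p_lumB,
                  "lumB", "lumA"), levels = c("lumA", "lumB"))
  })
}

#' Generate a synthetic CNA call matrix
#'
#' Per-gene independent categorical calls: each patient has an alteration
#' rate drawn from their subtype's Beta distribution, each gene is altered
#' with that rate, and altered genes receive a call from the category
#' weights, so luminal B patients have stochastically higher burden scores.
#'
#' @param config A `cohort_config`.
#' @param subtype Optional factor of per-patient subtypes; drawn from the
#'   subtype substream when omitted.
#' @return A `cna_matrix`.
#' @export
generate_cna_matrix <- function(config, subtype = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients; g <- config$n_genes
  if (is.null(subtype)) subtype <- draw_subtypes(config)
  draw_rate <- function(n, par) {
    if (length(par) == 1L) {
      if (par < 0 || par > 1) stop("fixed alteration rate must lie in [0, 1]")
      rep(par, n)
    } else stats::rbeta(n, par[1], par[2])
  }
  calls <- withr_seed(substream_seed(config$seed, "cna"), {
    ab <- config$alteration_rate
    rate <- ifelse(subtype == "lumB",
                   draw_rate(n, ab$lumB),
                   draw_rate(n, ab$lumA))
    altered <- matrix(stats::runif(g * n), g, n) < rep(rate, each = g)
    vals <- c(-2L, -1L, 1L, 2L)
    cat_idx <- matrix(findInterval(stats::runif(g * n),
                                   cumsum(config$call_weights),
                                   left.open = TRUE) + 1L, g, n)
    m <- matrix(0L, g, n)
    m[altered] <- vals[cat_idx[altered]]
    m
  })
  colnames(calls) <- sprintf("SYN-%04d", seq_len(n))
  genes <- data.frame(symbol = sprintf("GENE%05d", seq_len(g)),
                      gene_id = as.character(seq_len(g)),
                      stringsAsFactors = FALSE)
  new_cna_matrix(genes, calls)
}

truncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a full synthetic cohort
#'
#' Draws subtype, CNA matrix, clinical covariates, then event times from the
#' proportional-hazards model h0(t) exp(lp) where lp applies the true
#' coefficients to the patient's design row. The design row uses CNA
#' quartiles computed from the generated scores through the real scoring
#' path. Deaths are observed subject to administrative censoring (uniform
#' entry into the follow-up window); DSS events are thinned from deaths by
#' the disease-death probability, with other deaths censored for DSS at the
#' death time. Expression-quantile labels are drawn with probability
#' increasing in the patient's CNA Score.
#'
#' @param config A `cohort_config`.
#' @return List of class `synthetic_cohort`: `cna` (a `cna_matrix`),
#'   `clinical` (a `clinical_table`), `labels` (a `quantile_labels` table)
#'   and `truth` (design matrix, linear predictor, coefficients, score
#'   table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  subtype <- draw_subtypes(config)
  cna <- generate_cna_matrix(config, subtype)
  cv <- config$covariates
  covars <- withr_seed(substream_seed(config$seed, "covariates"), {
    list(grade = sample(c("1", "2", "3"), n, replace = TRUE,
                        prob = cv$grade_probs),
         size = stats::rlnorm(n, cv$size_meanlog, cv$size_sdlog),
         nodes = stats::rnbinom(n, size = cv$nodes_size, mu = cv$nodes_mu),
         age = truncnorm(n, cv$age_mean, cv$age_sd,
                         cv$age_range[1], cv$age_range[2]),
         her2 = ifelse(stats::runif(n) < cv$p_her2, "positive", "negative"))
  })
  clin <- data.frame(patient_id = colnames(cna$calls),
                     os_months = 0, os_event = 0L,
                     dss_months = 0, dss_event = 0L,
                     pam50 = as.character(subtype),
                     grade = covars$grade,
                     tumour_size = round(covars$size, 1),
                     positive_lymph_nodes = covars$nodes,
                     age_at_diagnosis = round(covars$age, 1),
                     her2_status = covars$her2,
                     stringsAsFactors = FALSE)
  clin <- as_clinical_table(clin)
  score <- cna_score_table(cna)
  X <- build_design(clin, score, luminal_dss_formula())
  beta <- config$coefficients
  missing_terms <- setdiff(colnames(X), names(beta))
  if (length(missing_terms) > 0L)
    stop("config coefficients lack term(s): ",
         paste(missing_terms, collapse = ", "))
  lp <- drop(X %*% beta[colnames(X)])
  death_time <- withr_seed(substream_seed(config$seed, "times"), {
    e <- stats::rexp(n)
    if (config$baseline$dist == "weibull") {
      shp <- config$baseline$shape
      (e / (config$baseline$rate * exp(lp)))^(1 / shp)
    } else {
      e / (config$baseline$rate * exp(lp))
    }
  })
  censor_time <- withr_seed(substream_seed(config$seed, "censoring"), {
    config$censor_window - config$entry_window * stats::runif(n)
  })
  os_event <- as.integer(death_time <= censor_time)
  os_months <- pmin(death_time, censor_time)
  disease <- withr_seed(substream_seed(config$seed, "dss"), {
    stats::runif(n) < config$p_disease_death
  })
  clin$os_months <- round(os_months, 2)
  clin$os_event <- os_event
  clin$dss_months <- clin$os_months
  clin$dss_event <- as.integer(os_event == 1L & disease)
  labels <- withr_seed(substream_seed(config$seed, "quantiles"), {
    z <- as.numeric(scale(score$cna_score))
    u <- config$quantile_model$slope * z + stats::rlogis(n)
    cuts <- stats::quantile(u, cumsum(config$quantile_model$marginal)[1:3],
                            type = 1, names = FALSE)
    q <- paste0("q", 1L + (u > cuts[1]) + (u > cuts[2]) + (u > cuts[3]))
    as_quantile_labels(data.frame(patient_id = clin$patient_id,
                                  tish_quantile = q,
                                  stringsAsFactors = FALSE))
  })
  structure(list(cna = cna, clinical = clin, labels = labels,
                 truth = list(design = X, lp = lp,
                              coefficients = beta[colnames(X)],
                              score = score),
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk in the input dialects
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Named paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cna = file.path(dir, "data_CNA.txt"),
             clinical = file.path(dir, "clinical.tsv"),
             quantiles = file.path(dir, "expression_quantiles.tsv"))
  write_cna_matrix(cohort$cna, paths["cna"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_quantile_labels(cohort$labels, paths["quantiles"])
  invisible(paths)
}
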