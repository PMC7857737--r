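# lumcna — CNA burden and survival in luminal breast cancer

`lumcna` quantifies genomic instability (GI) in luminal breast cancer from
discrete gene-level copy-number alteration (CNA) calls and relates it to
patient survival. It is aimed at biostatisticians and cancer-genomics
analysts working with cBioPortal-style discrete CNA matrices (calls in
{−2, −1, 0, +1, +2}: homozygous deletion to high-level amplification) and
clinical follow-up tables.

## The model

The core metric is the **CNA Score** of patient *j*,

```
S_j = Σ_g | c_gj |
```

the sum of absolute CNA calls over all genes — a first-order burden measure
of GI. Patients are segmented into ranked **CNA quartiles** Q1–Q4 at the
empirical 25/50/75 percentiles of the score distribution (order-statistic
percentiles; ties at a threshold fall to the lower quartile).

Around that metric the package provides from-scratch survival machinery:

- Kaplan–Meier product-limit curves, median survival with a "not reached"
  sentinel, k-group log-rank tests with hypergeometric variance;
- Cox proportional-hazards regression by Newton–Raphson on the partial
  likelihood (Efron tie correction by default, Breslow optional), with
  likelihood-ratio, Wald and score tests, Wald confidence intervals on the
  log scale, the Breslow baseline cumulative hazard, and covariate-adjusted
  survival curves `S(t|x) = exp(−H₀(t))^{exp(x'β)}`;
- the full interaction model used in the luminal analysis: PAM50 subtype,
  histological grade, tumour size, positive lymph nodes, age at diagnosis,
  HER2 status, CNA quartile, and quartile-by-subtype interactions
  (13 treatment-coded design columns, reference lumA / grade 1 /
  HER2-negative / Q1);
- scaled Schoenfeld-residual diagnostics of the PH assumption
  (Grambsch–Therneau, KM time transform);
- a confounder screening battery (log-rank and univariate Cox screening of
  clinical variables; chi-square / Fisher-exact / Kruskal–Wallis tests
  against quartile, with expected-cell-below-5 routing to Fisher);
- recursive-partitioning survival trees using maximally selected log-rank
  statistics with Bonferroni adjustment, over clinical covariates and the
  raw CNA Score (or the ordinal quartile);
- cross-stratification of CNA quartiles against published expression-based
  quantile labels (q1–q4), with block overlap summaries;
- a synthetic METABRIC-like cohort generator whose true log-hazard
  coefficients default to the published luminal DSS estimates, used for
  end-to-end testing and parameter-recovery studies.

## Worked example

Generate a synthetic cohort of 1175 luminal patients, score it, and fit the
interaction Cox model for disease-specific survival (DSS):

```r
library(lumcna)

cohort <- generate_cohort(cohort_config(seed = 1))
score  <- cna_score_table(cohort$cna)
print(score)
#> CNA Score table: 1175 patients; quartile thresholds  264 / 426 / 611
#>  Q1  Q2  Q3  Q4
#> 295 293 298 289

fit <- fit_cox_model(cohort$clinical, score, outcome = "dss")
cat(render_cox_table(fit), sep = "\n")
#> Term                             Beta      SE      HR         95% CI  P-value
#> ------------------------------------------------------------------------------
#> pam50lumB                       0.914   0.283   2.495  (1.431-4.348)    0.001 **
#> ...
#> quartileQ4                      0.779   0.216   2.179  (1.426-3.329)   <0.001 ***
#> quartileQ4:pam50lumB           -0.738   0.349   0.478  (0.241-0.948)    0.034 *
#> ------------------------------------------------------------------------------
#> Likelihood Ratio Test p-value: <2e-16
#> Significance codes: 0(***) 0.001(**) 0.01(*) 0.05(.) 0.1()
```

The quartile thresholds are the cohort's empirical score percentiles; the
positive quartile main effects say that, within luminal A, higher CNA
burden carries a higher DSS hazard (here HR ≈ 2.2 for Q3/Q4 vs Q1), while
the negative quartile-by-subtype interactions shrink those differences
inside luminal B — the qualitative structure of the published luminal
analysis. Median DSS by quartile from the same cohort:

```r
idx <- match(cohort$clinical$patient_id, score$patient_id)
lr  <- logrank_test(cohort$clinical$dss_months, cohort$clinical$dss_event,
                    score$quartile[idx])
print(lr)
#> Log-rank test: chi-square = 26.19 on 3 df, p = 8.701e-06
```

with Q1's median not reached within follow-up and Q4's at 219.4 months.

The whole analysis (scores, KM tables with risk counts, screening reports,
Cox JSON + rendered table, PH diagnostics, survival tree, crosstab, and a
markdown report) runs in one call:

```r
cfg <- pipeline_config(synth = cohort_config(seed = 1), outdir = "out")
run_pipeline(cfg)
```

or from a shell via the thin wrapper `inst/cli/lumcna.R`
(`run`, `simulate`, `score` subcommands).

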