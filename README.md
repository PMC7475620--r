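# jointpred

Joint modeling of a longitudinal biomarker and a time-to-event outcome,
with individual dynamic risk prediction and time-dependent ROC/AUC model
comparison. Built for the canonical HIV registry setting — repeated CD4
counts (modeled on a root scale) and time from diagnosis to AIDS-related
death, with sex, addiction history and age at diagnosis as covariates —
but the machinery is generic to any declining marker with right-censored
survival.

Two model families are implemented side by side:

* **SREM** (shared random-effect model): a linear mixed model for the
  marker, `Y_i(t) = β'x_i + b_i0 + (β_time + b_i1) t + ε`, whose random
  intercept and slope enter a Weibull proportional-hazards model as
  log-linear terms `α₄ b_i0 + α₅ b_i1`. One homogeneous population,
  continuous individual deviation.
* **JLCM** (joint latent class model): a finite mixture of `G` latent
  classes — multinomial-logistic membership on baseline covariates,
  class-specific trajectory intercept and slope, and class-proportional
  Weibull hazards `λ₀(t) e^{α'w + ξ_g}` — under conditional independence
  of marker and event given class. Class number is chosen by BIC
  (`−2ℓ + P log n`, with `P = 14 + 7(G−1)`) subject to a χ²₂ score test
  of the conditional-independence assumption.

Both models produce dynamic predictions — the probability of the event in
`(s, s+t]` given survival to the landmark `s` and the marker history up to
`s` — and are compared by time-dependent AUC over a landmark grid
(default `s = 1, 1.5, …, 8` years, window `t = 3`).

A seeded synthetic-cohort generator (`simulate_jlcm_cohort()`,
`simulate_srem_cohort()`) emulates the registry structure (~213 subjects,
~24% event rate, twice-yearly jittered visits, 25-year horizon) and
records the generating truth, so every stage is testable without any
external data.

## Worked example

```r
library(jointpred)

cohort <- simulate_jlcm_cohort(simulation_config(n_subjects = 250,
                                                 generator = "JLCM",
                                                 seed = 1))
ds <- filter_eligible(cohort$dataset)   # eligibility: >= 2 measurements
summarize_cohort(ds)$event_pct
#> [1] 24

srem <- fit_srem(ds, se = FALSE)
fits <- lapply(1:4, function(G) fit_jlcm(ds, G, n_starts = 2, seed = G))
cands <- lapply(fits, function(f)
  list(G = f$G, fit = f,
       score = conditional_independence_score_test(f, ds)))
sel <- select_num_classes(cands)
sel$trace
#>   G    loglik n_params      bic score_stat      score_p ci_ok
#> 1 1 -6644.904       14 13367.11  20.381893 3.750836e-05 FALSE
#> 2 2 -6619.895       21 13355.74   2.622084 2.695390e-01  TRUE
#> 3 3 -6609.509       28 13373.62   4.869009 8.764117e-02  TRUE
#> 4 4 -6599.434       35 13392.12   5.510287 6.359988e-02  TRUE
sel$G
#> [1] 2
```

Reading the trace: the single-class model decisively fails the
conditional-independence test (residual marker–hazard association,
p < 1e-4), so at least two classes are needed; among the candidates that
pass, the 2-class model has the lowest BIC and is selected. (The cohort
was generated from 3 classes, two of which are similar — at n = 250, BIC's
parsimony merges them; larger cohorts recover all three.)

```r
jlcm <- fits[[sel$G]]
classification_quality(posterior_class_probs(jlcm$params, ds))
#>   class n_assigned proportion_pct mean_max_posterior
#> 1     1         50             20          0.8549780
#> 2     2        200             80          0.9144698

cmp <- compare_models(ds, srem, jlcm)
round(cmp$average, 3)
#>  JLCM  SREM
#> 0.742 0.727
```

The high-risk class (20% of subjects, mean maximal posterior probability
0.85) is cleanly separated, and the latent-class model's landmark-averaged
AUC exceeds the shared-random-effect model's — the discrimination gain
from modeling the heterogeneity explicitly.

`run_pipeline(pipeline_config(...))` chains all of the above (ingest or
simulate → SREM → JLCM enumeration with score tests → selection →
classification → survival curves → dynamic predictions → AUC comparison →
residual diagnostics) and writes every table as CSV/JSON with a seeded run
log; `inst/cli/jointpred.R` exposes the same stages as shell subcommands
(`simulate`, `fit-srem`, `fit-jlcm`, `select`, `predict`, `evaluate`,
`run-all --config inst/cli/demo.yaml`).

See the methods vignette (`vignettes/joint-modeling-methods.Rmd`) for the
model definitions, the adaptive-quadrature likelihood, the score-test
estimator, and every defaulted constant with its rationale.

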