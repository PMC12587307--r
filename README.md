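# comorbLCA

Latent-class clustering of comorbidities and its impact on healthcare
resource use.

People with a chronic disease such as multiple sclerosis rarely have *a
number* of comorbidities that matters by itself — what matters is the
*pattern*. comorbLCA is for epidemiologists and biostatisticians who want
to move from counting conditions to clustering them: it fits latent-class
models to binary comorbidity indicators, chooses and validates the number
of clusters, identifies which comorbidities define them, and quantifies
how the clusters differ in nurse visits, physician visits, sick leave and
medication dispensations relative to people without comorbidities.

## The model

Comorbid subjects follow a finite mixture of independent Bernoullis: with
classes $k = 1..K$, weights $\pi_k$ and item probabilities $\theta_{kj}$,

$$P(x_i) = \sum_k \pi_k \prod_{j=1}^{26} \theta_{kj}^{x_{ij}}(1-\theta_{kj})^{1-x_{ij}},$$

estimated by EM with restarts (`fit_lca`). The pipeline then

1. scans $K = 1..10$ and scores BIC, entropy-augmented ICL, and the
   average silhouette width under Jaccard distance (`scan_models`);
2. takes the best $K$ under each criterion as candidates
   (`candidate_models`);
3. assesses each candidate's stability over pairs of 80% subsamples,
   scored by the clusterwise Jaccard coefficient and the adjusted Rand
   index, and keeps the most stable (`assess_stability`,
   `select_final_model`);
4. ranks comorbidities by discriminative power — half the BIC gap between
   the fitted model and one with that indicator forced class-homogeneous —
   and derives cluster labels (`discriminative_power`, `label_clusters`);
5. restores the no-comorbidity stratum as reference and estimates Cohen's
   d plus univariable and age/sex/SES-adjusted linear models per outcome
   (`outcome_report`).

A synthetic-cohort generator (`cohort_config`, `generate_cohort`)
reproduces the statistical structure of a population-based MS cohort —
a ~40% no-comorbidity stratum and two latent classes (cardiovascular- and
psychiatric-dominated) with class-linked demographics and outcome shifts —
with known ground truth, so the full pipeline runs and is testable without
patient-level data.

## Worked example

```r
library(comorbLCA)

cfg <- cohort_config(seed = 42)   # default study conditions
cfg$n_subjects <- 1200L           # scaled down for a quick run

res <- run_pipeline(pipeline_config(
  input = cfg, k_max = 4,
  fit_opts = list(n_restarts = 5),
  stability_opts = list(B = 20, f = 0.8),
  seed = 42))
print(res)
#> Comorbidity-clustering pipeline: n = 1200 (751 comorbid), selected K = 2
#>   clusters: 1 = hypertension+dyslipidaemia; 2 = anxiety+depression
#>   K = 2: mean JC 0.980, mean ARI 0.961
```

The scan shows why two clusters win — lowest BIC and ICL, highest ASW:

```r
round(as.data.frame(res$metrics)[, c("K","loglik","BIC","ICL","ASW")], 2)
#>   K   loglik      BIC      ICL  ASW
#> 1 1 -5006.42 10184.99 10184.99   NA
#> 2 2 -4599.38  9549.69  9733.22 0.28
#> 3 3 -4576.68  9683.06 10187.85 0.21
#> 4 4 -4555.10  9818.69 10503.21 0.18
```

Hypertension and anxiety carry the most discriminative power for the
clustering (rare conditions the least):

```r
head(res$dp, 5)
#>            name        dp rank
#> 1  hypertension 158.91536    1
#> 2       anxiety 137.29528    2
#> 3    depression 126.25132    3
#> 4 dyslipidaemia 111.34535    4
#> 5      diabetes  47.42659    5
```

And the adjusted models quantify resource use against the no-comorbidity
reference — e.g. the cardiovascular-dominated cluster 1 uses ~1.8 more PCP
visits and ~313 more medication dosage units per year:

```r
res$effects[res$effects$model == "adjusted" &
            res$effects$outcome %in% c("pcp_visits", "dispensations"),
            c("outcome","cluster","cohens_d","beta","ci_lo","ci_hi","p")]
#>          outcome cluster cohens_d   beta  ci_lo  ci_hi         p
#> 7     pcp_visits       1     1.71   1.77   1.57   1.96  6.14e-60
#> 8     pcp_visits       2     1.32   1.59   1.41   1.77  2.13e-57
#> 15 dispensations       1     3.47 313.43 299.00 327.86 8.10e-218
#> 16 dispensations       2     1.22 141.36 128.01 154.70  1.27e-78
```

A thin command-line wrapper with `simulate`, `cluster`, `stability`,
`outcomes` and `run` subcommands ships in `inst/cli/comorbLCA.R`.

## Documentation

The methods vignette (`vignettes/comorbidity-clustering.Rmd`) documents
the model and its assumptions, every tunable default and why it has the
value it does, the synthetic generator's scope, and known limitations.
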