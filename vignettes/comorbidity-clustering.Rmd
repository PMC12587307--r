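---
title: "Latent-class clustering of comorbidities: models, selection, stability and outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class clustering of comorbidities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

comorbLCA clusters people by their *pattern* of comorbidities rather than by
how many they have. Two patients with one condition each — say cancer versus
migraine — have very different needs; counting conditions treats them as
equal. The package was built around multimorbidity in multiple-sclerosis
(MS) cohorts drawn from primary-care records, but nothing in the machinery
is MS-specific: the input is a subject-by-indicator binary matrix plus
demographics and healthcare-use outcomes.

This vignette explains the statistical model, the decisions behind every
tunable default, what the synthetic cohort generator does and does not
emulate, and the limits of what the test suite demonstrates.

## The measurement model

Subjects with at least one comorbidity are modelled by a latent-class (LC)
model: a finite mixture of independent Bernoulli distributions. With $K$
classes, class weights $\pi_k$ and item probabilities $\theta_{kj}$ for the
$J = 26$ indicators,

$$ P(x_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J}
   \theta_{kj}^{x_{ij}} (1-\theta_{kj})^{1-x_{ij}}. $$

The key assumption is *conditional independence*: within a class, carrying
one comorbidity tells you nothing further about carrying another. Classes
therefore absorb all the co-occurrence structure. An LC model is preferred
over distance-based clustering here because binary comorbidities are
asymmetric (sharing a condition is informative, jointly lacking it much
less so), membership is probabilistic but exhaustive and exclusive after
modal assignment, and the model supports ordinary likelihood-based
diagnostics.

Subjects with no comorbidities are **not** clustered: an all-zero row makes
Jaccard distances undefined and would dominate any mixture fit. They form
their own stratum and re-enter as the reference group in the outcome
models.

### Estimation

`fit_lca()` maximises the likelihood by EM. Design choices that matter:

* **Initialisation by random responsibilities** (rows drawn from a flat
  Dirichlet), not random $\theta$: for sparse binary data random item
  probabilities often start EM in a degenerate corner, whereas random
  responsibilities begin from a data-driven M-step. Default 20 restarts;
  the model scans in this vignette's examples use fewer because the default
  synthetic classes are well separated and EM reaches the same optimum
  from almost any start.
* **Convergence** when $|\Delta\ell| < 10^{-6}(1+|\ell|)$, capped at 500
  iterations. Per-iteration log-likelihoods of the winning run are kept so
  monotonicity is checkable.
* **Boundary convention**: $\theta$ is clipped to $[10^{-6}, 1-10^{-6}]$,
  preventing the unbounded-likelihood degeneracy of Bernoulli mixtures.
* **Label switching**: classes are reported in canonical order (descending
  $\pi_k$, ties by lexicographic $\theta$ row), so "cluster 1" is stable
  across runs and seeds.
* $K = 1$ is the closed form $\hat\theta_{1j} = \bar x_{\cdot j}$; no EM.

## Choosing the number of classes

`scan_models()` fits $K = 1..10$ (ten is a deliberate ceiling: beyond that,
clinical interpretability of clusters evaporates) and records three
criteria:

* **BIC** $= -2\ell + p\log n$, $p = (K-1) + KJ$;
* **ICL**, taken as the entropy-augmented BIC: $ICL = BIC + 2EN$ with
  $EN = -\sum_{ik}\tau_{ik}\log\tau_{ik}$. Several ICL variants circulate;
  this form is the standard one, needs nothing beyond the fitted
  responsibilities, and guarantees $ICL \ge BIC$, which doubles as an
  internal consistency check. ICL favours *well-separated* classes, not
  just well-fitting ones;
* **ASW**, the average silhouette width of the modal partition under the
  **Jaccard distance** $d(x,y) = 1-|x\wedge y|/|x\vee y|$. The distance
  choice follows the same asymmetric-binary argument as above; simple
  matching would reward agreement on jointly absent conditions. Silhouettes
  of singleton clusters are set to 0 (Rousseeuw's convention), and ASW is
  undefined at $K = 1$.

The best $K$ under each criterion forms the candidate set (ties go to the
smaller $K$). The criteria need not agree — with many weakly structured
indicators, ASW often peaks at a larger $K$ than BIC — which is exactly why
the final arbiter is stability, not any single index.

## Stability: subsample pairs, Jaccard, adjusted Rand

`assess_stability()` draws, per iteration, **two independent subsamples of
80% without replacement**, refits the candidate model on each, and compares
the modal partitions on the shared subjects with two indices:

* clusterwise **Jaccard coefficient**: each cluster of the first partition
  is matched (greedily, by default) to the cluster of the second that
  maximises $|A\cap B|/|A\cup B|$; the coefficient is the size-weighted
  mean of matched similarities;
* **adjusted Rand index** in the Hubert–Arabie form, chance-corrected
  pair-counting agreement.

The candidate with the highest mean of the two indices wins
(`select_final_model()`; ties to the smaller $K$).

Scheme details that were genuinely open, and how they were fixed:

* *Pairing*: one fresh pair of subsamples per iteration ($B$ pairs total),
  rather than all pairs among $B$ subsamples — the parsimonious reading,
  and it bounds compute at $2B$ fits.
* *Fraction and replacement*: $f = 0.8$ without replacement. Bootstrap
  resampling with replacement duplicates subjects, which distorts Jaccard
  set arithmetic on the shared set.
* *Matching*: greedy per-cluster matching; a one-to-one assignment variant
  is available (`method = "assignment"`). They coincide for well-separated
  clusters; greedy is reported because it never punishes a cluster for
  another cluster's better claim.
* *Warm starts*: refits reuse the full-data parameters as one extra
  initialisation. This damps pseudo-instability caused by local optima
  rather than by the data, which would otherwise depress JC/ARI for large
  $K$ for the wrong reason.

## Which comorbidities drive the clustering

For the selected model, `discriminative_power()` quantifies each
indicator's relevance as

$$ DP_j = \tfrac12\left( BIC_{\text{hom}(j)} - BIC_{\text{het}} \right), $$

where the "homogeneous" model refits with $\theta_{1j} = \dots =
\theta_{Kj}$ (one pooled parameter, all other indicators free). This is an
approximate log-Bayes factor for class-dependence of indicator $j$:
positive values support relevance, and an indicator whose prevalence truly
does not differ across classes scores $\le 0$ in expectation because the
constrained model saves $K-1$ parameters. The constrained refits are
warm-started from the unconstrained fit, so ranking all 26 indicators
costs 26 cheap EM runs. Cluster labels (`label_clusters()`) join each
cluster's top two distinguishing indicators by DP rank; a user label map
(e.g. "Cardiovascular"/"Psychiatric") overrides.

## Outcome analysis

With the no-comorbidity stratum restored as reference, `outcome_report()`
builds, per outcome (annual nurse visits, PCP visits, sick-leave days,
medication dispensations):

* group means/SDs and **Cohen's d** against the reference, using the
  pooled-SD formula — reported because with thousands of subjects p-values
  saturate while effect sizes stay interpretable (0.2/0.5/0.8 small/
  medium/large);
* **univariable OLS** on the cluster factor — the cluster coefficient is
  then exactly the difference in group means, an identity the tests check
  to machine precision;
* **adjusted OLS** adding age (per year), sex (male reference) and
  socioeconomic quintiles (Q1, the least deprived, as reference — the
  interpretation implied by reporting Q2–Q5 against a least-deprivation
  baseline).

Sick-leave models use only subjects flagged sick-leave eligible (people on
disability pension or retired accrue no sick leave). Missing SES/smoking
are handled by complete-case analysis per model — the per-variable
availability is reported, nothing is imputed. Outcomes are count-like and
right-skewed, yet modelled by OLS on purpose: coefficients stay in natural
units (visits/year, dosage units/year). No multiple-testing correction is
applied; the report is a coherent descriptive surface, not a family of
confirmatory tests.

## The synthetic cohort generator

`cohort_config()`/`generate_cohort()` produce cohorts with the latent
structure the analysis assumes, with known ground truth:

* 5548 subjects, 60.1% with at least one comorbidity; comorbid subjects
  split 1754:1580 between a **cardiovascular-dominated** class (high
  hypertension 0.80, dyslipidaemia 0.68, diabetes 0.32; older, mean age
  56.3) and a **psychiatric-dominated** class (anxiety 0.78, depression
  0.72; younger, 80% female, more ever-smokers). Low-prevalence items
  (e.g. lung cancer below 1%) are included so the relevance ranking has a
  realistic floor.
* Comorbid rows are independent Bernoulli draws from the class profile;
  all-zero draws are rejected and redrawn so the comorbid/none strata are
  well defined. This truncation inflates observed marginals by at most
  ~2–3% of a percentage point times the class's zero-row probability
  (about 0.02 for anxiety at the defaults) — visible in recovery tests as
  a small, bounded bias.
* Outcomes are linear in class shift, age and sex with **zero-truncated
  Gaussian noise**. Baselines, slopes and noise scales were chosen once so
  the linear predictor stays at least ~2.5 SDs above zero for plausible
  subjects; then truncation is negligible and the generative model matches
  the OLS analysis model, so adjusted coefficients are unbiased for the
  configured shifts. The class shifts (e.g. +1.8 PCP visits and +331
  dispensations for the cardiovascular class) sit on the scale of the
  adjusted estimates the method is meant to produce. A mean-parameterised
  gamma noise option (`noise = "gamma"`) gives overdispersed, count-like
  outcomes when realism of dispersion matters more than exact alignment.
* Sick-leave eligibility is Bernoulli with log-odds $3.5 - 0.045\,
  \text{age}$ (~80% eligible overall, declining with age); SES is missing
  completely at random at 23.4%, smoking at 12.6%.

What the generator does **not** emulate: ICD-coding error, within-class
residual dependence between conditions (real comorbidities co-occur beyond
class structure), longitudinal visit streams, zero-inflation of outcomes,
and any MS-specific clinical course. Passing recovery tests therefore shows
the estimator is correct *under its own assumptions* — it does not certify
behaviour under the dependence structures of real registry data, where the
conditional-independence assumption is only an approximation.

## Numerical and testing choices

* Likelihoods are computed in log space with log-sum-exp; $J = 26$ causes
  no underflow.
* Empty classes in an M-step fall back to column means with a warning.
* Effect-recovery simulations evaluate the adjusted models on the
  generator's ground-truth partition. Modal assignment misclassifies a few
  percent of subjects even at the default separation, which attenuates
  cluster coefficients (a property of the clustering step, quantified by
  the ARI-versus-truth checks), and would confound a test of the outcome
  machinery itself.
* Simulation sizes in the test suite are the package's chosen working
  points: model-number recovery runs the full default cohort over 20
  seeds with 2 restarts per fit and 5 stability pairs per candidate;
  stability behaviour uses 25 subsample pairs; coverage uses 20 replicates
  (160 nominal-95% intervals). Grid-search oracles for EM use $n = 8$,
  $J \le 3$ instances where exhaustive enumeration is feasible.
* Every stochastic stage takes an explicit seed; the pipeline fans a
  master seed out per stage by a documented hash (`stage_seed()`), so any
  single stage can be reproduced in isolation.

## Known limitations

* The conditional-independence measurement model cannot represent
  within-class correlation; with strongly dependent indicators BIC tends
  to add classes to soak up dependence.
* The DP statistic ranks indicators one at a time; it is not a joint
  variable-selection search over relevance patterns, and different
  relevance criteria in the literature can order mid-table indicators
  differently.
* Greedy Jaccard matching can over-credit agreement when cluster counts
  differ grossly between subsample fits; the assignment variant is
  provided for sensitivity checks.
* OLS on skewed non-negative outcomes yields valid mean contrasts but
  non-constant variance; a robust-SE option is a natural extension and is
  intentionally not the default.
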