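---
title: "Scoring the reliability and trustworthiness of crowd video raters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the reliability and trustworthiness of crowd video raters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdtrust)
library(dplyr)
```

## The problem

Crowdsourced tagging of behavioral features in short home videos is a cheap
way to feed a diagnostic classifier for autism, but only if the workers
doing the tagging are capable, reliable and trustworthy — and worker quality
must be judged *without* telling workers the diagnosis or exposing any
ground-truth label to the metric itself. `crowdtrust` implements a family
of purely behavioral per-worker metrics, the probability-of-correct-class
(PCC) performance criterion they are screened against, and the statistical
pipeline that asks whether the metrics predict performance.

The rating task emulated throughout is: a worker watches a short video of a
child and answers M = 13 multiple-choice questions, each an ordinal scale
(4 levels by default, codes 0–3). Ratings faster than T = 120 seconds
trigger a warning and an invitation to revise; the same videos are posted
again 30 days later so returning workers re-rate them blind to their first
answers.

## Performance criterion: mean PCC

A fixed binary logistic-regression classifier maps an answer vector
$a \in \mathbb{Z}^M$ to a probability of autism
$p = \operatorname{logit}^{-1}(\beta_0 + \sum_j w_j a_j)$, treating the
ordinal codes as integers. The probability of the correct class of one
rating is $p$ when the video's true class is autism and $1-p$ otherwise,
and a worker's performance is their mean PCC over rated videos (attempt-1
ratings by default, so each worker contributes one figure). The
classifier's coefficients are *configuration*, not something this package
fits: `classifier_spec()` accepts any weights, and the simulator draws a
ground-truth specification. A probability exactly at the 0.5 threshold
classifies as the positive class; the boundary had to be fixed somewhere
and the `>=` convention is documented in `classify()`.

## The four behavioral metrics

For a worker who rated N distinct videos (metrics are only computed at all
for workers with N ≥ 10):

* **MSCL1** (mean same-child L1 distance) — test–retest reliability: the
  mean, over videos rated at both administrations, of
  $\sum_j |A_{i,j,2} - A_{i,j,1}|$. A value of 13 means the worker moved
  one ordinal level per question on average; undefined (`NA`) without any
  re-rated video.
* **MPIL1** (mean pairwise internal L1 distance) — internal variety: the
  mean L1 distance over all $N(N-1)/2$ unordered pairs of the worker's
  answer vectors. Exactly 0 for copy-paste answering; undefined for N < 2.
* **PT** (penalized time) — trustworthiness: a worker never warned receives
  the baseline score M; otherwise PT is the mean total rating time
  (initial plus revision seconds, missing revision time counting 0) plus
  $c \cdot$ RMSCL1, where RMSCL1 is the mean L1 distance between original
  and revised answers over warned-and-revised videos. Default c = 1; the
  analysis module sweeps c over [0.05, 10] in steps of 0.05. The printed
  formula is ambiguous about whether the time sum ranges over all rated
  videos or only warned ones; this package sums over all rated videos,
  which is the reading consistent with a per-worker baseline branch.
  Note the baseline M is not in seconds — PT mixes units by construction,
  which is one reason it behaves poorly; we implement it literally.
* **Mean time** — mean initial seconds per rating.

Undefined metrics propagate as explicit `NA`, never as zeros: *which*
workers have a defined metric is itself informative (low performers tend
not to return for the retest or to answer warnings), and the analysis
functions report per-metric cohort sizes for exactly that reason.

## Analysis pipeline

`correlate_metrics()` screens each metric against mean PCC with Pearson's r
and a two-sided t-based p-value, over workers whose mean rests on at least
5 underlying data points (re-rated videos for MSCL1, revised warnings for
RMSCL1, rated videos otherwise). The Bonferroni flag is `p < 0.05/4` for
the family of four primary metrics. Spearman alternatives are deliberately
out of scope — the design is a linear screen.

`sweep_pt_constant()` recomputes PT at each of the 200 grid values of c.
Because PT is linear in c, the time term and RMSCL1 are computed once per
worker and the grid is evaluated as one matrix; p-values use the exact
$t = r\sqrt{(n-2)/(1-r^2)}$ transform (a test cross-checks grid points
against `cor.test()`). `postwarning_correlations()` diagnoses PT's two
ingredients separately.

`fit_subset_regressions()` evaluates all 7 non-empty subsets of
{MSCL1, MPIL1, mean time} as OLS predictors of mean PCC with worker-level
5-fold cross-validated MAE in percentage points. Folds are a single
shuffle under a recorded seed with labels dealt 1..k, so fold sizes differ
by at most one and a worker is never split. Each subset is scored both on
all workers with that subset defined (`cv_same_set`, so cohort size varies
with missingness) and on the fixed intersection cohort with every metric
defined (`fixed_55_subset`); an intercept-only baseline row gives the MAE
of predicting the cohort mean. `cross_cohort_mae()` fits on one cohort and
evaluates on a disjoint one (shared worker ids abort as contamination),
reporting in-sample MAE alongside for comparison.

## The synthetic cohort generator

No real worker data ship with the package; `simulate_cohort()` generates
the study conditions instead: 24 videos balanced 12/12 between autism and
neurotypical, 60 workers, 13 four-level questions, the 120 s warning rule,
and a second administration of the same videos. Each video carries a
latent *ideal* answer vector drawn so the ground-truth classifier scores
its true class with PCC ≥ 0.8 (rejection sampling from a
classifier-aligned ordinal distribution); the classifier's intercept is
calibrated so the neutral mid-scale vector scores exactly 0.5.

Workers are careless-responder mixtures. Each worker has a latent
diligence in [0, 1], a personal *habitual* answer vector, and answers each
question from the video's ideal vector with probability `diligence`, from
the habitual vector otherwise, plus a small rounded Gaussian ordinal
perturbation (sd 0.3; an extra 0.4 of drift at the second administration).
Fully lazy workers (15% by default) paste their habitual vector verbatim.
This mixture — rather than plain additive noise around the ideal — is the
load-bearing design choice: additive noise would *raise* MPIL1 while
lowering PCC, coupling them with the wrong sign, whereas careless mixing
reproduces the empirically observed mechanism (low internal variety and
low performance arrive together through copy-paste behavior), so the
generator implies a positive MPIL1–PCC correlation.

With `coupling = TRUE` (the default study condition) rating time rises
with diligence (mean 30 + 330·diligence seconds, so careless workers
trigger warnings), warned workers revise toward the ideal vector with
probability proportional to their revision effort (= diligence), and the
probability of skipping the retest is 1·(1−diligence) capped at 0.9,
reproducing the informative missingness of real cohorts. With
`coupling = FALSE` (the null mode) answer quality still varies, but times,
revision behavior and revision content are independent draws — revisions
are pure ordinal noise — so time-based trust metrics carry no signal and
the c-sweep should find nothing. Both modes are exercised in the tests:
the coupled mode for parameter recovery (a detectable positive MPIL1
correlation in ≥ 80% of replicates; the 3-metric regression beating the
intercept-only baseline in ≥ 90%; cross-cohort MAE above in-sample MAE on
average), the null mode for the negative sweep finding.

Remaining generator defaults are stated assumptions, chosen once as
plausible for this kind of workforce, not estimates from data: diligence ~
Beta(5, 2) (most workers fairly diligent, a careless tail), each video
rated with probability 0.9, rating times with 25% relative noise floored
at 5 s, video durations ~ Normal(47.75, 30.71) truncated at 10 s.

## What the synthetic results do and do not show

Passing tests on simulated cohorts demonstrate that the estimators compute
their definitions exactly (loop-based oracles agree to 1e-10), that the
pipeline is deterministic under seeds, and that it *recovers structure the
generator put in* — including refusing to find a PT signal in the null
mode. They do not validate the metrics on real crowd workers, do not
reproduce the source study's specific correlation or MAE values (its raw
worker data are not public, and its trained classifier weights are not
printed), and do not test question semantics, item difficulty, or worker
learning over time, none of which the generator models. Question-level
modeling (item-response theory) is deliberately out of scope; questions
are exchangeable here.

## Numerical and design details

* Answer codes are 0-based consecutive integers; per-question level counts
  are configurable (`study_config(levels = ...)`) since the source design
  does not state them — 4 levels per question is the default.
* Ingestion is strict: malformed rows abort with the offending worker,
  video and question named, so nothing is ever silently dropped. The
  recorded `warned` flag is cross-checked against `t1_s < T` and
  inconsistencies raise a warning rather than an error (the flag is
  platform-recorded data, the cross-check an audit).
* `n_warned` counts warned videos *with a revision record*: a warning the
  worker ignored leaves nothing to measure, and this keeps "RMSCL1 defined
  iff n_warned > 0" exact.
* All metrics except MSCL1 use attempt-1 ratings only; MSCL1 pairs
  attempts by video id. Revised and attempt-2 answer vectors can be scored
  separately (`score_responses(use_revised = TRUE)`, `worker_pcc(attempt =
  2)`).
* Test problem sizes: oracle checks run 50 workers × 12 videos and a
  100-worker cohort for the regression oracle; recovery and null suites
  use 50 replicates of the default 60 × 24 design.

## Worked example

```{r example}
co <- simulate_cohort(sim_config(), seed = 42)
m <- compute_all_metrics(co$responses, co$scored, co$study)
correlate_metrics(m)
fit <- fit_subset_regressions(m, k = 5, seed = 42)
glance(fit) |> filter(cohort_mode == "fixed_55_subset")
sw <- sweep_pt_constant(co$responses, co$scored, co$study)
attr(sw, "any_positive")
```

```{r plots, fig.width = 6, fig.height = 3.5}
plot_metric_pcc(m, "mpil1")
autoplot(sw)
```
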