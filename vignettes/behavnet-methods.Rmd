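---
title: "Methods: conditional Gaussian networks for health-behavior cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional Gaussian networks for health-behavior cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavnet)
```

## The model

`behavnet` works with Bayesian networks over a mixed set of cohort
variables: binary indicators (ever-smoking, insomnia, depression,
arthritis, coded 0/1 with 1 = yes) and continuous measures (age, BMI,
accelerometer activity, PROMIS sleep scores, SF-36 quality-of-life scores,
log-transformed biomarkers). A network is a directed acyclic graph $M$
whose node set is the variable set $X$, together with one local
conditional distribution per node. The graph encodes the factorization

$$\Pr(X \mid M) = \prod_i \Pr(X_i \mid \mathrm{pa}(X_i)),$$

which `factorization()` renders as text and `log_likelihood()` evaluates on
data.

The package restricts local models to the **conditional linear Gaussian
(CG)** family:

* a continuous node is linear-Gaussian in its parents,
  $X_i = \beta_0 + \sum_j \beta_j \,\mathrm{pa}_j + \varepsilon$,
  $\varepsilon \sim N(0, \sigma_i^2)$, binary parents entering as 0/1
  shifts;
* a binary node is logistic in its (necessarily binary) parents, with
  coefficients interpretable as log-odds ratios.

The structural counterpart of this family — no continuous parent of a
discrete node — is enforced everywhere: in the scorer, in the search
blacklist, and in `fit_network()`. Parentless, strictly positive, skewed
measures (monthly alcohol intake; moderate-to-vigorous activity minutes in
the activity-deconstruction variant) instead carry a log-normal marginal,
which keeps simulated values positive without affecting any CG machinery
downstream (they only ever appear as linear regressors).

## Scoring and structure search

Model fit is measured by a rescaled BIC,

$$\mathrm{BIC}(M) = \log L(M) - \tfrac{1}{2} k \log n,$$

(higher is better; this is the classic definition divided by $-2$), with
$k$ counting an intercept and slopes plus a residual variance per
continuous node and an intercept plus slopes per binary node. The score
decomposes over nodes, which `local_score()` exposes directly and the
search exploits through per-node caching.

`hill_climb()` is a greedy single-edge search: starting from the empty
graph it applies the best add/delete/reverse move that keeps the graph
acyclic and blacklist-compliant, until no move improves the score by more
than `tol = 1e-6` (the tolerance guards against floating-point cycling
between equal-scoring states). Equal-scoring moves are broken
lexicographically by (child, parent) name so results are reproducible.
Random restarts (`restarts > 0`) re-run the climb from sparse random
admissible DAGs; the default is 0, which is already sufficient for the
strong signals in these cohorts and keeps a 500-replicate bootstrap fast.

Directionally implausible edges are excluded *a priori* by tiers declared
in the schema: quality-of-life scores are pure outcomes (no children), and
age, education, tumor stage, years since diagnosis and neighborhood
walkability are exogenous (no parents). `default_blacklist()` materializes
these constraints, plus the CG restriction, as forbidden (parent, child)
pairs; extra pairs can be supplied via configuration.

## Bootstrap model averaging

A single learned structure is a local optimum of a noisy objective. The
package follows the standard remedy: learn `B = 500` structures on
nonparametric bootstrap resamples (full $n$, with replacement), then
summarize:

* **arc strength** — the fraction of replicates containing an edge
  between two variables, irrespective of orientation;
* **direction strength** — among replicates containing the edge, the
  fraction oriented a given way.

The consensus ("averaged") network keeps arcs whose strength reaches a
data-driven threshold. `significance_threshold()` chooses, among the
observed strengths, the candidate $t$ minimizing the $L_1$ distance
between the empirical CDF of strengths and the idealized two-point CDF of
a perfectly separated strength distribution (mass $\hat F(t^-)$ at 0, the
rest at 1), breaking ties toward the larger threshold. Retained arcs are
oriented by majority direction; an exact 50/50 tie takes the orientation
that keeps the graph acyclic, then lexicographic order. Because
majority-orientation can in principle assemble a cycle out of individually
acyclic replicates, `averaged_network()` guarantees acyclicity by dropping
the weakest edge on any residual cycle and recording the repair — an
artifact of averaging, not of any single fit.

## The synthetic cohort generator

No subject-level data ship with the package. Instead,
`ground_truth_config()` + `calibrate_network()` build a fully
parameterized generative network for a cohort of overweight
postmenopausal breast-cancer survivors, and `sample_cohort()` draws
complete records from it by ancestral (topological-order) sampling. Two
variants exist: 19 variables with total physical activity, and 20 with
activity split into moderate-to-vigorous minutes and sedentary time.

The generator's fixed inputs are the published structure, the published
edge coefficients, and published marginal summaries (means/SDs for
continuous variables, prevalences for binary ones). Calibration derives
the remaining free parameters in topological order:

* **linear-Gaussian nodes**: a Monte-Carlo pilot (50,000 draws of the
  already-calibrated parent sub-network) estimates the mean and variance
  of the linear predictor; the intercept centers the node on its target
  mean, and the residual SD absorbs the remaining target variance,
  $\sigma = \sqrt{\mathrm{Var}_{target} - \mathrm{Var}_{explained}}$,
  floored at 1% of the target variance (an infeasible target — explained
  variance at or above the target — is an error naming the node);
* **logistic nodes**: the intercept is solved by root finding so the
  implied marginal prevalence matches the target — exactly through the
  parent's target prevalence for a single binary parent, otherwise
  against the pilot draws;
* **roots**: intercept and SD are the targets themselves.

Design choices worth stating explicitly:

* The log-scale biomarker targets are the published obese / non-obese
  group means and SDs blended by the obesity weight
  $P(\mathrm{BMI} \ge 30)$ under $N(31.1, 4.9)$, because only medians and
  IQRs are published for the raw assays. The natural logarithm is used
  throughout (consistent with the published log-scale group means, with
  CRP handled on the log pg/mL scale on which those group means are
  expressed).
* BMI is generated as an untruncated normal even though the cohort
  enrolled only overweight women; untruncated moments reproduce the
  published obese/non-obese conditional means to first order. A
  `truncate_bmi_at_25` flag exists but defaults off.
* Variables with no edges in the published structure (tumor stage, years
  since diagnosis, neighborhood, education, alcohol, coping, and the
  root binaries) are sampled independently from their marginals. Alcohol
  has only a published median (4 drinks/month); a log-normal with
  `meanlog = log 4`, `sdlog = 1` was chosen once as a realistic
  right-skewed monthly count and not revisited. Education enters as its
  college-degree indicator and tumor stage as the moments of the printed
  stage distribution; both are isolated nodes, so these conventions have
  no downstream effect.
* The sleep-impairment local model in the total-activity variant reuses
  the activity-deconstruction variant's published row (the total-activity
  table omits it); the two variants print essentially identical estimates
  for every shared edge, so the transfer is innocuous.
* One root seed drives everything, but each node draws from its own
  substream (a stable hash of the node name), so cohorts are
  bit-reproducible and adding a variable never perturbs the draws of
  existing ones. Identical seed and configuration give identical CSVs.

What the generator deliberately does **not** emulate: missing data,
measurement error, longitudinal follow-up, floor/ceiling effects and
skewness in the SF-36 and PROMIS instruments, and the selection of the
real cohort into a weight-loss trial. Tests that pass on these synthetic
cohorts therefore validate the algorithms under the published effect
sizes and noise levels — they do not certify behavior under real-data
pathologies such as informative missingness.

## Network comparison and intervention prediction

`network_bic()` refits a structure on data and reports the rescaled BIC;
`compare_networks()` reports the BIC difference, which is also the log
Bayes factor under the BIC approximation (the two are reported as the
same number by construction). Two comparison idioms mirror common
practice: deleting a single edge, and isolating a node by removing all its
incident edges (`isolate_node()`).

`propagate()` predicts intervention contrasts by **logic sampling**:
forward ancestral sampling of the joint, followed by rejection against
each condition's evidence. Evidence predicates are half-open intervals
`[lo, hi)`, exact binary values, or marginal-quantile tails (e.g. above
the 75th percentile), the latter resolved against an unconditioned
reference sample at query time; published activity cut-points (270 / 380
counts/min/day) ship as fixed presets. Sampling proceeds in batches until
both conditions reach `min_accepted` draws (default 100,000, so
Monte-Carlo error is well below reporting precision: the published
per-condition tables imply large effective samples) or a batch cap is
reached, in which case the result is flagged. Joint conditions (the
combined sleep + weight query) condition on all predicates
simultaneously.

This is observational conditioning, not a do-calculus intervention:
evidence also updates the posterior of the conditioned variable's
ancestors. That matches what logic sampling computes and what the
published contrasts report; truncated-factorization interventions are out
of scope.

## Numerical choices

* Gaussian ML variances are floored at `1e-8` in scoring (and reported
  residual SDs at `1e-6` in fits) so degenerate constant columns score
  finitely instead of diverging.
* BIC uses the ML variance denominator $n$; reported residual SDs use the
  unbiased $n - p$. The two conventions are kept consistent between the
  scorer and `fit_network()`.
* Logistic fits are unpenalized maximum likelihood (IRLS to `1e-10`);
  separation is an error naming the node, with an optional ridge fallback
  flag for degenerate user data. The calibrated cohorts cannot separate
  at study size under the published prevalences.
* A constant 0/1 column is treated as degenerate continuous (it hits the
  variance floor) rather than binary; binary columns require both levels.

## Problem sizes in the test suite

The suite validates the pipeline at the study's own scale: study-size
cohorts ($n = 333$) for structure learning and refitting, 500-replicate
bootstraps for stability, 50-replicate seeded batches for BIC-loss
recovery, 200 replicates for coefficient and standard-error calibration,
100,000-draw marginal checks, and at least 100,000 accepted draws per
propagation condition. Brute-force oracles (path enumeration for
d-separation, exhaustive DAG enumeration for the searcher, grid
integration for the threshold) run on deliberately small instances
(≤ 7 nodes, ≤ 4 variables) where exhaustion is exact.

## Known limitations

* Greedy search with random restarts has no optimality guarantee beyond
  the small-instance checks; the bootstrap-averaged network, not any
  single climb, is the intended primary output.
* Arc strengths are computed for the orientation-blind edge; in
  score-equivalent situations (e.g. two binary variables with no other
  neighbors) direction strengths hover near 0.5 and should not be
  over-interpreted.
* The recovery checks compare synthetic-cohort statistics against
  published point estimates; data-dependent absolutes (raw BIC levels,
  the exact arc-strength table of the real cohort) are not reproducible
  without the study data and are validated only through
  tolerance-banded recovery.
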