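---
title: "Cognitive diagnosis models and learning-trajectory extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive diagnosis models and learning-trajectory extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmtraj)
```

## The measurement model

`cdmtraj` analyses dichotomous test data under restricted latent-class
models known as cognitive diagnosis models (CDMs). The latent variable is
an *attribute pattern* $\alpha = (\alpha_1,\dots,\alpha_K) \in \{0,1\}^K$:
a binary mastery indicator for each of $K$ fine-grained skills. A
$J \times K$ Q-matrix $q_{jk}$ states which attributes item $j$ requires.
Each item's response probability depends on $\alpha$ only through the
*reduced pattern* — the projection of $\alpha$ onto the attributes the
item requires — so an item requiring $K_j$ attributes distinguishes
$2^{K_j}$ equivalence classes of respondents.

Six members of the G-DINA family are implemented, each a fixed pairing of
structure and link:

| model | structure | link | free item parameters |
|-------|-----------|------|----------------------|
| DINA  | conjunctive (and-gate) | identity | guess $g_j$, slip $s_j$ |
| DINO  | disjunctive (or-gate)  | identity | guess $g_j$, slip $s_j$ |
| A-CDM | additive | identity | $\delta_{j0}$ + one main effect per required attribute |
| LLM   | additive | logit    | same, on the logit scale |
| RRUM  | additive | log      | same, on the log scale |
| G-DINA| saturated | identity | one probability per reduced pattern ($2^{K_j}$) |

For the additive models,
$f(P(X_j = 1 \mid \alpha)) = \delta_{j0} + \sum_{k: q_{jk}=1}
\delta_{jk}\alpha_k$ with $f$ the link. The saturated G-DINA nests every
other model; DINA and DINO arise from it by zeroing all but two of each
item's probabilities. The log-link additive form is an equivalent
parameterization of the reduced reparameterized unified model (R-RUM),
and the logit-link *saturated* model (sometimes presented separately as
the LCDM) is a reparameterization of the saturated G-DINA — the package
exposes only `GDINA` for that likelihood, and the published comparison
table treats the LCDM row with the saturated parameter count.

The marginal likelihood of person $i$ with responses $x_i$ is
$\sum_{c} \pi_c \prod_j P_j(\alpha_c)^{x_{ij}} (1-P_j(\alpha_c))^{1-x_{ij}}$
over all $2^K$ latent classes, with mixing weights $\pi$. Missing scores
are skipped person-by-item.

## Estimation

`em_fit()` maximizes the marginal likelihood by EM.

* **E-step.** Posterior class-membership probabilities for every person
  under the current parameters.
* **M-step.** $\pi$ is the mean posterior. For identity-link structures
  (DINA, DINO, saturated) the item updates are closed-form
  posterior-weighted success proportions per reduced pattern, DINA/DINO
  pooling their two groups. The additive models maximize the expected
  complete-data log-likelihood numerically (BFGS; under the default
  monotonicity constraint, via a log-barrier method with the linear
  constraints that keep main effects non-negative and identity/log-link
  probabilities inside $[0,1]$). A numerical update is accepted only when
  it does not decrease the expected complete-data log-likelihood, so the
  algorithm is a generalized EM and the observed log-likelihood trace is
  non-decreasing — a property the test suite checks on randomized
  instances.

Numerical choices, all overridable:

* **Initialization** is deterministic: uniform class weights; guess and
  slip 0.2; additive/saturated success probabilities linearly spaced from
  0.2 (nothing mastered) to 0.8 (everything mastered). A `seed` argument
  jitters the start by up to ±0.01 when basins of attraction are a
  concern.
* **Convergence**: largest absolute change in implied success
  probabilities and class weights, or in the log-likelihood, below
  `tol = 1e-4`; `max_iter = 1000`.
* **Boundary guard**: estimated probabilities are clipped to
  $[10^{-4}, 1-10^{-4}]$ inside M-steps, so items without score variation
  degrade gracefully (with a warning) instead of diverging.
* **Monotonicity** (mastery never lowers the success probability) is
  enforced by default for the additive models and not for DINA/DINO or
  the saturated model, the convention in this literature. User-facing
  `irf()` evaluation *errors* on additive parameters whose implied
  probability leaves $[0,1]$ rather than clamping silently, so estimation
  bugs cannot hide.

Model comparison uses deviance $-2\ell$, $\mathrm{AIC} = -2\ell + 2p$ and
$\mathrm{BIC} = -2\ell + p\ln N$ with $N$ the number of persons fitted;
`select_model()` prefers the lowest BIC, breaking ties by AIC and then by
parameter count. The free-parameter count is the item total (2 per item;
$K_j + 1$; or $2^{K_j}$) plus $2^K - 1$ class proportions.

## Person inference and group summaries

`posterior_classes()` applies Bayes rule with the fitted class
distribution as prior; `eap_mastery()` gives each person's marginal
mastery probability per attribute (the EAP); `classify_mastery()`
thresholds the marginals at 0.5, a probability exactly at the threshold
counting as mastered — the tie rule is fixed for determinism. MAP
(posterior-mode pattern) and MLE (likelihood-mode pattern) are available
through `mastery_profiles(method = )`; whether a published analysis
thresholded EAP marginals or took the posterior mode is often ambiguous,
so both are provided with EAP-threshold as the default. Group summaries
are the per-group attribute means of the marginals and the per-group
pattern frequency tables (`pattern_frequencies()`, optionally restricted
to the top $k$ patterns as printed country tables usually are).

### Pooled versus multigroup calibration

A single pooled fit estimates one class distribution for everyone. When
groups genuinely differ in their latent-class composition, classifying
every person against the pooled prior shrinks group-specific pattern
frequencies toward the international average; with few items the
likelihood is too weak to undo this, and a state common in one group but
rare overall can disappear from that group's classified table *even when
classification uses the true item parameters*. We observed exactly this
in the planted-trajectory experiments: the data-handling-first groups
lost their planted $(0,0,0,1)$ state under pooled classification.
`em_fit(by_group = TRUE)` therefore fits a multigroup structural model —
item parameters pooled across groups (one calibration, the measurement-
invariance assumption), one latent-class distribution per group, each
group's distribution serving as its members' classification prior. This
is the standard resolution in cross-group latent-class analysis. The
single-distribution fit remains the default because model *comparison*
tables are conventionally reported from one pooled fit.

## Learning trajectories

The $2^K$ attribute patterns ordered by inclusion form a Boolean lattice;
its Hasse diagram (`build_lattice()`, $K \cdot 2^{K-1}$ edges) encodes the
prerequisite relation "state $v$ adds exactly one attribute to state
$u$" — the assumption that students master one attribute at a time. Given
a group's pattern frequencies, `extract_trajectory()` walks the lattice
greedily from the null state: at each level it moves to the successor
with the highest observed frequency. The runner-up successor is retained
as a *secondary* branch when the chosen-to-runner-up frequency ratio is
at most 10 — a runner-up more than an order of magnitude rarer is treated
as noise. The boundary (ratio exactly 10) keeps the branch; retained
branches are extended greedily one level forward. Further rules, fixed
for determinism:

* ties in frequency are broken by the lowest added-attribute index;
* a level whose successors all have frequency 0 is resolved by the
  tie-break and flagged `unsupported` in the provenance;
* `restrict_top_k = 5` zeroes all frequencies outside the group's top
  five, reproducing analyses run from printed top-five tables;
* extraction is invariant to rescaling all frequencies by a constant.

The greedy per-level rule is the primary scorer because published
trajectory figures describe a main and a secondary state *per level*. A
global scorer (maximize the product of state frequencies over all $K!$
complete chains) is exposed via `scorer = "global"` for sensitivity
analysis; on frequency tables concentrated on a single chain the two
agree, which the test suite verifies exhaustively for all 24 attribute
orders at $K = 4$.

`compare_trajectories()` clusters groups by identical main chains and
tallies which attribute each group masters at each level.
`export_graph()` writes DOT (main chain solid red, secondary branches
dashed, remaining lattice edges gray) and a JSON serialization that
round-trips through `trajectory_from_json()`.

## The synthetic-data generator

`pisa_like_scenario()` emulates the structure of a 14-country PISA 2012
statistics-item study at desk scale: 14 groups of 500 respondents
answering the packaged 9-item, 4-attribute Q-matrix. Responses are drawn
from an LLM with null-pattern success 0.15 and full-mastery success 0.85
split into equal logit main effects — mid-sized guessing and slipping
noise typical of multiple-choice items. Each group's latent-class
distribution concentrates on the mastery chain
$(0,0,0,0) \to (1,0,0,0) \to (1,0,0,1) \to (1,0,1,1) \to (1,1,1,1)$ with
level masses $(0.40, 0.20, 0.14, 0.10, 0.09)$, the null-state mass tilted
deterministically between 0.30 and 0.50 across groups (the chain masses
renormalized accordingly) and the leftover 7% spread uniformly over the
eleven off-chain states; these magnitudes mirror published top-five
country tables, where the null state carries 23–65% and chain states a
few to twenty percent. Two groups (`BG`, `CR`) are planted with the
alternative first step $(0,0,0,1)$ — data handling before uncertainty —
to exercise the secondary-trajectory logic. One global seed expands into
fixed per-stage sub-seeds so individual stages can be regenerated
independently; the same seed reproduces the dataset byte for byte.

What the generator deliberately does **not** emulate: booklet rotation
and planned missingness, sampling weights, polytomous partial credit,
within-group clustering (schools), or Q-matrix misspecification.
Passing recovery tests on these data therefore show that the estimator
and the trajectory logic are correct under the stated model, not that
the model is adequate for any particular real assessment.

## Problem sizes and verification

The package's own experiments are sized for a desk machine: parameter
recovery uses 3,000 simulated respondents on the 9-item Q-matrix
(conjunctive-model item-parameter RMSE ≤ 0.05, class-proportion error
≤ 0.02 at that size), and the end-to-end trajectory experiment uses the
default 14 × 500 scenario, where the multigroup pipeline recovers all
planted main chains including both data-handling-first groups. Marginal
likelihoods are verified against a brute-force class-enumeration oracle
on small instances, EM ascent is checked on randomized instances, and
the published worked examples (parameter counts against printed
AIC-deviance gaps, the number-correct table's cumulative percents,
model selection, and the per-country trajectories implied by printed
top-five tables) are asserted exactly in the test suite.

## Known limitations

* Identity- and log-link additive M-steps rely on constrained numerical
  optimization; pathological posteriors can leave an update at its
  current value (the generalized-EM guard), slowing convergence.
* No standard errors of item parameters, and no absolute fit statistics —
  only relative comparison by information criteria.
* Q-matrices that alias latent classes (e.g. an attribute that never
  appears without co-requirements under a conjunctive model) leave some
  class proportions unidentified; the EM splits the aliased mass evenly
  rather than warning.
* The trajectory extractor is descriptive: it summarizes a cross-
  sectional frequency table and makes no longitudinal claim.
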