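---
title: "Bridging UPDRS and MDS-UPDRS with a multivariate graded response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging UPDRS and MDS-UPDRS with a multivariate graded response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmbridge)
```

## The problem

Clinical trials in Parkinson's disease have scored symptom severity with
the UPDRS instrument for decades; newer studies use its Movement Disorder
Society revision (MDS-UPDRS), whose items are similar but not identical in
construct and response wording. Analyses that sum items into a total score
cannot combine the two instruments, and discard item-level information.
`irmbridge` implements an item-response-theory bridge: item characteristic
curves (ICCs) developed on MDS-UPDRS data are reused for UPDRS items, with
a small number of new parameters absorbing the differences between the two
instruments, so that trials scored with either version can be analyzed on
one common latent-disability continuum.

## Model

Each of UPDRS items 1--31 (parts I--III) is scored 0--4; seven items are
rated for several body parts and/or sides, giving 44 evaluations per
assessment (`build_item_table()`). Evaluations load on one of three latent
disability variables: patient-reported items (PR, items 1--17), non-sided
clinician-rated items (NSR), and side-specific clinician-rated items (SR).
Tremor-at-rest and rigidity contribute their non-sided evaluations
(face/lips/chin, neck) to NSR and their sided evaluations to SR, each
evaluation exactly once.

Given a subject's latent disability $D$, responses follow the graded
response model
$$
P(Y_{ij} \ge k) = \frac{e^{a_j (D_i - b_{jk})}}{1 + e^{a_j (D_i - b_{jk})}},
\qquad
P(Y_{ij} = k) = P(Y_{ij} \ge k) - P(Y_{ij} \ge k+1),
$$
with discrimination $a_j > 0$ and ordered difficulties $b_{jk}$
(`category_probabilities()`).

**Bridging taxonomy.** Items map onto the MDS-UPDRS instrument in three
ways (24 indirect, 11 direct, 9 UPDRS-exclusive evaluations;
`mapping_summary()`):

* *direct* — the MDS ICC is reused unchanged;
* *indirect* — the MDS ICC is reused, then part of the probability mass is
  reassigned between adjacent categories to absorb the difference in
  category wording. Using leg agility as the template,
  $$
  P(Y=1) = P1 + P2 \cdot FR2,\quad
  P(Y=2) = P2(1 - FR2) + P3 \cdot FR3,\quad
  P(Y=3) = P3(1 - FR3),
  $$
  with $P0$ and $P4$ unchanged — a linear, mass-preserving map with two
  free fractions per item (`reassign_probabilities()`). Every indirect item
  uses this adjacent-split template, with its fractions shared across the
  item's left/right evaluations;
* *exclusive* — items absent from MDS-UPDRS (falling, freezing,
  tremor-at-rest, action tremor) carry their own ICCs, estimated from
  UPDRS data.

**Population structure.** Baseline latent disabilities are multivariate
normal with per-latent means and variances and a $3 \times 3$ correlation
matrix, separately per study population (early versus advanced disease).
A two-class mixture captures which body side is the more disabled at
baseline (probability $\pi$ that it is the right side). For SR
evaluations, an item either evaluates the subject's more disabled side
(the *same* combination) or the other side (*different*), which receives
the negative shift $S_1$ plus its own random effect. Advanced-population
means are shifted by $S_2$ (PR), $S_3$ (NSR), $S_4$/$S_5$ (SR,
same/different). Disability progresses linearly in time,
$$
D_i(t) = D_{i,0} + \mathrm{Shift} + \mathrm{Slope}_i \cdot t ,
$$
with time in weeks and subject-specific slopes (fixed effect plus normal
random effect per latent).

**Estimation.** The marginal likelihood integrates the product of category
probabilities over the subject's random effects (three correlated baseline
latents, the $S_1$ effect, slope effects when longitudinal data are
present) and sums over the two mixture classes. The integral is
approximated by a Laplace approximation at the per-subject posterior mode,
located by a damped Newton iteration with analytic first and second
derivatives; setting `nodes > 1` in `irm_control()` refines it by adaptive
Gauss--Hermite quadrature centered and scaled at that mode (`nodes = 1`
*is* the Laplace approximation). Constrained parameters are optimized on
transformed scales: $S_1 \le 0$ via a negated log, $S_2$--$S_5$ and all
variances via logs, $\pi$ and the fractions via logits, correlations via
atanh with a positive-definiteness barrier. Missing item responses
(`MDV = 1`) contribute nothing to the likelihood — no imputation, which is
one of the motivations for item-level modelling. Model comparison uses the
likelihood-ratio test on $-2\log L$ for nested fits and AIC otherwise
(`compare_models()`).

The staged workflow mirrors how such a bridge is built in practice:
stage 1 estimates what is new on the item side (reassignment fractions,
exclusive-item ICCs, baseline latent means/variances, $S_1$) with the
prior ICCs fixed; stage 2 estimates the population contrasts ($S_1$,
$S_2$--$S_5$, advanced variances, optionally the correlations); the
longitudinal stage estimates progression slopes. `irm_fit()` exposes the
presets and accepts any explicit `free` set.

## Default parameter values

The packaged defaults (`default_population()`) are the fitted population
values reported for the two source trials: baseline means
$(0.535, 0.219, 0.353)$ and variances $(0.774, 1.23, 0.821)$ for
(PR, NSR, SR) in early disease; $S_2 = 0.697$, $S_3 = 1.36$,
$S_4 = 0.322$, $S_5 = 1.15$; advanced variances $1.88$ (PR) and $2.63$
(NSR); $S_1 = -1.94$ with variance $0.105$; $\pi = 0.58$; and a placebo
progression slope of $-0.0094$ per week for SR under the same-side
combination (other slopes not distinguishable from zero). Where the source
fits do not report a value, the package fixes one default and documents it
here:

* advanced-population SR variance: set equal to the early value $0.821$
  (no advanced SR variance is reported; S4/S5 carry the mean contrast);
* latent correlations: reported only graphically as "mostly 0.7 or
  above", with PR--NSR and PR--SR slightly higher than NSR--SR and similar
  across studies; defaults are $r_{PR,NSR} = r_{PR,SR} = 0.75$,
  $r_{NSR,SR} = 0.70$ in both studies;
* slope random-effect variances: $10^{-4}$ per latent (SD $0.01$/week,
  i.e. between-subject slope variation of the same order as the mean
  slope);
* reassignment fractions: $FR2 = FR3 = 0.3$ for every indirect item — a
  moderate reassignment keeping most mass on the matching category — used
  as simulation truth and starting values.

## The synthetic item bank

The reference ICC values behind the bridge are not shipped with this
package, so `generate_fixture_bank()` draws a synthetic bank, clearly
labelled as such: discriminations uniform on $(1, 2.5)$, first thresholds
on $(-2, -0.5)$ with gaps on $(0.8, 1.6)$, spanning roughly $(-2, +4)$
latent units so items are informative across both severities studied.
Mirrored left/right evaluations of one item share parameters: the question
asked is the same on either side, side differences are carried by the
latent structure, and the likelihood is then exactly invariant under a
global left/right relabelling (with $\pi \mapsto 1 - \pi$) — a property
the test suite asserts. User banks in the documented tab-separated format
are accepted via `load_item_bank()`. Which items would receive an extra
severe-category threshold in a real re-estimation is unknowable from the
published material; `generate_fixture_bank(extra_severe = ...)` makes it a
configuration, not a guess.

## The synthetic trial generator

`simulate_trial()` runs the fitted model forward under the two emulated
designs (`make_presets()`): an early-PD study (N = 161, baseline only), an
advanced-PD study (N = 393 at baseline) and its placebo arm followed at
weeks 0, 1, 2, 3, 4, 6, 8, 10, 12, 16, 20 and 24. All sizes are
overridable for scaled-down work; per-subject seed streams make subjects
reproducible under resizing. The generator emulates the statistical
structure the analysis assumes — ordinal item responses driven by
correlated latents, side dominance, population shifts, linear progression
— and deliberately not features of real trials it has no information
about: no dropout pattern (a flat per-record missingness probability is
available, default 0), no titration or crossover structure, no
item-specific residual dependence, and item parameters from the synthetic
bank rather than a fitted instrument. Passing recovery tests therefore
demonstrates the estimation machinery, not the field validity of any
particular parameter value.

## Numerical choices

* Inner Newton iterations stop when the largest step falls below $10^{-7}$
  (cap 50), with step halving against objective decrease and an escalating
  ridge if a curvature matrix loses positive definiteness.
* The outer optimizer is `nlminb` on the transformed scale with relative
  tolerance $10^{-6}$; finite-difference gradients.
* Standard errors come from the numeric Hessian of the marginal
  log-likelihood at the optimum, delta-method transformed to the natural
  scale.
* Pure Laplace is accurate to a few $10^{-3}$ log-likelihood units per
  subject with full 44-item records but degrades on sparse toy records
  (measured up to $\sim 5 \times 10^{-2}$ with five items); the quadrature
  mode agrees with dense-grid integration oracles to $\sim 10^{-6}$ and is
  the reference when precision matters. Tensor-product grids limit it to
  few effective dimensions.
* Category probabilities are floored at $10^{-300}$ before logging;
  reassignment fractions are validated into $[0,1]$; degenerate
  (near-zero) latent variances reduce the marginal likelihood to the
  plug-in probability, which the tests exercise.
* Simulation bands in the diagnostics use inverse-ECDF (type 1)
  percentiles, so at 2 replicates the band is exactly the min/max, and at
  200 replicates the realized band level runs slightly below the nominal
  95%.

## Diagnostics

`item_mean_check()` compares each evaluation's observed mean score with
the 2.5th--97.5th percentile band of per-replicate means across
simulations of the fitted model on the observed record layout (200
replicates by default, stratified by population). `residual_correlation()`
correlates per-record residuals (observed minus expected score at the
empirical-Bayes latent mode) across evaluations; under a well-specified
model the off-diagonals are near zero, and constant residuals yield `NA`
rather than a spurious zero. `vpc_check()` sums scores into the three
latent subscores (PR 0--68, NSR 0--36, SR 0--72) and the total, and
compares observed medians and outer percentiles per visit week with 95%
prediction intervals from 500 replicate datasets. All three are pure
functions of (data, parameters, seed).

A practical caveat found while calibrating the suite: within one stratum
all per-item means share the same subject draw, and with latent
correlations around 0.7 a single unusual cohort shifts most items at once.
Item-band coverage is therefore assessed across repeated experiments in
the tests, and a single experiment's covered count should be read with
that clustering in mind.

## Design choices on open points

* The same/different side classification uses the mixture class as the
  more disabled side at baseline; the different-side combination carries
  $S_1$ (with random effect) in both studies, and $S_4$ versus $S_5$
  separates the two combinations in the advanced population.
* Only the same-side SR slope is reported as distinguishable from zero in
  the source analysis, so the different-side SR slope defaults to 0 but is
  a free, estimable parameter (`slope_SR_diff`).
* Correlation between baseline and slope random effects is not
  implemented (block-diagonal random effects); the source analysis treated
  it as an optional exploration contingent on stability.
* Stage 2 frees $S_1$ together with $S_2$--$S_5$ and the advanced
  variances; latent correlations join via
  `irm_control(include_correlations = TRUE)`. This grouping matches the
  recovery experiments the package ships.
* One reassignment scheme per item, shared across its evaluations; the
  published material prints the explicit scheme only for leg agility, and
  the adjacent-split template with per-item fractions covers all indirect
  items.

## Problem sizes used by the shipped experiments

The packaged recovery experiments run at deliberately reduced sizes chosen
to keep a desktop run comfortable while leaving the estimators
well-conditioned: a two-population baseline trial of 150 + 150 subjects
for the $S_1$ and mixture-proportion recoveries, and a 200-subject
placebo arm with the full 12-visit schedule for the slope recovery.
Diagnostic self-consistency uses 200 item-check replicates (10
experiments pooled) and one 100-subject VPC at 500 replicates.

## Limitations

* The synthetic bank stands in for the real instrument; nothing here
  reproduces the numeric ICCs of the original cohort model.
* Drug-effect terms are out of scope (placebo/baseline only), as are
  total-score conversion formulae between the instruments.
* Laplace bias, though small at 44 items per assessment, is not zero;
  quadrature refinement is exact only in low dimension.
* Full stage-1 estimation (48 fractions plus 45 exclusive-item ICC
  parameters) is supported by the machinery but slow with
  finite-difference gradients; the shipped tests exercise it on focused
  subsets.
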