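---
title: "Modelling preferred noise-reduction strength from paired comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preferred noise-reduction strength from paired comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefnr)
library(dplyr)
```

## The problem

Single-channel noise reduction (NR) in hearing aids attenuates estimated
background noise at the price of audible speech distortion. How strongly it
should do so — here parameterised by the maximum gain reduction, `Gmin`, in
dB — differs between listeners, and clinics have no prescription rule for
it. The pipeline in this package analyses two-alternative forced-choice
listening data designed to answer three questions: does hearing loss shift
the preferred NR strength, how many distinct NR settings would cover a
population of listeners, and how few paired comparisons suffice to place a
new listener on the right setting.

The experimental unit is a *trial*: two successively presented
speech-in-noise stimuli processed at strengths `g_first` and `g_second`,
and the listener's forced choice. The full design crosses ten strengths
(0, 4, 6, 7, 8, 9, 10, 12, 16, 18 dB) in both presentation orders with two
repetitions: `10 * 9 * 2 = 180` trials per listener.

## The quadratic-utility logistic (QUL) model

Each listener is assumed to trade residual noise against processing
distortion according to a quadratic utility of strength,

$$u(g) = a\,g + b\,g^2,$$

and to choose the first stimulus with probability

$$P(\text{first}) = \operatorname{logit}^{-1}\!\big(u(g_\text{first}) - u(g_\text{second})\big).$$

Design choices worth making explicit:

* **No intercept.** Any constant added to `u` cancels in the difference, so
  an intercept is structurally unidentifiable and is omitted. An optional
  presentation-order bias term can be switched on (`order_effect = TRUE`),
  but the balanced AB/BA design cancels order effects by construction, so
  it is off by default.
* **No lapse rate, no ties.** The task forces a choice; the minimal
  two-parameter model is used.
* **Preferred strength.** With concave utility (`b < 0`) the preference
  peaks at `-a/(2b)`; this estimate is clipped to the tested range
  (default 0–18 dB) so it never extrapolates beyond stimuli the listener
  actually heard. With `b >= 0` the utility is maximal at an endpoint; if
  both endpoints tie exactly there is no preference information and the
  midpoint is returned with a `degenerate` flag — a deterministic answer to
  a degenerate input.

Because the utility difference is linear in `(a, b)` with covariates
`(Δg, Δg²)`, maximum likelihood is an intercept-free binomial logistic
regression, computed by iteratively reweighted least squares with the
coefficient covariance taken from the inverse observed information. The
test suite verifies the optimum against an exhaustive likelihood grid
search (step 0.005 in both coordinates).

**Separation.** A listener who always prefers the stronger (or weaker)
stimulus is predicted perfectly by any sufficiently steep utility, so the
likelihood has no finite maximiser. `fit_qul()` detects this — every
observed choice assigned fitted probability within `1e-6` of 1 — flags the
fit `separated`, reports the favoured endpoint as the preferred strength
and marks the covariance unreliable rather than failing.

**Pointwise uncertainty.** The model-side analogue of the empirical win
fraction at level `g` is the mean choice probability of `g` over all other
design levels; its standard error comes from the delta method. Note the
SEs legitimately differ across levels even for a flat fit, because levels
near the edge of the grid have higher leverage; only a grid symmetric about
its midpoint yields mirror-equal SEs.

## Response-feature group analysis

Rather than modelling all 180 correlated responses per listener jointly,
each listener is reduced to one feature — the preferred strength — and the
features are compared across hearing-status groups (response-feature
analysis; it trades some power for interpretability). The sequence
implemented by `group_stats_report()` is: Bartlett's variance-equality
check, a Kolmogorov–Smirnov normality check of group-centred residuals,
Kruskal–Wallis across groups, Dunn's z-tests on pooled mean ranks with
Bonferroni correction (`m = 3`), and Spearman correlations of the preferred
strength with better-ear PTA, SRT and age.

Two methodological notes:

* The KS test is run with mean and SD estimated from the sample, which is
  how it is commonly (if loosely) applied; this makes the p-value
  anti-conservative. A `lilliefors = TRUE` option applies the proper
  correction for estimated parameters.
* The Kruskal–Wallis post hoc is not uniquely defined by "mean ranks,
  Bonferroni corrected"; Dunn's z-test on the pooled ranking with
  ties-corrected variance is the standard choice and is what is
  implemented, with the exact z and adjusted p verified by hand in the
  tests.
* The design-stage sample size uses the two-sample normal approximation
  `n = 2σ²(z₁₋α/₂ + z_power)²/Δ²` rounded to the nearest integer; with
  σ = 1.8 dB and Δ = 2.5 dB this gives 8 per group. A stricter
  noncentral-t version (`method = "exact-t"`) is available and never
  returns less.

## Clustering win-count profiles

A listener's *win profile* is, per strength level, the fraction of trials
containing that level in which it was chosen. Profiles are clustered with
Ward's minimum-variance agglomeration on Manhattan (L1) distances — Ward
because roughly equal-sized groups are wanted, L1 because it is robust to
outlying profiles. Numerical specifics:

* Distances are computed on win *fractions*, not raw counts. On the
  complete design every level appears 36 times, so counts and fractions
  differ by a constant factor and the tree is identical; fractions remain
  comparable when designs are reduced.
* The Lance–Williams recurrence with Ward coefficients is applied to the
  dissimilarities *as given* (the `"ward.D"` convention), not squared; the
  squared variant (`"ward.D2"`) is available but non-default. The
  agglomerator is verified against a naive O(n³) reference on random
  matrices up to n = 6, including the hand-checked three-point case whose
  second merge height is 19/3.
* Levels with no appearances in a partial profile are `NA`, never 0 —
  imputing 0 would fabricate strong dispreference — and distance
  computation refuses profiles containing them.
* A clustering into k groups is *stable* if it persists over a long span of
  merge heights. `stable_solutions()` formalises the visual "long
  horizontal range on the dendrogram" criterion as
  `lifetime(k) = h(k→k−1) − h(k+1→k)`, with the root height bounding the
  k = 2 solution. This formalisation is this package's; any monotone
  transform of heights would reorder lifetimes differently, so lifetimes
  are reported alongside the heights they span.
* Equal minimal dissimilarities are merged lowest-index first (inherited
  from the agglomerator); on continuous data ties have probability zero.

## The comparison-budget simulation

To ask how few comparisons classify a listener into the right preference
cluster, a reduced design keeps only levels 0, 7, 8, 9, 10, 18 dB: each
extreme against each mid level in both orders (8 + 8 ordered pairs) plus
the extreme-vs-extreme pair doubled (2 × 2) — 20 weighted pairs, 40
comparisons with two repetitions. Doubling up-weights the only comparison
separating the no-NR from the strong-NR cluster; the doubled entries reuse
the listener's recorded response, they do not re-ask.

`subsample_classify()` then simulates a shortened test: draw n of the 40
comparisons uniformly *without replacement*, form win fractions over the
levels appearing in the draw, and assign the draw to the nearest cluster
centroid in Euclidean distance. Choices that had to be made where the
procedure is underdetermined:

* Centroids from the full-design clustering are restricted to the six
  reduced levels before any distance is computed (the draw cannot inform
  other levels).
* Levels absent from a draw are *excluded* from the distance, not imputed
  as 0, for the same reason as above.
* Exact distance ties split the assignment equally between the tied
  clusters, so reported probabilities still sum to one.
* One seed governs a whole budget curve; identical inputs and seed give
  bit-identical output (R's default Mersenne–Twister generator via a
  locally scoped seed).
* Adaptive comparison selection — stopping early once an answer is clear —
  would only improve on this average-case analysis and is deliberately not
  implemented.

Where enumeration is feasible (e.g. all 40 leave-one-out subsets at budget
39), an exact mode replaces Monte-Carlo and the tests require the two to
agree within three binomial standard errors.

## The synthetic cohort generator

No individual-level data ship with this package, so `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes: three
hearing-status groups of 10, preferred strengths drawn from truncated
normals on [0, 18] dB with group medians 8.2, 11.6 and 15.7 dB, curvature
`b` uniform on [−0.06, −0.01] (spanning the flat to sharply peaked
empirical profiles), `a = −2b·g_opt` so the utility peaks exactly at the
drawn optimum, and every trial answered by a Bernoulli draw at the QUL
probability. Covariates follow the group definitions (NH better-ear PTA
≤ 20 dB HL, HI-mild ≤ 40, HI-moderate > 40) with age and SRT affine in PTA
plus noise, calibrated so the usual moderate positive correlations emerge;
five NH listeners lack an SRT, mirroring the study's missing measurements.
The within-group spread of the preferred strength defaults to 3.8 dB,
between the 3.6 and 4.0 dB spreads reported for comparable experiments —
the true within-group spread is not identifiable from published summaries,
and this is the one generator parameter that is a genuine modelling choice.

`archetypes()` plants the idealised three-cluster structure (6 no-NR, 9
intermediate, 15 strong-NR listeners) with near-deterministic responders
kept inside the QUL family: steep linear utilities for the boundary
preferrers and a sharply concave utility peaking at 10 dB for the middle
group. Its `noise` argument is the per-trial probability that a choice is
flipped; 0 gives fully deterministic cohorts for exact recovery tests.

Every participant draws from a dedicated RNG substream derived from the
master seed, so cohorts are reproducible and an individual's data are
stable when other group sizes change.

**What passing tests do and do not show.** The generator emulates the
study *design* — not real listeners. Real paired-comparison data contain
intransitivities, drifting criteria, lapses and order effects that the
Bernoulli-QUL generator does not produce; recovery results here bound what
the pipeline can do when its own model is true, and say nothing about model
misfit. That is exactly the role the synthetic cohort is meant to play.

## Problem sizes

The shipped tests and the acceptance script use: 200 synthetic listeners
(180 trials each) for parameter recovery; 50 seeded archetype cohorts at
flip probability 0.1 for planted-cluster recovery; 500 resampling
replicates per budget point (the study's own replicate count); exhaustive
reference computations up to n = 6 matrices and 40 leave-one-out subsets.
These sizes give Monte-Carlo standard errors comfortably below the margins
being asserted while keeping a full run in the order of a minute.

## Known limitations

* The QUL parameterisation here is the minimal one consistent with
  "quadratic utility + logistic choice"; published variants may carry
  nuisance parameters (lapse rates, scale factors) that would change
  uncertainty estimates but not the location of the preference peak.
* Delta-method standard errors understate uncertainty for near-separated
  fits; such fits are flagged rather than corrected.
* Lifetime-ranked stability is a heuristic; it has no inferential
  calibration and should be read alongside the dendrogram.
* The budget simulation scores an average-case random protocol; a clinical
  implementation would use adaptive selection and should do strictly
  better.
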