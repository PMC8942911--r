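---
title: "Measurement models for confidence-rating recognition data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models for confidence-rating recognition data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptsdt)
```

## The problem

In recognition-memory experiments on false memory, participants study lists
of items (here: concrete words in coloured fonts, or door-scene
photographs) under one of two orienting tasks — naming the item's colour or
naming its semantic category — and are then tested on old items (targets)
mixed with three kinds of unstudied lures: *category lures* (right
category, wrong colour), *colour lures* (right colour, wrong category) and
*critical lures* (both features match).  Each test item is judged on a
4-point confidence scale from 1 (definitely new) to 4 (definitely old).
The scientific question is whether "recall-to-reject" retrieval monitoring
— rejecting a lure because a recollected study feature disqualifies it —
depends on the interaction of encoding orientation, material, and the
feature in which a lure mismatches.

Because per-participant trial counts are small (9 trials per lure type),
the measurement models are fitted to counts pooled over the participants of
a condition.  The package implements both halves of the standard
dual-modelling strategy:

* a **discrete-state** account, the two-high-threshold model (2HTM), a
  multinomial processing tree (MPT) over the four rating categories; and
* a **continuous** account, unequal-variance signal-detection theory
  (UVSDT) on the rating receiver-operating characteristic.

## Reconstructing pooled counts from published proportion tables

Published summary tables usually give participant-mean rating proportions
to three or four decimals.  When every participant contributes the same
number of trials per item class — true of both bundled designs — the
participant mean equals the pooled proportion, so pooled integer counts are
exactly `p * N * t` up to rounding (N participants, t trials each).
`reconstruct_counts()` rounds by largest-remainder apportionment, which
guarantees the cell counts sum exactly to the design total; ties in the
fractional remainders go to the lower rating.  A rounded cell that moves
more than one count away from `p * total` signals proportions inconsistent
with the declared design and raises an error rather than guessing.  For the
bundled tables every reconstructed cell is within 0.5 of `p * total`, i.e.
the printed four-decimal proportions are exactly consistent with integer
counts.  Counterbalancing of stimulus assignment affects which items served
as targets, not the per-class totals, so it is irrelevant to pooled counts.

## The 2HTM for ratings

Each item class has its own processing tree.  A target is detected as old
with probability $D_o$ and then rated 4 with probability $s$ (else 3).  A
lure of type $k$ is detected as new with probability $D_{n,k}$ and rated 1
with probability $n_k$ (else 2); $D_{n,k}$ and $n_k$ are lure-type
specific, which is what lets detection be compared across lure types — the
recall-to-reject signature.  Undetected items of any class enter a common
guessing state: guess old with probability $g$, then rate 4 with
probability $a_o$ (else 3); guess new with $1-g$, rating 1 with
probability $a_n$ (else 2).

For one experiment the two encoding conditions are fitted jointly with
condition-specific detection and confidence parameters and the guessing
parameters $g, a_o, a_n$ shared across conditions — guessing reflects the
test situation, not the study task.  That sharing is the one structural
choice the degrees of freedom pin down: 2 conditions × 4 trees × 3 free
categories = 24 cells, 19 free parameters, 5 df, matching the reported
fits; the exact reproduction of every published $G^2$ and $\Delta G^2$
from the reconstructed counts confirms the structure.  `share_guessing =
FALSE` is available for sensitivity analyses.  The combined cross-material
model simply concatenates the per-experiment models with no sharing
(38 parameters, 10 df).

Fitting maximizes the product-multinomial likelihood with `optim` (BFGS) on
logit-transformed parameters, so all probabilities stay in (0, 1) by
construction.  Twenty starts are used by default — one central start (all
parameters 0.5) plus seeded random interior points — and the best solution
is polished with `nlminb`; among likelihood ties the lexicographically
smallest estimate vector is kept, making refits exactly reproducible.
Goodness of fit is $G^2 = 2\sum o \ln(o/e)$ with $0\ln 0 = 0$; expected
cells are floored at $10^{-12}$ only against zero-probability/positive-count
degeneracies.  Nested hypotheses (equality of a parameter across
conditions or lure types) are tested by $\Delta G^2$ with the difference in
parameter counts as df.

### The guessing ridge: a caveat on raw parameter estimates

The rating 2HTM with fully shared guessing is *not* locally identified,
although the degrees-of-freedom arithmetic suggests it is.
`check_identifiability()` reports a Jacobian rank of 18, one short of the
19 free parameters, and the deficiency is an exactly flat one-dimensional
ridge: for any admissible shift of the guessing rate $g$, the remaining
parameters can be moved so that every category probability is unchanged —
$(1-D_o)(1-g)$, $(1-D_{n,k})\,g$, $a_o$, $a_n$ and the extreme-rating cell
masses are the identified quantities, and $D_o$, $s$, $D_{n,k}$, $n_k$
individually are not.  The ridge is bounded, because all derived
parameters must stay in (0, 1), which is why reported estimates are
typically stable in practice (parameters near a boundary pin it down), but
users should treat raw parameter values — including bootstrap spreads — as
ridge-conditional.  None of the goodness-of-fit or likelihood-ratio
statistics are affected: the ridge moves along the model manifold, not off
it, so $G^2$ and every $\Delta G^2$ are well defined.  Equating $D_o$ or
$D_{n,k}$ across conditions, or $D_{n,k}$ across lure types, constrains
the identified combinations one-for-one, so those tests keep their 1-df
chi-squared calibration (verified by simulation, below).  Where the
package's tests need recoverable parameters they either assert the
identified combinations or fix $g$, which removes the ridge
(`mpt_constraints(fixed = c(g = ...))` gives a rank-18, fully identified
submodel).  The reported df follow the conventional
cells − trees − parameters bookkeeping used by the field's software; under
the rank-deficient structure the effective model dimension is one smaller,
so nominal goodness-of-fit p-values are slightly conservative.

### Interactions as ratio invariance

Across materials, an interaction is tested on the ratio scale: in the
combined model, the colour-condition value of a parameter is
reparametrized as $\lambda_e$ times its category-condition value,
separately per experiment $e$.  With $\lambda_1, \lambda_2$ free this is a
likelihood-preserving reparametrization (the package refits it and checks
it reaches the combined likelihood); constraining $\lambda_1 = \lambda_2$
gives the 1-df interaction test.  $\lambda$ is optimized on the log scale,
unbounded above, and only the product $\lambda \cdot \text{base}$ is
constrained to (0, 1).

## The UVSDT model

New-item strength is N(0, 1), old-item strength N($\mu$, $\sigma^2$), and
three ordered criteria cut the axis into the four ratings.  Sensitivity is
$d_a = \mu\sqrt{2/(1+\sigma^2)}$ and bias is the middle criterion
$x_c = c_2$ — the boundary between "new" and "old" responses — on the
new-distribution axis, the convention that matches the published values.
Optimization is unconstrained (free $\mu$, $\log\sigma$, $c_1$ and log
increments for $c_2, c_3$) from a deterministic 3 × 2 grid of
($\mu_0$, $\sigma_0$) starts with criteria started at the new-class
empirical quantiles.  Standard errors use the observed information
(numerical Hessian at the MLE in natural parameters) with the delta method
for $d_a$; the published standard errors are reproduced to the fourth
decimal, which settles the observed- versus expected-information question
in favour of observed.  Condition contrasts use the two-sample Wald
$z = (\hat\theta_1-\hat\theta_2)/\sqrt{SE_1^2+SE_2^2}$.

## The synthetic-data generator

`simulate_2htm()` traverses the processing tree literally — every split is
an independent Bernoulli draw per trial — and `simulate_uvsdt()` draws
strengths and bins them by the criteria; both pool trials into the same
counts format the fitters consume.  Participants are homogeneous by
default, matching the pooled-fitting assumption; a beta-distributed
heterogeneity knob (`heterogeneity = kappa`) exists but is off by default,
and data generated with it will overdisperse relative to what pooled
fitting assumes — useful precisely for studying that robustness.
Replicate $r$ of a spec draws its seed from the base seed by a fixed
counter scheme, so single replicates are reproducible in isolation.

The presets in `scenario_spec()` fix the study conditions for calibration
runs at the bundled designs: `"null"` shares every parameter across
conditions ($D_o = 0.65$, $s = 0.85$, $D_n = 0.45/0.45/0.25$ for
category/colour/critical lures, $n = 0.8$, $g = 0.4$, $a_o = a_n = 0.6$ —
mid-range values of the kind rating 2HTM fits typically produce, with
critical-lure detection lowest as observed empirically); `"word_like"`
raises colour-lure detection under category encoding (0.75 vs 0.35);
`"picture_like"` mirrors it for category lures under colour encoding at
the picture-experiment design.

What passing simulation tests do show: the fitting machinery is calibrated
(type-I error of the 1-df condition tests ≈ 0.05 under the null preset),
powerful under the preset effect sizes, and unbiased for identified
quantities.  What they do not show: robustness to participant
heterogeneity, to unequal trial counts, or to response styles outside the
model family — pooled real data carry all three risks.

## Numerical and design choices

* Boundary estimates (within $10^{-4}$ of 0 or 1) are flagged in
  `mpt_fit$boundary`; bootstrap percentile intervals near a boundary are
  asymmetric and truncated, as they should be.
* The parametric bootstrap (default B = 1000) resamples per-tree
  multinomials at the fitted probabilities and refits warm-started from
  the original solution plus random restarts; failed refits are counted
  and more than 5% triggers a warning.
* `delta_g2()` warns when the "constrained" fit beats the general one by
  more than 0.01 — an optimizer failure signal — instead of silently
  clipping.
* Problem sizes used by the package's own test suite were chosen to make
  Monte-Carlo noise small relative to the asserted tolerances: 200
  replicates for type-I calibration, 40 for bias checks, 30 for power,
  200 bootstrap resamples for the scaling law, and single large samples
  (600 participants per condition, or 2 × 10^5 trials per class) for
  consistency checks.

## Known limitations

* Pooled fitting only; hierarchical or per-participant estimation is out
  of scope.
* The guessing ridge means raw 2HTM parameter values are
  convention-dependent; compare identified combinations, or fix $g$, when
  parameter values themselves matter.
* The count reconstruction inherits the printing precision of the source
  proportions; all bundled comparisons carry tolerances (0.3 on $G^2$, 0.5
  on $\Delta G^2$) that cover this rounding, and the one comparison that
  uses most of its band (the ratio-interaction $\Delta G^2$, 13.37
  recomputed vs 13.12 published) is exactly the statistic most sensitive
  to it.

## Reproducing the published analysis

```{r, eval = FALSE}
report <- reproduce_study(seed = 1)
report
```

The report recomputes all twelve bundled comparisons (three goodness-of-fit
$G^2$, four $\Delta G^2$ tests, $d_a$, $x_c$, the Wald $z$, and two
descriptives) and marks each against its tolerance.
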