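---
title: "Measuring gross motor development in GM units: methods and design"
author: "gmunits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gross motor development in GM units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmunits)
```

## The measurement problem

Instruments for child gross motor development are numerous and mutually
incomparable: built with classical test theory, their total scores are
ordinal and sample-dependent, so a score on one instrument cannot be
expressed in units of another. `gmunits` implements the theory-driven
alternative used to build the Lexile scale for reading: regress an
interval-scaled difficulty hierarchy on task characteristics derived from
developmental theory (a *specification equation*), then fix origin and unit
size by *anchoring* the equation to two reproducible reference tasks. The
result is a universal interval unit — the Gross Motor (GM) unit — whose
meaning comes from theory and fixed anchors rather than from any particular
calibration sample.

## The component rating schema

Every gross motor task receives three ordinal ratings, each grounded in a
strand of developmental theory:

| component | range | low end | high end | rationale |
|---|---|---|---|---|
| body position | 1–12 | supine | airborne | difficulty grows as the head and center of mass rise and the base of support shrinks |
| movement | 1–22 | no movement | hopping on one foot | ordered by established motor milestones |
| support | 1–5 | full proximal + head support | no support | external support makes tasks easier |

Validation is strict: an out-of-range or non-integer rating is rejected,
never clamped, because the ranges define the construct's full extent and a
clamped value would silently corrupt a measure. Ratings are stored as plain
integers; label text is metadata. Item names are free text and never used as
keys (the bundled tables spell a few names differently between fixtures).

## The specification equation

Task difficulty is modeled linearly in the three ratings. The published
instance is

$$D = 6.76 + 1.23\,\mathrm{BP} + 1.21\,\mathrm{MV} + 4.93\,\mathrm{SP},$$

carried at the printed two-decimal precision: only these coefficients, with
predictions rounded to two decimals, reproduce the bundled reference table
bit-exactly, so the rounded values — not higher-precision refits — are the
canonical equation.

`forward_stepwise_fit()` re-derives such equations from an observed
difficulty vector. The procedure is pure forward stepwise OLS: at each step
the candidate with the largest adjusted-$R^2$ gain is entered if its
partial-F p-value is below the entry criterion (default $\alpha = 0.05$,
t/F inference with $n-k-1$ degrees of freedom); there is no removal step.
Zero-order Pearson correlations are screened first and variance inflation
factors ($\mathrm{VIF}_j = 1/(1-R^2_j)$, flagged at the conventional
$\ge 10$) are computed on the full candidate set. Collinearity handling is
deliberately non-destructive by default — flags are reported, and a
predictor is dropped only when `drop_collinear = TRUE`, in which case the
flagged predictor with the weaker zero-order correlation goes. An automatic
default removal would bake a judgment call into the code that properly
belongs to the analyst.

Because the ratings are ordinal codes entered as numbers, coefficient
estimates cannot be read on an interval scale; every report carries this
caveat. Degenerate inputs are handled explicitly: a constant difficulty
vector yields an intercept-only model with a warning (and no derivable
anchors), and an exactly collinear predictor reports an infinite VIF.

## Anchoring and the GM unit

With $D_\ell = 14.13$ (supine, brings hands to midline) and $D_h = 61.88$
(walking, hands free), the anchored transform is

$$\mathrm{GM} = (D - 14.13) \times 2.09,$$

assigning 0 GM units to the low anchor, 100 to the high anchor, and a unit
size of 1/100 of the anchor distance. Three rounding conventions are
load-bearing and fixed by exhaustive agreement with the bundled reference
table:

1. predicted difficulties are rounded to 2 decimals before the transform;
2. the anchor constants themselves are rounded to 2 decimals
   (offset $-14.13$, scale $2.09$ rather than $100/47.75 \approx 2.0942$);
3. integer GM units are the nearest integer, ties away from zero
   (`base::round()`'s half-to-even is the wrong convention here).

The source material never states these conventions; they are inferred — the
2-dp scale is the only choice under which all 66 printed GM integers
reproduce (items 35, 62 and 68 discriminate: they print 84, 84 and 89, but
the unrounded scale gives 85, 85 and 90). An `"exact"` mode keeps the
unrounded constants for theoretical work; measured against the 2-dp table it
shifts six non-anchor items (35, 62, 68, 78, 79, 86) by one GM unit and
never moves an anchor. Rounded constants also break exact invertibility at
the high anchor: `from_gm(100)` returns $100/2.09 + 14.13 = 61.97$, not
61.88 — a documented asymmetry, not a bug.

The map is affine, so it preserves order and intervals, and the scale
extends beyond both anchors (hopping: 123 GM units). `person_measure_to_gm()`
applies the identical map to person abilities on the difficulty metric; the
source framework defines the transform only for tasks, so person measures
are flagged as an extension.

## The partial credit model layer

The observed difficulty hierarchy that the regression consumes comes, in the
original derivation, from an external Rasch calibration of the 66-item
instrument on 537 children with cerebral palsy. That dataset is not public,
so the package makes the pipeline exercisable with a synthetic stand-in at
two levels of realism.

**Difficulty vectors.** `generate_difficulty_dataset()` returns
specification-equation predictions plus i.i.d. Gaussian noise. The default
noise SD is 6.09 — the residual scale (RMSE) of the reference fit — so the
default conditions mimic that fit's error structure. With this generator the
mean adjusted $R^2$ across refits lands near 0.87 and the mean
predicted-vs-observed $r$ near 0.93, matching the reference statistics in
expectation (the acceptance script recomputes both over 200 seeds).

**Response matrices.** `simulate_responses()` draws ordinal scores from the
partial credit model, the polytomous Rasch model named in the source
methodology: category $k$ of an item with steps $d_j = \delta + \tau_j$ has
probability $\propto \exp\sum_{j\le k}(\theta - d_j)$. Items default to 4
categories because the emulated instrument is scored 0–3. Thresholds are
centered (sum zero), separating overall difficulty $\delta$ from the step
structure.

`calibrate_pcm()` estimates $\delta$ and $\tau$ by joint maximum likelihood:
alternating Newton–Raphson updates of person and item parameters
(damped steps, parameters clamped to $\pm 15$ logits), convergence when the
largest post-clamp parameter change falls below `tol = 1e-6` within 200
outer iterations, and item difficulties centered to mean zero for
identification. JMLE was chosen over conditional/marginal estimators because
it is simple, dependency-free and adequate at this scale; its known
statistical bias — overstating the spread of item locations by roughly
$K/(K-1)$ for $K$ items, a factor of two in a two-item design — is removed
by the standard $(K-1)/K$ correction, applied by default. Missing responses
are ignorably missing (skipped in likelihood sums). Degenerate inputs are
surfaced, not patched: items observed in a single category are flagged
inestimable and excluded with a warning, and persons with all-minimum or
all-maximum patterns (no finite ability MLE) are excluded from estimation
and reported at $\mp\infty$. `estimate_person_ability()` likewise returns a
flagged boundary result for extreme patterns rather than a number dressed up
as an MLE.

The calibrated logit metric is arbitrary up to affine transform;
`rescale_logits()` maps it onto a conventional range (default 0–100).
Anchoring makes this choice immaterial: any interval metric for observed
difficulty yields the same GM units after the anchors are imposed.

## What the synthetic checks do and do not show

Simulation parameters are fixed at what the emulated study design implies:
66 items, 500 simulated respondents (near the external calibration's 537),
standard-normal abilities, 4 response categories, difficulty noise SD 6.09.
Under these conditions the test suite verifies, among others:

- exact reproduction of all 66 reference (difficulty, GM) pairs;
- exact recovery of any generating equation from noiseless difficulties
  (OLS identifiability), and agreement of the stepwise end point with a
  normal-equations solve to 1e-8;
- PCM probability normalization over random parameters, and calibration
  recovery with mean absolute error well under 0.2 logits at 66 items ×
  500 persons over 20 seeds;
- end-to-end duality: simulating response data whose item difficulties are
  an affine image of the equation's predictions, calibrating, rescaling and
  refitting recovers positively correlated coefficients.

These are checks of *internal consistency*: they show the pipeline inverts
its own generative model. Real calibration data differ in ways the generator
deliberately omits — ability distributions specific to clinical populations,
item misfit and multidimensionality, dependence between items, missingness
that is not ignorable, and residuals that need not be Gaussian or
homoscedastic. Passing these tests therefore validates the machinery, not
the developmental theory; the theory is tested by confronting the
specification equation with independently calibrated difficulty hierarchies.

## Numerical choices and limitations

- Problem sizes throughout (200-seed Monte Carlo means, 20-seed recovery
  studies, 500-person simulations) were chosen as the smallest designs that
  make the Monte-Carlo error negligible relative to the tolerances checked.
- Seeds are explicit arguments everywhere randomness enters; the global RNG
  state is never touched (`withr::with_seed`), so identical configs give
  byte-identical outputs.
- The stepwise entry rule (largest adjusted-$R^2$ gain, partial-F
  admission, no removal) is one reasonable reading of "forward stepwise";
  other software orders entry by p-value or uses different thresholds and
  may enter predictors in a different sequence on noisy data, though the
  full-model end point is identical whenever all predictors are admitted.
- JMLE with clamping can leave a step parameter at the boundary when a
  category is (almost) unobserved for an item; the item's difficulty is then
  only weakly determined. The calibrator reports convergence and standard
  errors so such items are visible.
- Fit statistics beyond the basics (infit/outfit, DIF, alternative
  estimators) are out of scope, as are clinical interpretation bands and
  equating other instruments onto the GM scale.
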