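---
title: "Methods: discriminant-driven pain scoring for post-surgical mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant-driven pain scoring for post-surgical mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painscore)
```

## The model and its assumptions

`painscore` analyses one observation session per animal, summarised as an
ethogram: a vector of behaviour frequencies (counts) and, where scored,
durations (seconds). The statistical engine is canonical discriminant
analysis: with between-group scatter $B$ and pooled within-group scatter
$W$, the canonical functions are the eigenvectors of $W^{+}B$, each
eigenvalue $\lambda_f$ measuring the ratio of between- to within-group
variation along its axis. Per-animal scores are centred on the grand mean
and scaled to unit pooled within-group variance, the convention of the
classic statistical packages, so scores from different fits are
comparable.

The analysis assumes (i) a fixed factorial design — strain (C57/C3H) x
surgery (A/V) x drug (Sa/BupL/BupH), six treatment groups, equal cell
sizes up to listwise exclusions; (ii) that group separation is linear in
the behaviour frequencies; and (iii) for the Wilks significance tests,
approximate multivariate normality within groups. Behaviour counts are
overdispersed and skewed, so the Bartlett chi-square p-values are
approximations; the package therefore verifies their operating
characteristics empirically (see the test suite's null-cohort
calibration) rather than treating them as exact.

Sequential ("peel-off") significance follows
$\Lambda_f = \prod_{j \ge f} 1/(1+\lambda_j)$, tested by
$\chi^2 = -(n - 1 - (p+k)/2)\log\Lambda_f$ on $(p-f+1)(k-f)$ degrees of
freedom. The identity between $\Lambda$ and the eigenvalues is exact and
unit-tested; the chi-square approximation is the standard one for this
analysis and is cross-checked against the closed-form Hotelling
$T^2$ equivalence in the two-group case.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff` (selection) | 0.1 | correlation | inclusive threshold on signed structure correlations; the conventional screening value for this assay |
| `fold_limit` (magnitude exclusion) | 2.0 | fold vs subset median | keeps one high-frequency act from dominating a composite average |
| band `anchors` | 10, 50, 100 | events/session | typical Low/Medium/High frequencies of home-cage activity measures |
| `baseline_limit` (corticosterone) | 800 | ng/g faeces | baseline screen; values above it are order-of-magnitude outliers |
| `alpha` | 0.05 | — | significance level throughout |
| `n_paper` (generator) | 4 | animals/cell | converts printed SEMs to between-animal variance, $\sigma^2 = n \cdot \mathrm{SEM}^2$ |
| `tol` (pseudo-inverse) | 1e-10 | relative | rank threshold of the within-scatter eigendecomposition |

A note on the selection threshold: the cut-off is written "R²" in parts of
the assay literature but is applied to *signed* values (≥ 0.1 or ≤ −0.1),
which only makes sense for the correlation $r$ itself; `painscore` treats
it as a signed correlation threshold.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws behaviour counts per strain x group cell from a
negative binomial with the cell's published mean and variance
$n_{\mathrm{paper}}\cdot\mathrm{SEM}^2$ (Poisson when that variance does
not exceed the mean, structural zeros when the mean is zero, deterministic
rounded means when the SEM is zero). Durations are gamma-distributed
conditional on the count, with per-animal mean proportional to the count
so time tracks event number. Baseline corticosterone is lognormal per
strain (means near 30.3 and 31.5 ng/g); the 9-hour peak is the baseline
times a per-group multiplier times mean-one lognormal noise; body weight
starts near 26.5 g and changes by roughly +1.3% (controls) or −3.7%
(surgery). The calibration table for the manual ethogram ships as a
plain-text fixture (`inst/extdata/manual_group_params.csv`); the automated
ethogram has no published per-cell table, so its defaults are synthetic
magnitudes chosen so each behaviour's overall mean lands near its
frequency-band anchor, with surgery halving activity and roughly doubling
grooming.

The generator deliberately does **not** model: correlations between
behaviours within an animal (independence is assumed — real pain
behaviours co-occur), time-resolved event streams within a session,
repeated sessions per animal, or observer error. Consequently, passing
parameter-recovery tests shows that the analysis chain correctly inverts
*this* data-generating process at the published group statistics; it does
not certify performance on real videos, where between-behaviour
correlation would change the discriminant geometry.

Reproducibility is counter-based: each (behaviour, cell) pair derives its
own substream seed from the global seed, so appending a behaviour to the
catalog never perturbs the draws of existing behaviours.

## Numerical choices

- **Within-scatter singularity.** With up to 29 automated behaviours and
  48 animals, $W$ can be rank-deficient. The fit uses an eigenvalue
  thresholded pseudo-inverse (relative tolerance 1e-10) and reports the
  effective rank; a ridge term is available as configuration. This is
  deterministic and testable, unlike relying on a black-box solver's
  internal behaviour.
- **Sign convention.** Eigenvector signs are arbitrary, so each function
  is oriented so the *last* group level (V when grouping on surgery)
  scores above the first — the axis "increases with surgery", matching
  how the composite scores are interpreted. The alternative convention
  (largest loading positive) was rejected because the strongest loadings
  on the surgery function are the *normal* behaviours, which would flip
  pain behaviours to the negative side and destabilise downstream subset
  labels. A largest-loading fallback covers the measure-zero case of an
  exactly zero group contrast.
- **Zero-variance variables** are dropped with a warning and recorded on
  the fit, never silently; a fit with no usable variables is a classed
  error.
- **Band boundaries.** Bands are assigned by log-scale proximity to the
  anchors, equivalent to geometric-midpoint boundaries
  $\sqrt{10\cdot50}\approx22.4$ and $\sqrt{50\cdot100}\approx70.7$; an
  exactly boundary-valued mean assigns upward, and a never-observed
  behaviour goes to Low with a flag.
- **G-behave parenthesization.** The activity summary is computed as
  $10^{\log_{10}\{(L+1)(M+1)(H+1)\}/3-1}$ — the incremented band totals
  multiplied, not `L + (1·M) + …` — because only that reading is a
  geometric mean, keeps the zero-activity case finite (floor 0.1), and
  makes equal totals of 9 give exactly 1.
- **Type III sums of squares** with sum-to-zero contrasts (via
  `car::Anova`) match the SPSS-style univariate GLM convention and stay
  determinate under the mild imbalance introduced by corticosterone
  exclusions; on the fully balanced design Types I–III coincide, which
  the tests exploit by cross-checking against a sequential `aov()` fit.
- **Degenerate responses** (zero variance) yield a flagged table with
  $F = 0$, $p = 1$ rather than NaN statistics.

## Design choices where the design was open

- **Score memberships.** By default Score 1 = {Writhe, Press2, Rear Leg
  Lift, Lick Wound, Scratch Wound} and Score 2 = {High Rear, Lick Head,
  Scratch Head, Scratch Other, Dig, Normal Posture}, with Abnormal Walk,
  Walk Normal and Stop standalone. These are pinned (config-overridable)
  rather than re-derived per run: the data-driven magnitude-exclusion
  rule (drop members above `fold_limit` x subset median) also flags wound
  licking on the calibration means, because wound licking is itself an
  order of magnitude more frequent than the other pain acts in untreated
  surgery groups — yet it is the single most informative pain behaviour
  and belongs in the composite. The fold rule is therefore an
  operationalisation for *new* data (`memberships = "selection"`), while
  the pinned sets are the documented default.
- **Which function drives selection** defaults to Function 1 of the
  surgery-grouping fit, gated on its sequential Wilks test at
  $\alpha = 0.05$: selection refuses (empty subsets, flag, warning) on a
  non-significant function rather than thresholding noise.
- **Frequencies, not durations**, enter the screening discriminant
  analysis by default (`use = "frequency"`); durations are carried and
  can be entered via `use = "duration"`/`"both"`, but the composite
  scores and figures are frequency-based and frequency scoring is the
  practicable cage-side method.
- **The "Group" factor.** Published df patterns imply shifting model
  parameterisations (sometimes 2x2x3 factorial terms, sometimes a
  one-way 6-cell factor). Both are exposed: `factorial_anova()` takes the
  crossed factors, post-hocs use the 6-cell grouping, and combining
  `group` with `surgery` + `drug` in one model is an explicit aliasing
  error rather than a silent drop.
- **Weight change** is analysed in percent (`100 ·
  (w24 − w0)/w0`); the generator's group means (+1.3 / −3.7) are read as
  percentages, the only units under which a post-surgical change of that
  size is "modest" for a 26.5 g mouse.

## Problem sizes used in validation

The suite validates the discriminant engine against a brute-force scatter
eigenproblem and an independent reference implementation on 50 random
cohorts (3–6 groups, 4–10 variables, 30–60 animals, agreement to 1e-6);
parameter recovery runs 20 cohorts of 200 animals per cell; the type-I
calibration uses 500 null cohorts of 48 animals at the study's own cell
size. These sizes give binomial confidence intervals tight enough to
detect meaningful miscalibration while keeping the default test run
fast.

## Known limitations

- The Bartlett chi-square approximation is asymptotic; with 48 animals and
  14 skewed count variables its realised size can drift a point or two
  from nominal (the calibration test bounds this, it does not remove it).
- Structure correlations use the pooled within-group convention;
  total-sample correlations (available via `structure_correlations(fit,
  "total")`) can differ noticeably when group separation is strong.
- The independence-across-behaviours assumption of the generator makes
  recovered discriminant geometry cleaner than real data would be.
- No stepwise variable selection, cross-validated classification or
  prior-based allocation: the discriminant analysis is used descriptively,
  as a selection and visualisation device, not as a classifier.
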