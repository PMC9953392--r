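---
title: "Methods: affect-coupled network-based statistics on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: affect-coupled network-based statistics on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldnbs)
```

`coldnbs` implements a pre/post within-subject analysis of resting-state
ROI-to-ROI functional connectivity and its coupling with changes in
self-reported affect, exercised end-to-end on a synthetic cohort
generator. This vignette is the package's account of the underlying
models, the choices that were genuinely open, and what the test suite
does and does not establish.

## The inference model

For each subject $s$ and condition $c \in \{\text{pre}, \text{post}\}$ a
weighted Pearson correlation matrix over the 30 atlas ROIs is Fisher
transformed, $z = \operatorname{atanh}(r)$, giving 435 unique undirected
edges (870 ordered connections). The second-level response per edge is
the paired difference $\Delta z_s = z_s^{\text{post}} -
z_s^{\text{pre}}$. An edge-wise GLM

$$\Delta z_s = \beta_0 + \beta_1 \,\Delta\text{PA}_s +
  \beta_2 \,\Delta\text{NA}_s + \varepsilon_s$$

is fitted by least squares; a contrast $c^\top\beta$ yields a per-edge
$T$ statistic with $df = n - \operatorname{rank}(X)$. The condition
analysis uses the intercept-only design ($df = n-1$, i.e. $T(30)$ at $n
= 31$); each affect analysis uses an intercept plus that single
covariate ($df = n-2$), matching the degrees of freedom conventions of
the study design the package models. The control contrast
$(0, -1, 1)$ over (intercept, $\Delta$PA, $\Delta$NA) asks whether a
negative-affect association survives adjustment for positive affect.

Edges with two-sided $p$ below the height threshold (default $p <
0.001$) form a graph over ROIs; its connected components are the
candidate effects. Each component is summarised by its **mass**
$\sum_i T_i^2$ (the primary statistic; the secondary **intensity** is
$\sum_i |T_i|$) and its **size** (edge count). The mass-versus-intensity
choice was resolved from the worked numerical examples the package
reproduces: $5.70^2 + 6.64^2 + 3.75^2 + 8.64^2 \approx 165$ and $7.59^2
+ 8.31^2 \approx 126.7$, which match only the sum-of-squares definition.

Family-wise error is controlled by permutation: under the null the
pairing of responses and labels is exchangeable, so for the condition
contrast each permutation flips the sign of every subject's
$\Delta z$ row independently, and for covariate contrasts a single
random permutation of covariate rows is applied identically across all
435 edges, preserving the dependence between edges within a subject.
Each permutation reruns GLM, thresholding and component formation and
records the **largest** component mass; the FWE $p$ of an observed
component is the proportion of permutations whose largest mass is at
least as large (ties count; an add-one smoothed estimator is available
by flag). 1000 permutations is the default.

A threshold sweep reruns the NBS over a grid (default 0.05 down to 0.01
by 0.01, then 0.001 and 0.0001) and labels each family of
edge-overlapping significant components *focal* (significant only at
thresholds $\le 0.001$), *distributed* (only at $\ge 0.01$) or *mixed*.

Per-edge effect sizes are reported descriptively, without violating the
component-level inference: for covariate contrasts the Pearson
correlation between the covariate and $\Delta z$ with a Fisher-z 90%
interval; for the condition contrast the standardized mean difference
with a noncentral-$t$ interval. An interval that covers zero flags the
edge as not reliably estimable at that confidence level.

## The synthetic cohort generator

The generator defines the study conditions under which everything is
tested: 31 subjects, two sessions of 292 volumes at TR 2.68 s, 30
cortical ROIs in 7 networks (the two cerebellar nodes of the parent
atlas are excluded, and the sensorimotor network is represented by 3
nodes — two lateral and one superior — so the total is 30).

Session data are multivariate normal with a block-constant target
correlation: 0.4 within networks, 0.1 between (typical resting-state
magnitudes). Effects are injected on the Fisher-z scale of the target
correlation and mapped back with $\tanh$ — the same scale the inference
operates on, so a planted `delta_z` of 0.4 is recovered by the sample
z-difference up to the Fisher sampling error $1/(T-3)$ per session.
Covariate coupling adds $\beta \cdot (\text{covariate} - \mu)$ to an
edge's post-condition z, *centred* at the configured covariate mean, so
a coupled effect is a pure brain–behaviour association with no
group-mean shift; removing the covariate from the design then abolishes
detection, which is exactly the control analysis the package mirrors.
A non-positive-definite target (e.g. contradictory planted edges) fails
with the offending edges named.

Nuisance structure is layered on top: six-parameter random-walk motion
(steps chosen to give a mean framewise displacement near 0.1 mm), spikes
at a configurable per-frame rate implemented as persistent 1.2–1.8 mm
translation jumps (guaranteeing FD > 0.9 mm at the spike frame), ten
noise-ROI signals (drift plus respiratory- and cardiac-band sinusoids,
labelled `wm*`/`csf*`) partially leaked into the ROI data, and a global
intensity artifact at spiked frames. With the default leakage (0.15) the
per-edge noise roughly doubles relative to the clean configuration —
property-style tests that verify sampling-theory quantities therefore
switch leakage and spikes off, which the test helpers call the *clean*
configuration.

PANAS items are ordinal 1–5 scores obtained by thresholding latent
normals at equal-width cut points ($\pm 0.5$, $\pm 1.5$; latent SD 1).
Pre-condition expected totals emulate typical pre-intervention levels
(positive 29.28, negative 16.75, with *nervous* and *distressed*
starting elevated at an expected 3.5 so that a negative shift has room
above the per-item floor of 1). Each subject draws a target
positive-affect change from $N(7, 2.5^2)$ and a negative change from
$N(-4.66, 2.5^2)$; the latent means of the designated shifted items
(*active, alert, attentive, inspired, proud* up; *nervous, distressed*
down) are solved numerically so the expected subscale totals move by
those amounts, with overflow beyond an item's floor/ceiling spilling
onto the remaining items of the subscale. The equal latent spread
(2.5 for both subscales) is a homogeneity choice: the subscales still
differ in realized variability because mid-scale items (positive) carry
more ordinal measurement noise than near-floor items (negative), and
because the negative subscale's floor of 10 bounds how far a 16.75
baseline can drop — with larger spreads the configured $-4.66$ mean
change would be silently truncated. The same per-subject draws feed the
covariate-coupled connectivity shifts, so questionnaire and brain are
consistent within a cohort.

Physiology traces per subject comprise a 120 s seated baseline and a
300 s immersion: heart rate at 1 Hz with a step increase (mean +10.61
beats·min⁻¹), breath events with a tidal-volume step (mean +0.44 L) and
a single large inspiratory gasp (mean 2 L) within the first seconds of
immersion, and water temperature at 0.1 Hz from $N(19.93, 0.13^2)$ °C.

## Denoising

The pipeline is fixed and logged: build confounds → band-pass the
confounds → regress → band-pass the residuals → censor flagged frames.

* **Outlier flags**: framewise displacement above 0.9 mm or a
  frame-to-frame global-signal change above 5 SD. FD is the Power-style
  sum of absolute frame-to-frame differences of the three translations
  plus the three rotations converted to arc length on a 50 mm sphere (a
  definition choice; only the threshold, not the formula, was given for
  the design being modelled).
* **aCompCor**: the noise-ROI matrix is linearly detrended and the top
  5 principal-component time courses per mask (`wm`, `csf`) enter the
  design, unit-variance scaled. 12 motion regressors (6 parameters +
  first differences) complete the nuisance set. Global-signal
  regression is deliberately absent.
* **Band-pass**: an ideal (frequency-mask) zero-phase filter retaining
  0.008–0.09 Hz. The mask filter was chosen over an IIR design for a
  bit-reproducible contract; its sharp edges are acceptable because all
  downstream statistics are invariant to the filter's phase and the
  pass band is wide relative to the bin spacing.
* **Ordering**: confounds are band-passed *before* regression. With
  in-band confounds, regression residuals stay orthogonal to the
  confounds after filtering, which makes regress-then-filter idempotent
  (verified to RMS < 1e-6) and prevents the two steps from
  reintroducing each other's removed variance.
* **Censoring** removes flagged frames after filtering, before
  correlation.
* **QC-FC**: across subjects, each edge's connectivity is correlated
  with mean FD; a sign-flip permutation of the centred FD vector tests
  whether the edge-wise correlation distribution is centred on zero.

## Numerical choices and degenerate inputs

Correlations are clamped at $|r| = 1 - 10^{-12}$ before the Fisher
transform so duplicated series give the maximal finite z (flagged)
rather than infinities. Zero-residual edges in the GLM receive a
standard-error floor of $10^{-12}$ and a `clamped` flag. FWE $p$ uses
the plain proportion (an observed mass above every permutation gives
$p = 0$); the smoothed $(1+k)/(n+1)$ variant is one flag away. The
identical pre/post item-test case treats the $t$ statistic of all-zero
differences as 0, giving a well-defined Bayes factor below 1 rather
than an error. Signed-rank tests drop zero differences (the
convention of the underlying test). All random stages consume explicit
seeds; identical seeds give byte-identical cohorts and permutation
nulls.

Bayes factors use standard defaults: a JZS Cauchy prior of scale
$\sqrt{2}/2$ on the standardized effect for paired/one-sample tests and
a stretched beta of width 1 for correlations, both evaluated by
numerical integration (the correlation Bayes factor uses the exact
sampling density of $r$ via the Gauss hypergeometric function). Neither
the prior nor the engine was specified by the modelled analysis; these
are the conventional defaults, and the implementations are verified in
the tests against values frozen from an independent implementation.

The affect LMM is `score ~ affect * condition + (1 | subject)` by
maximum likelihood with sum-to-zero contrasts, Type-III F tests with
Satterthwaite denominator df, and Bonferroni-adjusted post-hoc
post-minus-pre contrasts within each affect. The random-intercept LRT
compares against a fixed-effects-only fit, $2\Delta\ell$ on one
chi-square df. Satterthwaite df is a choice: the denominator-df
convention of the modelled analysis (93 for every effect) follows from
a pooling rule that is not derivable from its description, so exact df
agreement is not a goal.

## Problem sizes in the test suite

Property-style checks run at sizes chosen to give stable Monte-Carlo
verdicts while keeping the default suite fast: FWE calibration uses 200
null cohorts of 20 subjects × 150 volumes with 200 permutations each
(the empirical rate must sit inside the binomial 95% interval around
0.05); power/recovery uses 50 cohorts at the full 31 × 292 design with
a planted 4-edge star whose coupling is calibrated for per-edge
$|T| \approx 5$; behavioural recovery fits 50 cohorts of 33 subjects;
the permutation estimator is validated against exhaustive enumeration
of all 64 sign-flip patterns at $n = 6$. The full suite runs in about
two minutes on one CPU.

## What passing tests do and do not show

The generator draws stationary Gaussian sessions with block-constant
covariance; real BOLD data have heavier tails, spatially structured
noise, autocorrelated sampling (which inflates the variance of
correlation estimates beyond $1/(T-3)$), imperfect atlases and
registration error. Calibration and power results on the generator
therefore validate the *inference machinery* — error control given
exchangeability, recovery of effects of known size — not claims about
any real cohort. In particular, real-data components cannot be
reproduced without the original scans: the worked component
reconstructions in the acceptance checks operate on the reported
per-connection statistics, which is exactly what they are meant to
verify (the component-forming and mass arithmetic, not the raw data).

## Known limitations

Temporal autocorrelation is not modelled by the generator, and the
weighted-correlation weights default to uniform (the weight profile
"spanning the whole session" is configurable but unspecified).
Sub-second slice timing, volumetric preprocessing and voxel-level
analyses are out of scope. The threshold-sweep classification depends
on the chosen grid and the 0.001/0.01 cut points for
conservative/liberal. The permutation scheme for covariate contrasts
is simple label rearrangement, not Freedman–Lane; with a single
covariate of interest and an intercept this is the standard NBS
practice, but it is approximate when nuisance covariates correlate
with the covariate of interest.
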