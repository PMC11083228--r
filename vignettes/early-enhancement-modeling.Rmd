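---
title: "Modeling early contrast enhancement in ultrafast DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early contrast enhancement in ultrafast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultraDCE)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI of the prostate acquired at ultrafast
temporal resolution (here 1.695 s per dynamic, 150 dynamics) resolves the
first two minutes of contrast uptake well enough to fit kinetic models
that conventional 5-15 s protocols cannot support. `ultraDCE` implements a
complete analysis chain for such data: signal-to-concentration conversion,
arterial input function (AIF) extraction with automatic bolus-arrival
detection, voxelwise fitting of a two-compartment uptake (2CU)
pharmacokinetic model and of two empirical mathematical models (EMMs),
time-to-peak, physiological validity masking, ROI summarization, and the
cohort-level statistics comparing prostate zones, PI-RADS categories and
biopsy grade groups.

Because clinical DCE data cannot be redistributed, the package ships a
synthetic-data module (digital reference object phantoms and cohort
simulators) whose defaults emulate the acquisition and cohort composition
of the motivating study, so every stage is testable against known ground
truth.

## Signal model and preparation

Signal is converted to contrast-agent concentration with the linearized
relation

$$C(t) = R\,\frac{S(t) - S_0}{S_0},$$

where $S_0$ is the mean baseline signal and $R = 1/(r_1 T_{10})$ collects
the contrast relaxivity and the native longitudinal relaxation time.
Without per-patient T1 mapping, $R = 1$ is assumed identical in lesions
and normal tissue, so concentration is unitless and all fitted amplitudes
carry an arbitrary common scale. The baseline window excludes the first
two timepoints (non-steady-state transients) and ends at the last frame
before arterial contrast arrival. Negative concentrations from noise are
deliberately not clipped: clipping would bias fits near baseline.

Bolus arrival is detected on the arterial mean curve with a running
threshold: the first frame exceeding the accumulated baseline mean by
5 baseline SDs, confirmed by the following frame (a genuine bolus stays
up; a noise spike does not). The threshold needs at least three baseline
frames for a usable SD estimate, so the earliest reportable arrival is
frame 6. If the threshold never fires, the start of the steepest global
upslope is used. The same rule is applied to any curve that needs an
arrival estimate. The AIF is the unscaled mean concentration over the
arterial ROI; no amplitude correction, partial-volume or dispersion
correction is attempted — there is no generally accepted solution, and
the validity ranges below absorb the resulting scale ambiguity.

All kinetic fitting is restricted to a 2-minute window from the onset of
enhancement (71 frames at the 1.695 s grid), re-origined so that $t = 0$
at arrival.

## The two-compartment uptake model

Early enhancement, before back-flux from the interstitium matters, is
described by the 2CU model: a plasma compartment with flow $F_p$ and
unidirectional extraction $PS$ into the extravascular extracellular
space. Its tissue curve is the convolution of the AIF with a
biexponential impulse response, which is the form actually fitted:

$$C(t) = \left[\alpha_+ + \alpha_- e^{-\beta_-(t - t_0)}\right] \ast
  \mathrm{AIF}(t).$$

Matching this against the physiological residue form
$F_p\,[E + (1 - E)e^{-t/MTT_p}]$ gives the conversion implemented in
`biexpToPhysio()`:

$$F_p = \alpha_+ + \alpha_-,\qquad E = \alpha_+/F_p,\qquad
  PS = \frac{F_p E}{1 - E},\qquad v_p = \frac{F_p + PS}{\beta_-},$$

with the derived quantities $MTT_p = v_p/(PS + F_p) = 1/\beta_-$,
$T_c = v_p/F_p$, $E = PS/(PS + F_p)$ and $K^{trans} = E F_p = \alpha_+$.
The mapping is validated two ways: the documented starting estimates
$(\alpha_+, \alpha_-, \beta_-) = (0.2, 0.2, 4)$ reproduce exactly their
stated physiological equivalents $(F_p, PS, v_p) = (0.4, 0.4, 0.2)$, and
the test suite checks that forward curves built independently from both
parameterizations coincide to $10^{-8}$ for random valid parameters and
arbitrary inputs.

```{r mapping}
biexpToPhysio(c(alphaPlus = 0.2, alphaMinus = 0.2, betaMinus = 4))
deriveSecondary(c(vp = 0.2, ps = 0.4, fp = 0.4))
```

### Numerical choices

The convolution is evaluated on the acquisition grid in minutes. The
default scheme treats the AIF as piecewise linear and integrates the
exponential kernel analytically from frame to frame; this is exact for
that input model, costs $O(n)$, and keeps full accuracy for fast decay
rates. A plain trapezoidal convolution is also provided and used as an
independent cross-check in the tests: at $\beta_- = 10\,\mathrm{min}^{-1}$
and 1.695 s frames its error against a 100x-oversampled quadrature
reaches $\approx 0.2\%$ of peak, while the default scheme stays below
$0.01\%$ — which is why the exact scheme, not the trapezoid, is the
default.

The bolus delay $t_0$ is fixed at 0 by default: both the AIF and the
tissue window are re-origined at the detected arterial arrival, and
prostate-to-iliac delay differences are small relative to the temporal
footprint of the impulse response. Fitting $t_0 \in [0, 10\,dt]$ can be
enabled per voxel via `dceConfig(fitT0 = TRUE)`.

Fitting minimizes the sum of squared residuals with bounded
Levenberg-Marquardt (`minpack.lm`), from the single documented start.
The optimizer bounds are loose positivity constraints
($\alpha_\pm \in [0, 20]$, $\beta_- \in (0, 100]$); the physiologically
credible ranges are applied *after* fitting, as validity masks. This
ordering matters: it reproduces the observed behavior that a whole ROI
can end up with no voxels in the accepted range for one parameter (PS,
and hence E and $K^{trans}$) while remaining analyzable for the others.
An all-zero voxel returns the starting estimates flagged non-converged.

### Validity ranges

`parameterRanges()` lists the accepted intervals: $v_p \in [0, 10]$,
$PS \in (0, 10]$, $F_p \in [0, 10]$, $MTT_p, T_c \in [0, 5)$ min,
$E \in [0, 1]$, $K^{trans} \in [0, 10]$, exponential rate
$\alpha \in (0, 1]$ per dynamic, sigmoid $A_1 - T_0$ and
$A_2 \in (0, 100]$ dynamics. The $v_p$ bound is deliberately far above
the physical limit of 1 because the unscaled AIF leaves a global
amplitude ambiguity in all AIF-scaled parameters. On disk, invalid
voxels are NaN in the value volume, with an explicit companion validity
volume.

## Empirical models and time-to-peak

Two curve-shape models are fitted per voxel on a time axis in dynamics
(frame counts, matching the units their parameters are reported in):

- exponential uptake $C(t) = A\,(1 - e^{-\alpha (t - t_0)})$, and
- a sigmoid, the integral of a Gaussian bump, implemented as
  $C(t) = A_0\,\Phi((t - A_1)/A_2)$.

The printed integral form of the sigmoid lacks a $1/A_2$ factor for a
normalized Gaussian; the $\Phi$ normalization used here is the only
reading under which $A_0$ is the plateau amplitude and $A_2$ a slope
width, and it is what the package implements. $A_1$ is fitted in
window coordinates, so it directly equals the center time relative to
arrival, $A_1 - T_0$.

Weighted least squares limits the influence of wash-out: weights are 1
over the uptake phase and 0 after. The default policy keeps frames up to
max(120 s, peak time) — "at least the first 120 s, or to peak of
enhancement". The original per-voxel optimizer-determined cutoff for the
exponential model is not recoverable from its description; the `to_peak`
policy is the provided approximation, and the combined default is used
throughout. Starting estimates come from an initial look at the curve:
amplitude from the last 10% of the weighted window, rate from the
half-amplitude time ($\alpha = \ln 2/t_{1/2}$), sigmoid width from the
10-90% rise divided by 2.563 (the number of normal SDs spanning that
rise). Time-to-peak is the argmax frame minus the arrival frame, earliest
maximum on ties, which makes it deterministic and invariant to positive
affine rescaling.

The amplitudes $A$, $A_0$ and the arrival $t_0$ are fitted but excluded
from cohort statistics; they show negligible tissue contrast.

## ROI summaries and cohort statistics

ROI summaries are computed masked-then-averaged: mean and sample SD
(denominator $n - 1$) over the voxels that are inside the ROI *and*
inside the validity mask. An ROI with no valid voxels produces an empty
summary that is dropped and logged per parameter — it never removes the
ROI's other parameters. The ROI-level mean is the unit of all statistics;
multiple lesions per patient are treated as independent, a simplification
shared with the motivating analysis and noted as a limitation.

Four analyses run per parameter:

1. Welch t-test, normal-appearing PZ vs TZ (pooled-variance optional via
   `dceConfig(var.equal = TRUE)`; Welch is the default because the zone
   split is heavily unbalanced, about 29 vs 6).
2. Two-way ANOVA over all ROIs with zone and PI-RADS category (normal
   tissue enters as category 1) as main effects, no interaction, Type II
   sums of squares — the appropriate single-p-per-factor decomposition
   for an unbalanced design.
3. Welch t-test of PZ lesions, biopsy negative vs positive (GG >= 1).
4. One-way ANOVA across grade groups in the PZ, with normal-appearing
   ROIs pooled into the negative class (5 levels).

One Benjamini-Hochberg correction at $q = 0.05$ is applied across the 33
ANOVA p-values — 11 parameters x 2 two-way factors plus 11 one-way
tests — which is the reading of the "33 ANOVAs" family that reproduces
its count; the two t-test families stay uncorrected, matching how the
results tables are presented. Tukey-Kramer HSD post hoc tables are
produced for parameters whose omnibus ANOVA is BH-significant.
Zero-variance degenerate groups return p = 1 with a flag instead of
failing the pipeline.

## What the synthetic data emulate — and what they do not

`makePhantom()` builds a 4D digital reference object: an arterial region
carrying a gamma-variate bolus (arrival 25 s, peak amplitude 5, time to
peak about 11 s after arrival, optional 10% recirculation plateau) and
homogeneous tissue regions generated from known 2CU or EMM truth
parameters, inverted through the signal equation around a baseline of
100, with seeded Gaussian noise on signal (Rician optional; at prostate
DCE signal-to-noise the difference is minor). Truth magnitudes default
to the documented physiological values $(F_p, PS, v_p) =
(0.4, 0.4, 0.2)$.

`makeCohort()` is a fast path that draws ROI-level parameter means
directly — statistics-level validation does not need voxel data. Its
defaults mirror the study composition exactly: 25 patients, 35 lesions
(4 PI-RADS 3, 21 PI-RADS 4, 10 PI-RADS 5; 29 PZ, 6 TZ), grade groups
11 negative and 6/9/5/4, one paired normal-appearing ROI per lesion.
Each ROI mean is baseline + zone shift + monotone severity effect +
Gaussian noise, with effects in within-group SD units (default 0.8 SD
per severity level on $F_p$, $MTT_p$, $T_c$, $E$, $\alpha$,
$A_1 - T_0$, $A_2$ and TTP; zero on $v_p$, $PS$ and $K^{trans}$; the
within-group SD is 40% of the baseline mean, the magnitude implied by
the zone-contrast p-values at the study's group sizes). Grade groups are
coupled to PI-RADS categories by jittered rank matching so one latent
severity axis drives both factors while the marginal counts stay exact.

What passing tests on these data do **not** show: the generators contain
no anatomy, no B1/T1 physics, no k-space undersampling artifacts, no
motion, and the cohort fast path has no voxel-level heterogeneity —
agreement on them validates the mathematics and the statistical wiring,
not clinical performance.

## Problem sizes used in validation

The shipped validation uses sizes chosen to exercise every claim at
desk scale: dual-parameterization and quadrature checks over 25 random
parameter/AIF draws on the full 150-frame grid; parameter recovery over
200 seeded noisy replicates at SNR 20 plus 50 replicates at each of SNR
5/10/20/50 (with common noise draws across SNR levels, so the
error-vs-noise comparison is paired); statistical calibration over 1000
single-parameter null-cohort replicates; selectivity over 60 full cohort
analyses; phantoms of $8^2$-$16^2$ voxels per slice. Larger volumes
change runtime, not behavior, since fitting is voxelwise.

## Known limitations

- $R = 1$ makes all AIF-scaled parameters relative; absolute physiology
  would need T1 mapping and AIF calibration.
- The 2-minute window intentionally under-constrains $PS$ in slowly
  enhancing tissue; the validity masks make this visible (empty PS
  summaries) rather than hiding it.
- The per-run selectivity check asks every one of 11 parameters to land
  on the correct side of BH significance simultaneously; with three true
  nulls whose p-values are uniform, the per-run success probability is
  bounded near 0.9 however large the injected effects are, so run-level
  "perfect split" rates settle below 0.95. The per-parameter error rates
  themselves are calibrated (see the null-rejection results the
  acceptance script reports).
- Motion correction, registration, DICOM conversion and ROI drawing are
  upstream, external steps; all inputs are assumed already on the DCE
  grid.
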