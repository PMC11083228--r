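# ultraDCE

Early contrast enhancement analysis for ultrafast dynamic
contrast-enhanced (DCE) MRI of the prostate.

DCE-MRI acquired at ultrafast temporal resolution (~1.7 s per dynamic)
resolves the first two minutes of contrast uptake well enough to fit
kinetic models that conventional 5–15 s protocols cannot support.
`ultraDCE` is for imaging scientists who want to turn such a 4D series
plus ROI masks into quantitative early-enhancement parameters and
cohort-level statistics, and to validate every step against synthetic
ground truth.

The pipeline:

1. **Preparation** — baseline `S0` (excluding the first two timepoints,
   ending before bolus arrival), conversion to concentration
   `C(t) = R (S(t) − S0)/S0` with `R = 1`, arterial input function (AIF)
   extraction from an arterial ROI, automatic bolus-arrival detection,
   and a 2-minute analysis window from the onset of enhancement.
2. **Two-compartment uptake (2CU) model** — voxelwise bounded
   least-squares fitting of the biexponential-convolution form
   `C(t) = [α₊ + α₋ e^(−β₋(t−t₀))] ∗ AIF(t)`, converted to physiology via
   `Fp = α₊ + α₋`, `E = α₊/Fp`, `PS = Fp·E/(1−E)`, `vp = (Fp+PS)/β₋`,
   with derived `MTTp = vp/(PS+Fp)`, `Tc = vp/Fp`, `Ktrans = E·Fp`.
3. **Empirical models** — weighted fits of an exponential uptake curve
   `A(1 − e^(−α(t−t₀)))` and a Gaussian-integral sigmoid
   `A₀·Φ((t−A₁)/A₂)`, plus time-to-peak, with uptake-phase weighting
   (1 through max(120 s, peak), 0 after).
4. **Summaries and statistics** — physiological validity masking
   (out-of-range voxels become NaN), per-ROI mean/SD, and four cohort
   analyses per parameter: a zone t-test on normal tissue, a two-way
   zone × PI-RADS ANOVA (Type II), a biopsy-outcome t-test and a one-way
   grade-group ANOVA, with one Benjamini–Hochberg correction across the
   33 ANOVA p-values and Tukey HSD post hocs.
5. **Synthetic data** — seeded digital reference object phantoms and a
   cohort simulator with known ground truth, so the whole chain is
   testable offline.

## Worked example

Build a small phantom with known truth, run the single-patient pipeline,
and look at the recovered parameters:

```r
library(ultraDCE)

ph <- makePhantom(phantomSpec(dim = c(10, 10, 1), noiseSd = 0.01, seed = 42,
  arteryBox = list(x = 1:2, y = 1:2, z = 1),
  regions = list(
    list(name = "lesion", label = "lesion", zone = "PZ", model = "2cu",
         params = c(vp = 0.2, ps = 0.4, fp = 0.4),
         box = list(x = 4:6, y = 4:6, z = 1)),
    list(name = "normal", label = "normal", zone = "PZ", model = "2cu",
         params = c(vp = 0.1, ps = 0.1, fp = 0.2),
         box = list(x = 8:10, y = 8:10, z = 1)))))

out <- runPatient(ph$series, ph$masks$artery,
                  ph$masks[c("lesion", "normal")])
out$aif
#> Aif: 150 frames @ 1.695 s, arrival frame 17, peak 5.14 (4 source voxels)
out$maps$fp
#> ParameterMap 'fp' [1/min]: 18/100 valid voxels, range 0.1905..0.4161
subset(out$summaries, parameter %in% c("fp", "e"),
       select = c(roi_id, parameter, mean, sd, n_valid))
#>    roi_id parameter      mean          sd n_valid
#> 3  lesion        fp 0.4014009 0.010427857       9
#> 6  lesion         e 0.5017534 0.011981453       9
#> 17 normal        fp 0.2020628 0.007154676       9
#> 20 normal         e 0.3301062 0.005603492       9
```

At 1% signal noise the lesion's true plasma flow (0.4 min⁻¹) and
extraction fraction (0.5) are recovered to well under 1% in the ROI mean;
only the 18 voxels inside the two tissue ROIs were fitted, and all fall
inside the credible ranges, hence `n_valid = 9` per ROI.

Cohort-level statistics on a simulated study-sized cohort (25 patients,
35 lesions with paired normal ROIs):

```r
tab <- makeCohort(cohortSpec(seed = 1))
res <- runCohort(tab)
res$twoway[, c("parameter", "p.zone", "p.pirads", "sig.pirads")]
#>      parameter       p.zone     p.pirads sig.pirads
#> 1           vp 2.805397e-01 2.032772e-01      FALSE
#> 2           ps 6.643651e-01 6.939303e-01      FALSE
#> 3           fp 3.100976e-04 1.538497e-08       TRUE
#> 4         mttp 4.078291e-01 6.584935e-07       TRUE
#> 5           tc 5.790002e-01 1.051347e-05       TRUE
#> 6            e 4.910174e-01 3.237799e-05       TRUE
#> 7       ktrans 7.722371e-01 5.671722e-01      FALSE
#> 8        alpha 1.432328e-05 1.103193e-10       TRUE
#> 9  a1_minus_t0 3.432751e-03 6.966345e-06       TRUE
#> 10          a2 6.588793e-03 4.928897e-05       TRUE
#> 11         ttp 1.484647e-01 7.201457e-08       TRUE
```

The simulator injects monotone PI-RADS effects on Fp, MTTp, Tc, E, α,
A₁−T₀, A₂ and TTP and none on vp, PS and Ktrans; the BH-corrected
PI-RADS column recovers exactly that split here. `sig.*` columns are
flags after the 33-test BH family at q = 0.05.

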