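# iodineperf

Quantitative, iodine-based analysis of dynamic dual-energy CT myocardial
perfusion in R.

Dual-layer spectral CT reconstructs *iodine density* images whose pixel
values are absolute contrast-agent concentrations (mg/ml), free of the
soft-tissue Hounsfield offset and largely immune to beam hardening. Imaging
the first pass of a contrast bolus through the heart as a dynamic series of
such images permits a fully quantitative assessment of myocardial
hemodynamics — of interest to radiologists and imaging scientists working
on the detection of ischemic or infarcted myocardium. This package
implements the complete analysis chain for such series, plus a calibrated
digital thorax phantom so that every stage can be validated without access
to scanner data.

## The model

Each pixel's time–enhancement curve is modelled as a gamma-variate bolus
with an explicit pre-contrast baseline,

```
I(t) = I0 + A (t − t0)^α exp(−(t − t0)/β),   t > t0,
```

fitted by bounded Levenberg–Marquardt in two steps: a preliminary fit over
all samples locates the peak, then samples more than 12 s past it — the
second pass of recirculating contrast — are excluded and the curve refitted.
From the fitted parameters the four standard maps follow in closed form:

| map | definition | units |
|---|---|---|
| peak enhancement | `Imax − Imin` (peak density minus baseline) | mg/ml |
| perfusion | max d/dt I(t) (maximal-slope method) | mg/ml/s |
| time to peak | `t0 + αβ` on the acquisition clock | s |
| iodine volume | ∫ I(t)dt over [0, min(50 s, density-stop)] | mg/ml·s |

Pixels whose fitted peak density stays below 0.55 mg/ml, or whose fit
failed, are masked invalid; maps are smoothed with a 3×3 median filter that
excludes invalid neighbors. A semi-static *two-shot* estimator reproduces
the peak-enhancement map from just two saturation-phase frames (average,
minor Gaussian blur, offset subtraction) at a fraction of the radiation
dose. Contrast metrics (relative signal increase, temporal CNR) and
protocol dosimetry arithmetic round out the pipeline.

See the vignette (`vignettes/iodine-perfusion-mapping.Rmd`) for the full
account of the model, parameter defaults and design decisions.

## Worked example

```r
library(iodineperf)

## calibrated phantom: 15 non-equidistant frames over 26 s, 0.40 mm pixels
spec    <- default_phantom(grid = 64, noise_sigma = 0)
phantom <- render_series(spec)
phantom$series
#> dynamic series: 15 frames of 64 x 64 px (0.40 mm), t = 0.00..24.90 s, mg/ml

## pixel-wise two-step fitting and map assembly
fits <- fit_field(phantom$series)
maps <- smooth_maps(compute_maps(fits))
st   <- roi_statistics(maps, phantom$masks, reference = "descending_aorta")
subset(st, quantity == "peak_enhancement",
       select = c(region, median, pct_of_reference))
#>              region median pct_of_reference
#> 1        myocardium   0.92         11.85567
#> 5    left_ventricle   7.52         96.90722
#> 9   right_ventricle   3.77         48.58247
#> 13 descending_aorta   7.76        100.00000
#> 17     ventral_lung   1.01         13.01546
#> 21 pulmonary_artery   6.92         89.17526
```

The myocardial medians recover the phantom's calibrated ground truth
exactly: peak enhancement 0.92 mg/ml (11.86 % of the descending aorta),
perfusion 0.085 mg/ml/s, iodine volume 29.89 mg/ml·s.

The two-shot estimate from the 23.3 s and 24.9 s frames, at the phantom's
native 256 px geometry:

```r
native <- render_series(default_phantom(grid = 256, noise_sigma = 0))
ia  <- which(native$series$frame_times == 23.3)
ib  <- which(native$series$frame_times == 24.9)
est <- two_shot_peak_enhancement(native$series$frames[ia, , ],
                                 native$series$frames[ib, , ],
                                 offset = 0.16, blur_sigma = 1)
err <- relative_error_map(est, native$truth$peak_enhancement,
                          native$truth$valid_mask)
round(median(err[native$masks$myocardium]), 1)
#> [1] 6.2
round(median(est[native$masks$left_ventricle]), 2)   # truth: 7.52
#> [1] 1.3
```

The saturated myocardium is recovered to within a few percent while
early-peaking ventricular and arterial structures are strongly
underestimated — the expected behavior of a saturation-phase estimator.
Contrast metrics and dose arithmetic:

```r
100 * relative_signal_increase(roi_sample(0.16, 0.02), roi_sample(1.08, 0.05))
#> [1] 575
cumulative_ctdivol(15, 9); cumulative_ctdivol(2, 9)
#> [1] 135
#> [1] 18
iodine_load_per_kg(40, 300, 78)$reported
#> [1] 154
```

## Command line

`exec/iodineperf` wraps the package for shell use:

```sh
iodineperf simulate --out sim --grid 256 --noise-sigma 0.05 --seed 1
iodineperf maps     --series sim/series.nii.gz --out maps
iodineperf twoshot  --series sim/series.nii.gz --frame-a 14 --frame-b 15 \
                    --offset 0.16 --out twoshot \
                    --reference sim/truth/peak_enhancement.nii.gz
```

Series are NIfTI (or multi-page TIFF) stacks with a JSON sidecar
(`frame_times_s`, `pixel_spacing_mm`, `units: "mg/ml"`); map runs emit the
four maps, the validity mask, a per-region CSV report and a JSON run
manifest.

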