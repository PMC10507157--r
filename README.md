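# sersvoc

Trace volatile aldehydes in exhaled breath are promising disease biomarkers,
but their surface-enhanced Raman scattering (SERS) spectra are nearly
degenerate: every analyte is read out through the same
4-aminothiophenol (4-ATP) reporter chemistry, and at ppb–ppt levels the
class-specific Schiff-base bands sit on an erratic, noisy background.
`sersvoc` is a tidyverse-style R package for the full analysis chain used to
discriminate six gaseous aldehydes (formaldehyde, benzaldehyde,
oxalaldehyde, glutaraldehyde, salicylaldehyde, 4-nitrobenzaldehyde) from
such spectra, built around a synthetic-spectrum generator that stands in for
undeposited laboratory data.

The package covers, as composable tibble-in / tibble-out functions:

* **Synthetic SERS spectra** — six aldehyde signatures sharing the 4-ATP
  reporter bands (1141 / 1179 / 1593 cm⁻¹) and a phenylacetylene internal
  standard at 1985 cm⁻¹ in the Raman-silent region, with class-specific C=N
  and C–C bands, Lorentzian line shapes, peak-center jitter, erratic
  miscellaneous peaks in 1100–1500 cm⁻¹, polynomial baseline and white
  noise, on a 1000–2300 cm⁻¹ axis of 648 points.
* **Ratiometric quantification** — windowed peak intensities with local
  edge-line baseline, the internal-standard ratio
  `I₁₆₂₅ / I₁₉₈₅`, an ordinary-least-squares calibration
  `ratio = k·log₁₀(c) + b`, and the limit of detection
  `LOD = 10^((m_b + 3·s_b − b)/k)` from blank statistics at
  signal-to-noise 3:1.
* **Featurization** — the 12-band partition of 1000–2300 cm⁻¹ (interior
  edges 1030, 1152, 1174, 1195, 1280, 1350, 1410, 1450, 1522, 1545,
  1800 cm⁻¹) and the per-band highest-peak position as a 12-dimensional
  feature vector.
* **Classification** — a fully connected 12 → 6 → 6 softmax network written
  out explicitly (Glorot initialization, sigmoid hidden layer, full-batch
  gradient descent on categorical cross-entropy, backpropagated gradients
  verified against finite differences), with stratified 540/108 splitting.
* **Evaluation** — confusion matrices whose row-normalized diagonal gives
  per-class prediction accuracy, one-vs-rest ROC curves with
  Mann–Whitney-consistent trapezoidal AUC, macro/micro averages, and a PCA
  baseline on the raw intensities.
* **Transport models** — an explicit finite-difference solver for Fick's
  second law ∂c/∂t = Dₐ ∂²c/∂x² comparing analyte retention under slow
  (MOF-confined) vs fast (open) diffusion, and the evanescent EM
  penetration depth Z = (λ/2π)·√((ε′ₘ − ε′_Ag)/ε′_Ag²).

## Worked example

Simulate the harder acquisition regime (4 cm⁻¹ jitter, 10 % noise, five
erratic peaks per spectrum), train the network and evaluate it:

```r
library(sersvoc)

res <- run_pipeline(pipeline_config(preset = "hard", seed = 7))
glance(res$report)
#> # A tibble: 1 × 5
#>   accuracy macro_auc micro_auc min_class_auc max_class_auc
#>      <dbl>     <dbl>     <dbl>         <dbl>         <dbl>
#> 1    0.713     0.958     0.960         0.919             1
```

Held-out accuracy is 71 % on this seed (chance is 16.7 %); the easy preset
reaches 99–100 %. The confusion matrix shows the physically expected
structure — confusions concentrate among classes whose strongest
characteristic bands are closest in Raman shift (oxalaldehyde 1632 vs
glutaraldehyde 1627 cm⁻¹; benzaldehyde 1574 vs formaldehyde 1585 cm⁻¹):

```r
res$report$confusion
#> Confusion matrix (accuracy 0.713)
#>                      predicted
#> true                  formaldehyde benzaldehyde oxalaldehyde glutaraldehyde ...
#>   formaldehyde               0.833        0.056        0.000          0.000
#>   benzaldehyde               0.444        0.500        0.000          0.056
#>   oxalaldehyde               0.000        0.000        0.500          0.500
#>   glutaraldehyde             0.000        0.000        0.333          0.611
#>   salicylaldehyde            0.111        0.000        0.000          0.056
#>   4-nitrobenzaldehyde        0.000        0.000        0.000          0.000
```

Quantify benzaldehyde over five decades of concentration and estimate the
detection limit:

```r
cal <- fit_calibration(generate_calibration_series(seed = 7))
cal
#> Ratiometric SERS calibration (ratio ~ log10 concentration)
#>   slope      0.3495 per decade
#>   intercept  3.3966
#>   R-squared  0.9939
#>   residual SD 0.04169  (n = 15)

blk <- blank_statistics(seed = 8)
estimate_lod(cal, blk$blank_mean, blk$blank_sd)
#> LOD = 3.09e-10 v/v (blank 0.0243 +/- 0.0162, SNR 3:1)
```

The fitted slope and intercept recover the generator's configured response
law (0.35 per decade, 3.45) within the noise, and the LOD back-projects the
blank decision level through that line. Every result type has an
`autoplot()` method (`autoplot(res$report)` draws the ROC curves,
`autoplot(cal)` the calibration line) and `tidy()`/`glance()` accessors.

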