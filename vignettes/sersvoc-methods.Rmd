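---
title: "Methods: synthetic SERS aldehyde discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic SERS aldehyde discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sersvoc)
```

## The measurement model

The package analyses SERS spectra of gaseous aldehydes captured on a
4-aminothiophenol (4-ATP) functionalized plasmonic substrate. The capture
chemistry is a Schiff-base condensation: the aldehyde's –CHO group reacts
with the amine of 4-ATP to form an imine, whose C=N stretch appears near
1625 cm⁻¹. Three consequences shape the whole analysis:

1. **Every class shares most of its spectrum.** The 4-ATP reporter bands at
   1141, 1179 and 1593 cm⁻¹ are analyte-independent, so class information is
   confined to the C=N / C–C region (roughly 1545–1660 cm⁻¹) plus weak,
   erratic structure in 1100–1500 cm⁻¹.
2. **Absolute intensities are unreliable.** Laser power, focus and hot-spot
   occupancy drift between acquisitions. A phenylacetylene internal standard
   (IS) — its alkyne band at 1985 cm⁻¹ sits in the Raman-silent region where
   nothing else absorbs — provides a per-spectrum intensity reference, and
   quantification uses the ratio *I*₁₆₂₅/*I*₁₉₈₅ rather than *I*₁₆₂₅.
3. **Adsorption follows a log-linear dose response.** Over the working
   decades (10⁻⁸–10⁻⁴ v/v) the expected ratio is modelled as
   `k·log10(c) + b`, clipped at zero.

## The synthetic-data generator

No experimental spectra are distributed with the package, so a generator
produces datasets with the statistical structure the analysis assumes. Each
spectrum on the 1000–2300 cm⁻¹ axis (648 points) is

> baseline(x) + Σ library peaks (jittered centers) + Σ misc peaks + noise

with Lorentzian line shapes by default (the natural Raman profile;
Gaussian available), FWHM 10 cm⁻¹, a gentle quadratic baseline, per-peak
center jitter `N(0, σ_c)`, a Poisson number of "erratic miscellaneous"
Lorentzians placed uniformly in 1100–1500 cm⁻¹ (the region where real
replicate spectra vary most), and white noise.

Two presets emulate the two acquisition regimes studied:

| parameter | easy (ppb-like) | hard (ppt-like) |
|---|---|---|
| center jitter σ_c (cm⁻¹) | 1 | 4 |
| noise SD (fraction of IS amplitude) | 1 % | 10 % |
| misc peaks per spectrum (mean) | 1 | 5 |

No per-spectrum noise statistics or line widths are published for this kind
of measurement, so the preset values are package conventions chosen to make
the easy regime nearly separable and the hard regime distinctly degraded but
far above chance — the qualitative behaviour the two experimental regimes
display.

**Response calibration.** Peak amplitudes must be chosen so that the
*measured* ratio (windowed maximum minus edge baseline, see below) follows
the configured law, not merely the planted amplitudes. Because the measured
window intensity is affine in the characteristic-peak scale, the generator
solves that affine relation exactly from two deterministic evaluations; in
the noiseless, jitter-free limit the measured ratio equals
`k·log10(c) + b` to ~10⁻⁶ relative, so calibration-recovery tests exercise
the fitting code rather than peak-overlap bias. Defaults `k = 0.35` per
decade and `b = 3.45` give a ratio of 1.0 at 100 ppb and stay positive over
the five calibrated decades; they were fixed once when the generator was
designed. Center jitter attenuates the measured windowed maximum by about
0.3 % at σ_c = 1 cm⁻¹ (the observed grid/jitter attenuation), which is far
below the replicate noise.

**Class archetypes.** The strongest concentration-dependent band per class
is formaldehyde 1585, benzaldehyde 1574, oxalaldehyde 1632, glutaraldehyde
1627, salicylaldehyde 1610 and 4-nitrobenzaldehyde 1652 cm⁻¹. Relative
amplitudes within a class are a design choice (experimental intensity
tables are not available): benzaldehyde's C–C band is set slightly stronger
than its C=N band, a partial-conversion regime, which keeps the six
archetype positions mutually distinct; the closest pair (1627 vs 1632 cm⁻¹)
is what limits hard-preset accuracy, and the confusion matrices show
exactly that pair collapsing first.

**Randomness.** Every spectrum draws from its own RNG substream spawned
from the root seed, so per-class counts can change without perturbing other
classes' draws, and identical `(config, seed)` reproduce datasets
bit-identically.

What the generator does **not** emulate: correlated (1/f) noise, detector
saturation and cosmic-ray spikes, slowly varying instrument response,
competitive adsorption between analytes, and class-specific fine structure
in 1100–1500 cm⁻¹ (the misc peaks there are random, hence uninformative by
construction). Passing tests therefore demonstrate the pipeline's
correctness and its behaviour under the modelled degradations — not
field performance on real spectra.

## Quantification

`peak_intensity()` takes the maximum intensity in a ±10 cm⁻¹ window and
subtracts the straight line through the window's two edge points, flooring
at zero. The window width is a package choice (nothing narrower than the
band spacing, wider than the jitter); the local edge-line removes any
linear background exactly, which is adequate for the generator's ≤2nd-degree
baselines and avoids committing to a global baseline model. Whether
experimental practice uses raw maxima or baseline-subtracted maxima is not
documented; the subtracted form is the conservative choice because it makes
the ratio invariant to both multiplicative drift and additive offsets
(both properties are tested).

`fit_calibration()` is ordinary least squares of ratio on log₁₀(c) via
`stats::lm` — base 10 because the calibration series is decade-spaced.
`estimate_lod()` back-projects `blank_mean + 3·blank_sd` through the line:
the "signal-to-noise 3:1" convention operationalized through the blank
ratio distribution, since no further operational detail is available. The
LOD is flagged with a warning when it reaches the top of the calibrated
range (a sign the calibration cannot see the blank level at all).

## Featurization

The axis is divided into 12 sections at the interior edges 1030, 1152,
1174, 1195, 1280, 1350, 1410, 1450, 1522, 1545 and 1800 cm⁻¹, and the
feature is the Raman shift of each band's intensity maximum — positions,
not intensities, which makes the features invariant to intensity scaling
and additive offsets (tested properties). Three conventions the edge
listing leaves open are fixed and tested rather than debated: intervals
are half-open `[lower, upper)` with the final band closed at 2300; argmax
ties break toward the lowest shift; and the classifier consumes
band-relative positions min–max scaled to [0, 1] (absolute positions are
available via `normalize = FALSE`).

## The classifier

A 12 → 6 → 6 fully connected network with a softmax output trained by
full-batch gradient descent on mean categorical cross-entropy. The
published description ("nonlinear softmax activation") is ambiguous about
the hidden layer — softmax *within* a hidden layer of the same width is
unusual — so the hidden activation defaults to the logistic sigmoid with
`tanh`/`relu` switches. No optimizer, batch size, learning rate or epoch
count is published; the package uses deterministic full-batch descent
(learning rate 0.5, 5000 epochs) because it is reproducible, fast at this
scale (540 × 12 inputs), and order-invariant — permuting training rows
leaves the trajectory unchanged, which is tested.

Numerical choices: Glorot-style uniform initialization with zero biases;
softmax with max subtraction; cross-entropy with a 10⁻¹² probability
floor; inputs z-scored inside `mlp_train()` using training-set statistics
stored in the model (band-relative positions occupy narrow slices of
[0, 1], and standardization spares the optimizer the job of inflating
first-layer weights). Backpropagated gradients are verified against
central finite differences (step 10⁻⁵, relative error ≤ 10⁻⁶).

The 540/108 split is stratified per class with largest-remainder rounding.
"Randomly separated" is all that is documented; stratification is declared
as a package choice so per-class test counts (18 each) are exact.

## Evaluation

Row-normalized confusion matrices report per-class *recall* on the
diagonal (the natural reading of "prediction accuracy per class"; whether
precision was meant instead is not documented). ROC curves sweep the
unique score thresholds; AUC is trapezoidal and equals the Mann–Whitney
pair statistic with half credit for ties (an exact equality, tested
against brute-force pair counting, and cross-checked once against pROC).
Macro AUC is the unweighted mean of the six one-vs-rest AUCs; micro AUC
pools all (probability, indicator) pairs. PCA runs on the raw centered
intensities over the full axis via `stats::prcomp`, with each component
oriented so its largest-magnitude loading is positive (a reproducible sign
convention); test oracles use an independent eigendecomposition of the
covariance matrix.

On the default synthetic conditions the easy preset reaches ≥ 0.95
held-out accuracy and the hard preset lands near 0.8 — the same
qualitative ordering as the two experimental regimes — while PCA leaves
the classes heavily overlapped, which is why the supervised network is
needed at all. The headline experimental accuracies themselves depend on
the undeposited laboratory spectra and are not reproduction targets.

## Transport models

`solve_fick_1d()` integrates ∂c/∂t = Dₐ ∂²c/∂x² with the explicit FTCS
scheme, enforcing the stability bound Dₐ·Δt/Δx² ≤ ½ (the error message
reports the admissible Δt). Closed boundaries are reflecting and conserve
trapezoidal mass to round-off; the "inlet" mode holds c = c₀ at x = 0 for
an injection period and 0 afterwards (carrier purge) with a zero-gradient
outlet, mimicking flow-through exposure. The multiphysics geometry behind
the published retention comparison is not available, so this is a
transparent 1D abstraction: the package's default comparison uses a 1 cm
path, a 60 s injection observed at 120 s, and a 100 : 1 diffusivity
contrast (10⁻⁶ vs 10⁻⁸ m²/s) for open vs MOF-confined transport — no
diffusivities are published, only the ordering, and the ordering (slower
diffusivity retains more) is what the tests assert. Accuracy is verified
against the spreading-Gaussian heat-kernel solution (relative L2 ≤ 10⁻³
at 401 grid points) with the expected second-order error reduction under
grid refinement.

`penetration_depth()` implements Z = (λ/2π)·√((ε′ₘ − ε′_Ag)/ε′_Ag²). The
printed form of this expression ends in a trailing "/2" where an exponent
½ clearly belongs (the standard evanescent-decay form); the square-root
reading is implemented and documented here. The silver permittivity at
633 nm is not printed anywhere; tests therefore assert the inequality
Z(ε′ = 1.34) > Z(ε′ = 1.0003) across the plausible range ε′_Ag ∈ (−40, −2)
instead of a point value, and the worked examples use ε′_Ag = −18, a
typical red-excitation literature value.

## Problem sizes and runtime

The test suite and `scripts/acceptance.R` use the full study geometry
(648 spectra of 648 points, 540/108 split, 5000 training epochs) for the
pipeline checks; Monte-Carlo style checks use 100–200 replicates; the
diffusion oracle uses 401 grid points. The complete suite runs in under
two minutes on one CPU, and the acceptance script in about one.

## Known limitations

* Feature extraction reduces each band to a single argmax position; peak
  shape, width and secondary peaks within a band are discarded, exactly as
  in the 12-input network design. Classes whose strongest bands fall within
  the jitter scale of each other are irreducibly confusable under this
  featurization.
* The LOD depends on the generator's blank behaviour; with the edge-line
  baseline the blank ratio is near zero, so synthetic LODs are more
  optimistic than experimental ones.
* The diffusion model is 1D with idealized boundaries; it reproduces the
  retention *ordering*, not absolute retained concentrations.
* `read_spectrum()` supports the package's CSV dialect only; vendor Raman
  formats are out of scope.
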