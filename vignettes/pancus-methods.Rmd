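---
title: "pancus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pancus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancus)
```

`pancus` implements a complete, testable pipeline for two linked problems
in pediatric pancreatic ultrasound: (i) screening morphology and texture
features of the masked pancreas on B-mode images as candidate biomarkers
of diabetes status, and (ii) patient-geometry-informed thermal simulation
of therapeutic ultrasound (TUS) exposure of the pancreas with CEM43
dosimetry. Because clinical image repositories of this kind are not
openly available, the package ships a seeded synthetic cohort generator
with the statistical structure the analysis assumes; every downstream
stage is exercised against it.

## The synthetic phantom model

A phantom is a B-mode-like scene: envelope-detected speckle, log
compressed and quantised to 8 bits, containing a single simply-connected
pancreas-shaped region (an ellipse with a low-order Fourier boundary
perturbation, which guarantees well-defined perimeter and eccentricity).

The speckle primitive is the magnitude of a complex circular-Gaussian
field whose real and imaginary parts are smoothed with a Gaussian kernel
of standard deviation `correlationLength` pixels. Two properties drive
the design:

* With no smoothing the per-pixel envelope is exactly Rayleigh, so the
  generator has an analytic single-pixel distribution that the tests
  verify by Monte Carlo (`mean/sd = sqrt(pi/2)/sqrt(2 - pi/2)`).
* Smoothing lengthens the *spatial* correlation of the speckle — which
  moves the co-occurrence and local-binary-pattern uniformity features —
  while leaving the amplitude histogram invariant (a smoothed complex
  Gaussian is still complex Gaussian). First-order features such as
  intensity entropy therefore cannot respond to smoothing alone. To let
  the diabetic class present the lower-entropy, more homogeneous texture
  expected from fibro-fatty replacement of parenchyma, the in-region
  speckle optionally carries a *coherent* (specular) component:
  `|c + x + iy|` with `c = coherentAmplitude` standard deviations of the
  diffuse field. This makes the envelope Rician; the relative amplitude
  spread shrinks with the coherent fraction, lowering intensity entropy
  and the GLCM marginal entropies while raising uniformity.

Class defaults (`phantomSpec()`), all configurable and all flagged as
package choices rather than literature values where no published value
exists:

| parameter | non-DM | DM | rationale |
|---|---|---|---|
| image, spacing | 160 x 160 px, 0.5 mm/px | same | 8 x 8 cm abdominal field |
| area (mm^2) | 1300 (sd 160) | 0.8 x (sd 160) | diabetic volume loss |
| centroid depth (cm) | 4.5 (sd 0.45) | 4.0 (sd 0.45) | shallower centroid in DM |
| aspect ratio | 1.6 (sd 0.2) | 1.9 (sd 0.2) | higher width/height in DM |
| texture smoothing | 1.0 | 1.5 | longer speckle correlation in DM |
| coherent amplitude | 0 | 2.5 | Rician homogenisation in DM |

With these defaults and 40 phantoms per class, the sign of the group
mean difference for the eight encoded features (area, intensity entropy,
LBP energy, Haralick angular second moment, inverse difference moment,
entropy, sum entropy, aspect ratio) is recovered in at least 95% of
replicate cohorts; with all class effects zeroed, the phantom classes
are exchangeable and the downstream t-test gate retains about 5% of
features at `alpha = 0.05`. Both properties are asserted by the test
suite (200 effect-free replicate cohorts of 8 + 8 small phantoms for
calibration; 20 default cohorts of 40 + 40 for direction recovery —
problem sizes chosen to keep the checks statistically meaningful while
remaining desk-scale).

What the phantoms do **not** emulate: a realistic point-spread function
(no anisotropic lateral/axial resolution, no scan-line geometry),
attenuation shadowing, depth-dependent gain, refraction artefacts, or
head/body/tail substructure. Passing tests therefore demonstrate that
the *pipeline* is correct and calibrated, not that the effect sizes
transfer to clinical images.

Layered abdominal geometries (`generateTissueStack()`) sample truncated
normal layer thicknesses for skin, muscle, bowel and blood proximal to
the pancreas and rescale the soft-tissue layers so the pancreas proximal
boundary always lies in the requested 2-6 cm window, the depth span seen
across pancreatic imaging windows.

## Image handling conventions

Pixels are used at native 8-bit depth; no histogram equalisation.
Indices are 0-based with row 0 at the transducer/dermis face, so depth
increases with the row index and the depth of a masked region is its
centroid row times the pixel spacing. Polygon annotations rasterise by
the even-odd rule applied to pixel centres — reproducible and matching
common annotation-tool semantics. Isotropic spacing is assumed. Masked
statistics exclude outside-mask pixels; they are never zero-filled
(zero-filling would corrupt histogram features), although a zeroed copy
is available for display. 16-bit sources are min-max rescaled to 0-255
with a warning. A minimal reader for single-frame uncompressed
little-endian DICOM (PixelData, PixelSpacing) is included; PNG/TIFF
require an explicit `spacingOverride`.

## Texture feature conventions

Haralick values differ between libraries mainly through quantisation and
angle handling, so the package fixes one convention and documents it:

* **GLCM**: in-mask intensities min-max quantised to 32 levels; distance
  1; the four offsets 0/45/90/135 degrees *accumulated* (not averaged
  per angle), then symmetrised by adding the transpose and normalised.
  Pairs are counted only when **both** endpoints are in-mask, so
  boundary pixels never contaminate the statistics.
* **Logarithms** are base 2 everywhere (entropies in bits);
  `0 log 0 := 0`. IMC2 keeps its conventional `sqrt(1 - exp(-2 dH))`
  form.
* **LBP**: rotation-invariant uniform mapping, P = 8, R = 1, bilinear
  interpolation for the diagonal samples, computed for pixels whose full
  square neighbourhood is in-mask; a small tolerance (1e-7 gray levels)
  makes exact ties compare as "greater or equal" despite interpolation
  round-off.
* **Gradient**: Sobel kernels normalised so a unit-slope ramp yields
  magnitude 1 gray/px, averaged over interior in-mask pixels.
* **Keypoints**: a compact difference-of-Gaussians detector (base sigma
  1.6, 3 intervals/octave, contrast threshold 0.03 on unit-scaled
  intensities, edge ratio 10), counting scale-space extrema inside the
  mask. Deterministic; no subpixel refinement or descriptors.
* **Degenerate regions** (constant texture) yield documented limit
  values — ASM = IDM = LBP energy = 1, entropies = contrast = 0 — with a
  flag, so cohort tables stay rectangular instead of erroring.
* **Perimeter** is the polygonal length of the marching-squares
  0.5-level contour of the Gaussian-smoothed (sigma = 1 px) mask
  indicator. The smoothing gives sub-pixel edge crossings; a digitised
  circle of radius 20 px recovers its circumference within 3%, where the
  binary-mask contour alone is biased by about 10%.

Centroids are emitted in physical units (cm) as the canonical features,
with pixel-unit values attached as attributes; screening uses the
physical values. Features can be computed per anatomical sub-region or
per whole-pancreas mask — the mask's `regionLabel` carries the choice
and the pipeline does not force one.

## Biomarker screening

The screening framework is deliberately univariate:

* **Gate**: pooled-variance Student t-test per feature,
  `df = n1 + n2 - 2` (a balanced 24 + 24 sample gives df = 46), with
  strict retention `p < alpha`. No multiple-testing correction is
  applied by default, matching the descriptive screening design;
  `stats::p.adjust` can be applied downstream.
* **Association**: Spearman rank correlation against the binary label
  (midranks; two-sided p by the t approximation), `-log10(p)` ranking
  with a cap at 300 for exact zeros, and mutual information between the
  continuous feature and the discrete label by the k-nearest-neighbour
  estimator (k = 3), in nats, clipped at zero. The MI estimator choice
  is exposed because different estimator families scale differently.
* **Effect size**: `|mean(DM) - mean(non-DM)|` divided by the feature's
  observed range, partitioned by sign. The area feature can be excluded
  from this ranking, since its scale otherwise dominates the display.
* **Discrimination**: a single-predictor unregularised logistic model on
  the z-scored feature, with discrimination summarised by the
  tie-corrected Mann-Whitney AUC of the feature in its *ascending
  orientation*. The AUC is never sign-flipped, so values below 0.5 are
  reported as such — this is documented prominently because most ROC
  libraries flip by default. Confidence intervals are percentile
  intervals (2.5/97.5) from a stratified bootstrap (default 2000
  resamples within each class at the original class sizes). Each
  replicate recomputes the rank AUC of the resample; for a monotone
  single-predictor model scored in ascending orientation this equals the
  AUC of a refitted model, so the refit is skipped inside the loop.
  Coverage of the interval against the known large-sample AUC on
  synthetic cohorts is 90-99%, asserted over 200 replicates.

All randomness flows through explicit integer seeds; per-feature and
per-phantom seeds derive from a master seed by integer mixing, so any
artifact can be regenerated in isolation.

## Therapeutic ultrasound thermal model

The acoustic model is linear and axisymmetric. Attenuation coefficients
are amplitude values in dB/cm at 1 MHz, linear in frequency (the
convention matters: heating scales directly with it). The on-axis field
is the plane-piston approximation for the unfocused 1.5 cm aperture and
the O'Neil closed form for the spherically curved radiator (focal depths
2-8 cm); the radial profile is a Gaussian whose width at each plane
conserves transmitted beam power, capped at the aperture radius where
near-field nulls would inflate it. At 1 MHz this aperture is only weakly
focusing (focal gain `k h ~ 2.9`), so pre-focal near-field maxima can
exceed the focal value — an O'Neil property, not a bug; the focusing
contract test therefore runs at 3 MHz. Because the near-field intensity
oscillates on a sub-millimetre scale, the solvers deposit the
*cell-averaged* source (10 sub-samples per axial cell), which makes the
deposited power mesh-independent.

Heat transport is the Pennes equation,
`rho c dT/dt = div(k grad T) - w_b c_blood (T - 37) + q` with
`q = 2 alpha I x duty`, solved by an explicit conservative
finite-difference scheme on an (r, z) mesh (default 0.5 mm spacing, 4 cm
radial extent, stack-depth axial extent), harmonic-mean interface
conductivities in z, the symmetric `4k/dr^2` stencil on the axis, fixed
37 C initial and boundary conditions (an insulated option exists for
energy-balance checks), and an auto-computed stable time step (safety
factor 0.8; unstable requests are reduced with a warning). Duty gating
is time-averaged by default — valid when the 1 s pulse period is far
below the thermal time constant — with explicit on/off gating available;
the two deposit identical energy by construction. Perfusion defaults to
zero because blood is modelled as an explicit layer; thermal
conductivities (skin 0.37, muscle 0.49, bowel 0.55, blood 0.52, pancreas
0.51 W/m/K) are literature placeholders outside the acoustic property
table. An independent reference solver — a separately written
finite-volume face-flux formulation on a mesh of half the spacing —
cross-validates the main solver; on the default five-layer stack
(skin 0.2, muscle 1.3, bowel 2.0, blood 0.5, pancreas 2.5 cm, total
6.5 cm, inside the 7 cm axial cap used for cross-validation) the
on-axis temperature series agree to well under 0.4 C RMSE, and both
match the lumped-heating closed form with conduction disabled.

Thermal dose is Sapareto-Dewey CEM43 (`R = 0.5` at or above 43 C, 0.25
below), accumulated piecewise over stored snapshots (1 s frame interval
by default). Safety verdicts compare per-tissue maxima against CEM43 <
240 equivalent minutes and pancreatic peak < 40 C, and advisory-flag
duty factors of 75% or more. A reported bound of "maximum abdominal
temperature < 135 C" in the surrounding literature is physiologically
implausible and treated as a typographical artefact; it is not enforced.

### A deliberate, documented safety finding

Under this model and the default geometry, the protocol sweep
(1/5/10 W/cm^2, duty 10-75%, 1-5 min, focused at 4 cm where the
pancreas begins) produces pancreatic peaks far above the 40 C
stimulation-safety bound at the higher intensities — the worst cell
reaches about 104 C. This is the genuine prediction of
`q = 2 alpha I` with the tabulated pancreatic attenuation (0.829 dB/cm)
and no perfusion: a surface intensity of 10 W/cm^2 at 75% duty deposits
megawatts per cubic metre at the focus, and a quasi-steady line-source
estimate (`dT ~ q_l / (4 pi k) x log(4 alpha t / sigma^2)`) confirms the
order of magnitude independently of the solver. The package reports
these protocols as unsafe rather than reproducing published claims that
all sub-100%-duty protocols stay below 40 C; those claims would require
roughly thirty-fold less absorbed power than the stated tissue
properties and intensities imply, or strong cooling mechanisms absent
from the stated model. The published comparison that superficial
(dermal/muscle) tissue out-heats the pancreas does hold here for the
*unfocused* configuration, where it was originally made; a focused beam
aimed at the pancreas reverses it, which is why the direction test uses
the unfocused transducer.

## Known limitations

* Linear acoustics only: no nonlinear propagation, cavitation or
  mechanical index; the Gaussian radial envelope ignores side lobes.
* The phantom cohort validates pipeline correctness and calibration,
  not clinical effect sizes; headline statistics from patient data
  (Spearman rho near -0.6, MI near 0.3, AUCs near 0.8) are not
  reproducible without those images and are not asserted anywhere.
* Within-class variance of the phantom texture features comes only from
  speckle sampling noise, which is small over thousands of in-region
  pixels; phantom cohorts therefore separate far more cleanly (AUCs near
  0 or 1) than clinical cohorts would. The generator's spread parameters
  act on geometry (area, depth, aspect), not on texture.
* The kNN mutual-information estimate is biased at small n and depends
  on k; values should be compared within an analysis, not across
  estimators.
* Single-frame, isotropic-spacing imaging only; anisotropic DICOM
  spacing would require using row spacing for depth and flagging
  aspect-ratio features, which is left to the caller.
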