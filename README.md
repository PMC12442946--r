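# pancus

Quantitative imaging biomarkers of the pediatric pancreas from B-mode
ultrasound, and thermal planning of therapeutic ultrasound (TUS)
exposure — in one tested R package.

## What it does

**Problem.** The diabetic pancreas shows subtle morphological and
textural change on imaging (volume loss, fibro-fatty homogenisation)
that trained radiologists cannot reliably see on B-mode ultrasound.
Quantitative features of the masked pancreas — morphology, gray-level
co-occurrence (GLCM/Haralick) texture, local binary patterns (LBP),
intensity entropy, gradients, scale-space keypoints — can be screened
statistically as candidate biomarkers of diabetes-mellitus (DM) status.
The same images describe the layered abdominal geometry a therapeutic
beam must traverse, which makes patient-informed thermal simulation of
TUS insulin-release protocols possible.

**Feature screening.** For each feature `x` with class labels
`y in {DM, non-DM}`:

* pooled two-sample Student *t* gate (`df = n1 + n2 - 2`), retaining
  features with `p < 0.05`;
* Spearman rank correlation rho(x, y), `-log10 p`, and mutual
  information I(x; y) by the k-nearest-neighbour estimator (k = 3,
  nats);
* range-adjusted absolute mean difference
  `|mean_DM - mean_nonDM| / range(x)`;
* discrimination by the tie-corrected Mann–Whitney AUC of `x` in
  ascending orientation (never sign-flipped, so AUC < 0.5 is
  reportable), with a 95% percentile CI from a stratified bootstrap
  (2,000 resamples preserving class proportions), alongside a
  single-predictor logistic fit on the z-scored feature.

**Thermal simulation.** Axial intensity through a layered tissue stack
(O'Neil on-axis form for a focused spherical cap, plane-piston for the
unfocused aperture, amplitude attenuation in dB/cm linear in frequency),
heat source `q = 2 alpha I x duty`, and the Pennes bioheat equation
solved by an explicit conservative finite-difference scheme on an
axisymmetric (r, z) mesh, with Sapareto–Dewey CEM43 dosimetry
(`R = 0.5` above 43 °C, 0.25 below) and safety verdicts (CEM43 < 240
equivalent minutes, pancreatic peak < 40 °C, duty >= 75% advisory
flag). An independently written fine-grid finite-volume reference
solver cross-validates the thermal output (RMSE of the on-axis
temperature series).

**Synthetic cohorts.** Patient images of this kind are not openly
deposited, so the package includes a seeded phantom generator:
speckle-textured scenes (Rayleigh envelope, optionally Rician inside
the pancreas region) with a pancreas-shaped blob whose texture
uniformity, entropy, size, depth and aspect ratio differ by class in
the documented directions. Everything downstream is exercised on these
phantoms; see the methods vignette (`vignettes/pancus-methods.Rmd`) for
what that does and does not demonstrate.

## Worked example

```r
library(pancus)

co <- generateCohort(cohortSpec(11, 11, masterSeed = 2024))
ft <- cohortFeatureTable(co)
sc <- screenFeatures(ft, alpha = 0.05)
head(sc[order(sc$p_value),
        c("feature", "t_value", "p_value", "spearman_rho", "retained")], 3)
#>               feature t_value  p_value spearman_rho retained
#>           lbp_entropy   -72.9 9.66e-26       -0.867     TRUE
#>  haralick_correlation    65.7 7.58e-25        0.867     TRUE
#>            lbp_energy    65.1 9.27e-25        0.867     TRUE

aucTable(ft, features = c("lbp_energy", "intensity_entropy", "centroid_x"),
         nBoot = 2000, seed = 7)
#>            feature   auc ci_low ci_high n_boot
#>         lbp_energy 1.000  1.000   1.000   2000
#>  intensity_entropy 0.000  0.000   0.000   2000
#>         centroid_x 0.488  0.256   0.736   2000
```

LBP energy is higher in the DM phantoms (AUC 1 on this clean synthetic
cohort), intensity entropy lower (AUC 0 — the ascending orientation is
never flipped), and the laterally uninformative centroid-x sits at
chance with a wide interval. On the thermal side:

```r
st  <- defaultTissueStack()                       # skin..pancreas, 6.5 cm
td  <- transducerSpec("focused", focalDepth = 4)  # 1.5 cm aperture, 1 MHz
fld <- solveBioheat(st, td, sonicationProtocol(intensity = 5,
                                               dutyFactor = 0.5,
                                               duration = 3))
rep <- safetyReport(thermalDose(fld), fld, st,
                    protocol = sonicationProtocol(5, 0.5, 3))
rep$perTissue
#>    tissue max_T max_cem43
#>      skin 48.23   48.5168
#>    muscle 51.31  229.3805
#>     bowel 41.91    0.1475
#>     blood 50.32  123.1433
#>  pancreas 56.46 6906.9192
rep$pass
#> [1] FALSE
```

Three minutes of 5 W/cm² at 50% duty focused at the pancreas proximal
boundary already exceeds the CEM43 damage threshold in this model — the
safety report exists precisely to flag such protocols (see the vignette
for the full analysis of why this model predicts hotter pancreata than
earlier simulation reports).

`runPipeline(runConfig(...))` orchestrates the whole chain (cohort →
features → screening → protocol sweep) into CSV/JSON artifacts, advisory
figures and a seeded, hashed manifest.

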