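# locfuse

Analysis of two-dimensional open-loop localization of visual (V), auditory
(A) and bimodal visual-auditory (VA) targets, for psychophysicists studying
multisensory spatial integration.

When observers point at remembered targets scattered over the frontal
field, each modality leaves a distinct signature in the response
distributions: auditory scatter is elongated vertically and compressed
toward a raised auditory horizon, visual scatter is elongated radially and
undershoots the target (foveal bias). `locfuse` estimates these per-target
bivariate response fields, summarizes their precision (variable error,
confidence-ellipse geometry, anisotropy) and accuracy (constant-error
vectors, distortion grids, a global affine target→endpoint map), and tests
the maximum-likelihood account of cue combination: for independent Gaussian
cues the optimal bimodal estimate is the reliability-weighted average

    σ²_VA = σ²_V σ²_A / (σ²_V + σ²_A) ≤ min(σ²_V, σ²_A)
    W_V   = (1/σ²_V) / (1/σ²_V + 1/σ²_A),   r̂_VA = W_V r̂_V + W_A r̂_A

with the full-covariance form `Σ_VA = (Σ_V⁻¹ + Σ_A⁻¹)⁻¹` target by target.
Multisensory improvement is quantified by the redundancy gain
`RG = 100 (ve_uni − ve_bi)/ve_uni`, inverse effectiveness (correlation of
gain with best-unimodal reliability), visual weights, and hierarchical
regressions of bimodal on unimodal precision. A calibrated synthetic
generator produces trial-level datasets with this field structure,
including exact-MLE bimodal data as the reference null.

## Worked example

Simulate a full study (10 subjects × 3 conditions × 35 targets × 10
repetitions), fit the localization fields, and predict the bimodal
condition from the unimodal ones:

```r
library(locfuse)

dat <- simulate_responses(seed = 42)     # 10,500 trials
fit <- locfield(dat)                     # screen outliers, fit every cell
fit
#> Localization field fit
#>   3 modalities (A, V, VA), 35 targets (25 retained), 10 subjects
#>   A   mean VE  5.56 deg, mean CE  4.29 deg
#>   V   mean VE  1.76 deg, mean CE  2.07 deg
#>   VA  mean VE  1.49 deg, mean CE  1.65 deg
#>   outlier screen removed 0.00% of trials

summary(fit, prediction = predict(fit))
#> Localization performance over 25 retained targets (per-subject-then-mean statistics)
#>                                          A             V            VA           MLE
#> Variable error (deg)            5.56 (0.30)   1.76 (0.19)   1.49 (0.12)   1.56 (0.13)
#> Constant error (deg)            4.29 (2.41)   2.07 (0.96)   1.65 (0.76)   1.71 (0.78)
#> Orientation deviation (deg)   44.49 (27.48)   3.57 (1.58)   5.26 (3.98)   5.39 (3.80)
#> Direction deviation (deg)     43.70 (25.74)   1.65 (1.82)   4.31 (3.71)   4.79 (3.51)
```

Reading the table: auditory pointing is about three times less precise and
less accurate than visual pointing; the bimodal condition is more precise
than the better unimodal one (1.49° ≤ 1.76° < 5.56°), and the MLE column —
computed purely from the A and V fits — predicts that improvement. Auditory
ellipses are oriented ~45° away from the target direction on average
(vertical scatter), visual ellipses are nearly aligned with it (radial
scatter).

```r
integration_report(fit)
#> Multisensory integration report
#>   redundancy gain: observed 14.24%, predicted 12.41% (best unimodal: V)
#>   inverse effectiveness (RG vs best VE): r = 0.660 (p = 0.000332); model: r = 0.672 (p = 0.000231)
#>   visual weight: azimuth 0.701, elevation 0.947 (range 0.53-0.98)
#>   weight-accuracy correlation (W_V vs CE_VA): r = 0.120 (p = 0.568)
#>   observed vs predicted precision: mean diff -0.0365 deg, t = -1.58, p = 0.127
#>   ...
```

The observed gain (14.2% dispersion reduction over vision) sits near the
model prediction (12.4%), the gain is largest where vision is least
reliable (inverse effectiveness, r ≈ 0.66), vision carries more weight on
the elevation axis than on azimuth, and the observed bimodal precision does
not differ significantly from the MLE prediction — as expected, since the
simulated bimodal data embody exact MLE integration.

Everything above is also available as one call writing a complete artifact
bundle (per-target tables, summary table, integration report, removal
accounting, affine maps, distortion edges, optional plots):

```r
run_pipeline(seed = 42, out_dir = "out", plots = TRUE)
```

or from the shell via the thin wrapper `inst/cli/locfuse`
(`simulate`, `analyze`, `all` subcommands).

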