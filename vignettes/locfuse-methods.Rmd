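---
title: "Localization fields and maximum-likelihood cue fusion: models and methods"
author: "locfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localization fields and maximum-likelihood cue fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locfuse)
```

## The problem

When an observer points, without feedback, at a briefly presented visual
(V), auditory (A), or combined visual-auditory (VA) target somewhere in the
two-dimensional frontal field, the scatter and bias of the repeated
responses carry two distinct signals. *Precision* — the variable error, VE —
is the dispersion of responses around their own centroid; *accuracy* — the
constant error, CE — is the displacement of that centroid from the true
target. Both vary strongly with modality, azimuth, and elevation: auditory
responses scatter mostly in elevation, visual responses scatter along the
target direction and undershoot it, and so on. The maximum-likelihood
estimation (MLE) account of cue combination predicts the bimodal field from
the two unimodal fields, and this package implements that whole chain:
per-target distribution estimation, ellipse and error-vector geometry,
MLE fusion, and integration metrics, plus a calibrated generator of
synthetic trial data for testing the chain end to end.

Coordinates are degrees of azimuth (positive rightward) and elevation
(positive upward) about the fixation point, treated as planar Euclidean
coordinates — adequate over the ±30° × ±20° field analysed here, and the
convention under which all downstream algebra (covariances, affine maps) is
exact.

## Per-target response distributions

For each subject × modality × target cell, responses are first screened by
the conventional ±3 SD rule: a trial is discarded when it lies more than
`k = 3` sample standard deviations from the cell mean on either axis, in a
single pass with mean and SD taken from the unscreened cell. Two properties
of this rule deserve attention:

* On clean bivariate normal data and large cells the expected removal is
  `1 - (1 - 2 pnorm(-3))^2` ≈ 0.54% (either-axis exceedance).
* In a cell of `n` trials the largest achievable deviation score is
  `(n - 1) / sqrt(n)` SDs — 2.85 at `n = 10` — because a gross outlier
  inflates the very SD it is tested against. A single contaminated trial in
  a 10-repetition cell therefore *cannot* be flagged at `k = 3`, whatever
  its amplitude; the screen only bites for cells of about 12 trials or
  more. This masking arithmetic motivated two package choices: cells with
  fewer than 3 trials are passed through untouched and flagged, and the
  calibrated generator defaults carry no contamination (below).

A Mahalanobis-distance variant of the screen was considered and not
adopted; the per-axis rule matches the "±3 SD on each coordinate" reading
and keeps the removal accounting transparent. It remains single-pass by
design: iterating the rule would change the nominal clean-data removal rate.

The screened responses in a cell give unbiased (n−1) sample moments: the
centroid `(mu_x, mu_y)`, variances, covariance and correlation. The 2D
variance is the trace `var_total = var_x + var_y`, and the VE is its square
root, in degrees — so a tabulated VE of 5.7° is a dispersion, not a
variance. Summary statistics are reported in two conventions: per subject
and then averaged over subjects (the default in the tabulated summaries,
matching the per-subject screening), and pooled over subjects (the default
wherever distributions feed further nonlinear computation, see *Fusion*
below).

### Ellipse geometry

The 95% confidence ellipse of a fitted cell has semi-axes
`a, b = sqrt(lambda_i * qchisq(coverage, 2))` from the covariance
eigenvalues, with the chi-square quantile on 2 df as the scaling convention.
The orientation `theta` of the major eigenvector is axial (theta and
theta + 180° identified, reported in [0, 180)); deviations between an
ellipse orientation and a target direction are folded into [0, 90°].

Anisotropy is reported as the ratio `epsilon = b/a`: 1 means circular
scatter (no preferred direction), small values mean strongly oriented
scatter. The squared-complement form `1 - (b/a)^2`, which reverses that
reading (1 = strongly oriented), circulates in the literature and is exposed
as `anisotropy_sq`, but `b/a` is the form consistent with the usual verbal
interpretation and is used throughout.

Degenerate cases are explicit rather than silent: circular covariance has
no orientation (flagged, reported 0); rank-1 covariance gives `b = 0`,
`epsilon = 0`, orientation along the data axis; the fixation target has no
direction, so direction-referenced deviations are `NA` there and excluded
from field averages.

## The accuracy field

The error vector of a cell runs from the target to the response centroid;
its length is the CE and its direction is compared with the target's own
direction in two forms: the circular deviation in [0, 180°] (180° = pure
undershoot, pointing straight back at fixation) and its fold into [0, 90°]
(undershoot and overshoot along the target axis both count as 0). Both are
emitted because the two conventions coexist in tabulated versus narrative
reports of the same data; the summary table uses the folded form and labels
it "direction deviation".

The global structure of the accuracy field is summarized by a least-squares
affine map from targets to centroids, decomposed as
rotation ∘ shear ∘ scale via QR factorization of the linear part (the
decomposition order is a convention; it is stated here and recomposes
exactly). A foveal-bias contraction appears as scales below 1 with small
rotation and shear. Local topology is checked by the distortion grid:
centroids of 4-neighbour targets are linked, per-edge length ratios
measure local compression, and a lattice cell whose response quadrilateral
has flipped orientation marks a fold-over.

## Maximum-likelihood fusion

For independent Gaussian cues the MLE of the target position given both
cues weights each cue by its reliability (reciprocal variance). In one
dimension,

$$\sigma^2_{VA} = \frac{\sigma^2_V \sigma^2_A}{\sigma^2_V + \sigma^2_A},
\qquad
W_V = \frac{1/\sigma^2_V}{1/\sigma^2_V + 1/\sigma^2_A},
\qquad
\hat r_{VA} = W_V \hat r_V + W_A \hat r_A,$$

and in two dimensions the same statement in matrix form:
`Sigma_VA = (Sigma_V^-1 + Sigma_A^-1)^-1`,
`mu_VA = Sigma_VA (Sigma_V^-1 mu_V + Sigma_A^-1 mu_A)` — the normalized
pointwise product of the two bivariate normal densities. The fused
covariance is dominated by both parents in the Loewner order, so the fused
marginal variances, trace and determinant never exceed either cue's. The
implementation is verified in the test suite against an independent
numerical oracle that multiplies the two densities on a fine quadrature
grid and takes moments (`grid_product_oracle()`), rather than against any
transcribed formula.

Scalar per-axis weights computed from the marginal variances (ignoring the
correlation) are reported alongside the full-matrix fusion because per-axis
weights are what field studies tabulate; for correlated covariances the two
routes legitimately differ, and both are exposed.

### Pooled versus per-subject fusion

Fusion of *estimated* distributions is nonlinear in the sample variances:
the harmonic combination is concave, so fusing noisy per-subject variance
estimates biases the predicted bimodal variance low — a second-order Taylor
computation puts the bias near −10% for 10-trial cells with the default
dispersions, and a calibration simulation confirms that per-subject fusion
makes observed-vs-predicted precision comparisons reject systematically
even when the data embody exact MLE integration. The package therefore
fuses the subject-pooled per-target distributions by default (about 100
trials per cell at the default design, bias ≈ 1%) and offers
`pooling = "by_subject"` for designs where subject heterogeneity matters
more than small-sample bias.

A numerically singular input covariance is regularized by `1e-8 * trace` on
the diagonal and flagged, never silently.

## Integration metrics

The redundancy gain is the relative dispersion reduction
`RG = 100 (ve_uni − ve_bi) / ve_uni`, with vision as the conventional best
unimodal reference (`best = "argmin"` switches to the per-target best).
The raw variance ratio `100 σ²_VA / σ²_V` is exposed as an alternative but
measures residual variance, not gain — applied to dispersions of 1.78° and
1.46° the reduction form gives the familiar ≈18% figure, the ratio form
≈67%. Gains are averaged per target (the gain of the average dispersions
differs slightly and is not used).

Inverse effectiveness is the product-moment correlation of per-target RG
with the best-unimodal dispersion (or variance): positive where gain
concentrates at targets with the least reliable best cue. Degenerate
(zero-variance) inputs are flagged undefined rather than propagating NaN.

The contribution of the unimodal precisions to the bimodal precision is
assessed by sequential ("enter") linear regressions with per-step R²,
R²-change F tests and variance inflation factors, and observed versus
predicted fields are compared by paired t statistics over targets. The
repeated-measures ANOVA machinery used in some reports of such designs is
deliberately out of scope; paired comparisons and correlations cover the
pipeline's comparison stage.

## The synthetic generator and its calibration

`simulate_responses()` draws every subject × modality × target × repetition
cell from the closed form `ground_truth_distribution()` implied by a
`modality_profile`: a bias field
`(g_r · az, h + g_e (el − h))` with hemifield-specific gains about a
horizon offset `h`, and a covariance field with major-axis SD
`base + slope·|az|`, minor/major ratio `q`, and orientation vertical,
radial, or isotropic. Under the default `bimodal_mode = "mle_exact"` the VA
cells are drawn from the *fused* A and V ground truths, so the synthetic
bimodal data embody exact MLE integration — the null against which the
pipeline's comparisons are calibrated. All randomness flows through
per-subject seeds derived from one base seed, so datasets are reproducible
and permuting subject seeds permutes subjects.

The default profiles were calibrated once, in closed form, against the
canonical field structure of open-loop 2D pointing (mean VE 5.73° auditory
and 1.78° visual over the central 25 targets; auditory axis ratio 0.35,
vertical everywhere; visual ratio 0.5, radial; visual undershoot gains
0.861/0.933 upper/lower hemifield, reproducing a CE near 2.0° that is about
twice as large above the horizontal meridian; auditory elevation
compression gains 0.548/0.741 about a +10° auditory horizon, reproducing a
mean CE near 4.0° that is about three times larger below the meridian).
The visual azimuth slope of 0.02 deg/deg yields the reliably observed
decline of visual precision with azimuth eccentricity while preserving the
mean VE. These closed-form choices were frozen before any end-to-end run
and are not adjusted to test outcomes.

Three things the generator deliberately does **not** emulate, which bounds
what passing tests can claim about real data: there is no between-subject
heterogeneity (all subjects share one generating field), no trial-order or
session structure, and no violation of the Gaussian cell model other than
optional symmetric outlier contamination. Real observers differ, drift,
and integrate sub- or supra-optimally; the generator provides the *exact
MLE* reference point, not a model of every departure from it.

On contamination: outliers are drawn at uniform direction with amplitude
uniform on [4, 8] local major-axis SDs. The calibrated defaults set the
contamination rate to zero, because (a) the ±3 SD screen cannot remove
within-cell outliers at 10 repetitions (the masking bound above), so
contamination would simply inflate every measured dispersion away from its
calibrated value, and (b) the calibration targets are post-screen
quantities. Contamination is exercised in the test suite at cell sizes
where the screen works (200-repetition recovery runs, 10⁵-draw removal-rate
checks).

## Numerical and design choices

* Chi-square(2 df) quantile for ellipse scaling; coverage a parameter,
  default 0.95.
* Orientations axial in [0, 180); ties in eigen-decomposition (circular
  covariance) flagged as undefined orientation, reported 0.
* Fusion regularization jitter `1e-8 * trace`, flagged.
* The quadrature oracle spans 6 SDs at step 0.05° by default; halving the
  step moves its moments by less than 1e-6.
* Degenerate comparisons (identical fields, zero-variance metrics) return
  flagged results, never NaN.
* Azimuth retention bound 20° by default, so direction comparisons use the
  5 × 5 core of the 7 × 5 grid.
* Problem sizes used by the test suite: study-scale runs are 10 subjects ×
  3 conditions × 35 targets × 10 repetitions (10,500 trials, about a second
  per fitted pipeline); repeated-run calibration checks use 50 and 200
  seeded replicates; recovery checks use 200 repetitions per target.

## Known limitations

* The reciprocal-variance weight band reported for such experiments
  (roughly 0.60–0.90 on both axes) is not attainable jointly with a
  5.73/1.78 dispersion ratio: the axis-summed variance ratio is 10.4, so
  the weight on the quieter axis necessarily exceeds 0.90. Published
  per-axis weights near 0.75/0.81 are instead consistent with
  reciprocal-*dispersion* (SD) weighting. The package computes the true
  MLE (reciprocal-variance) weights; users comparing against SD-weighted
  reports should expect this systematic discrepancy on the elevation axis.
* Planar geometry: no great-circle correction; adequate within ±30° but
  not for wider fields.
* No robust covariance estimation; the screen plus Gaussian moments is the
  model, and heavy-tailed cells at small n will pass through unflagged (the
  masking bound).
* No causal-inference model for spatially discrepant cues: the fusion rule
  presumes congruent stimuli perceived as one event, with a flat prior over
  positions.
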