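---
title: "Estimating 3D nodule volume from 2D probability maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 3D nodule volume from 2D probability maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Deep-learning nodule detectors for chest radiographs emit, besides a binary
call, a class-activation probability map: a per-pixel surface in [0, 1]
indicating where the network believes a nodule sits. Radiologists, however,
track nodules *volumetrically* — a lesion's change between serial films is
what drives management — and a single projection radiograph carries no direct
volume information. `camvol` implements a pragmatic bridge: summarize the
activation blob of a nodule by a handful of scalar parameters, regress
reference CT volumes on those parameters, and use the fitted model to score
interval change between serial radiographs of the same patient.

The working hypothesis is physical: a larger, denser lesion projects a larger
and more confident activation blob. The area of the supra-threshold region is
a proxy for the projected cross-section, and the mean activation inside it is
a proxy for lesion conspicuity. Neither is volume, but together they carry
enough signal for a useful regression.

## The extraction stage

An image's map is thresholded at a fixed activation cutoff of 0.2; connected
components of the mask (8-connectivity, so diagonal stair-steps merge) are
the regions of interest, ordered by descending area and capped at three per
image — matching how up to three index nodules per film are read. Five
parameters are computed per ROI:

* **area** (mm²) — pixel count × pixel area;
* **WOAP** (mm²) — the *weighted opacity–area product*, implemented as the
  integral of the probability surface over the ROI (probability-weighted
  area). It reduces to the plain area when the activation saturates at 1;
* **mean, median and maximum probability** inside the ROI.

Only area and mean probability enter the headline models; the other
parameters are computed and exported for completeness. Image-level positivity
is a separate, inclusive 15% threshold on the image score (the maximum pixel
probability stands in for the detector's own image-level output, which a map
alone does not contain).

Two boundary conventions are frozen and tested rather than left ambiguous:
the ROI mask uses a *strict* inequality (p > 0.2), so a uniform map exactly
at the cutoff yields no ROI, and image positivity uses an *inclusive* one
(score ≥ 0.15).

## The volume models

A projected area has units of mm²; a volume, mm³. If nodules were similar
solids, volume would scale as area^1.5 — this single observation motivates
the "unit-adjusted" degree-1.5 family. Three polynomial degrees are fitted,
univariable (area A only) and multivariable (A and mean probability P):

| degree | basis (multivariable) | terms |
|---|---|---|
| 1 | 1, A, P | 3 |
| 1.5 | complete cubic in (√A, √P): all (√A)^i (√P)^j, i + j ≤ 3 | 10 |
| 2 | 1, A, P, A², AP, P² | 6 |

Univariable ladders keep only the pure-area terms (2, 4 and 3 terms). The
degree-1.5 basis is the *complete* half-power cubic rather than the single
A^1.5 term: the published 10-term equation enumerates exactly these
monomials, and the frozen reproduction of that equation
(`published_model_15()`) predicts both halves of the published worked example
— 8.50 cm³ at (761.6 mm², 0.514) and 16.35 cm³ at (1079.6 mm², 0.529) — to
within printed rounding, which validates the basis reconstruction end to end.
Two term labels in the printed equation are garbled duplicates; they are
resolved as the A^1.5 and P^1.5 terms, the only members of the complete basis
not otherwise present, and the worked example confirms the resolution.

Fitting is plain least squares — no regularization, no intercept suppression,
and the comparison metric is training RMSE (mm³), because the reference
analysis performed no internal validation. Because the degree-1 basis is
nested in both higher-degree bases, training RMSE of the richer models can
never exceed the linear one; which *non-nested* variant wins (degree 1.5
vs. 2) is an empirical question, and on calibrated cohorts the 10-term
degree-1.5 multivariable model wins, mirroring the reported ordering.

**Numerical conditioning.** Basis columns span roughly ten orders of
magnitude (A^1.5 reaches 10⁵ while P^1.5 stays below 1). Columns are scaled
to unit maximum absolute value before a QR solve and coefficients are
rescaled afterwards; the contract is the exact least-squares solution, and
tests verify agreement with raw normal equations to 10⁻⁶ relative on
well-conditioned instances and exact recovery of a known degree-1.5
coefficient vector from noise-free data to 10⁻⁴ relative. Rank deficiency
after scaling raises an error naming the offending columns rather than
silently dropping them.

Predictions are *not* clamped to be non-negative by default — a cubic
extrapolated outside its calibration range can go negative, and hiding that
would mask a real failure mode — but `clamp_zero` is available, and the
serial-change stage floors predictions at 1 mm³ because a relative change
against a non-positive baseline is meaningless.

## The synthetic cohort generator

The package ships no clinical data; the generator builds cohorts with the
statistical structure the analysis assumes, so every downstream stage is
testable. Its defaults *are* the study conditions:

* **Composition**: 147 images from 72 patients; 104/25/18 images carry
  1/2/3 nodules (208 nodule observations). Images are partitioned into
  patient series of ≥ 2 timepoints with constant per-patient multiplicity,
  so every nodule is observed serially.
* **Volumes**: lognormal, truncated to [110, 70 400] mm³, calibrated so the
  *truncated* distribution has mean 9 370 and SD 11 690 mm³. The printed
  summary statistics describe an observed, range-limited sample, so the
  generator matches them after truncation; the closed-form untruncated match
  (`lognormal_moments()`, meanlog ≈ 8.676, sdlog ≈ 0.969) is the solver's
  starting point, and the calibrated parameters come out at meanlog ≈ 8.540,
  sdlog ≈ 1.319. Lognormality itself is an assumption — only mean, SD and
  range are known — chosen for right skew and positive support, both clearly
  present in the reported summaries.
* **Serial change**: each follow-up volume is the previous volume times a
  factor drawn from [1.3, 2.5] (growth) or [0.4, 0.77] (shrinkage), with
  growth probability 0.5. Both ranges are bounded away from 1.0 so
  ground-truth interval-change classes are unambiguous at the default ±25%
  band; the reference pilot study names the three classes but quantifies
  neither a threshold nor a change distribution, so these are separability
  choices, not reproductions.

**The forward model for CAM parameters** is where the calibration lives.
Per nodule observation, with true volume V and sphere-equivalent projected
radius r = (3V/4π)^⅓:

1. apparent contour radius = r · exp(ε/2), ε ~ N(0, `area_noise_sd`); the
   reported area is π · (apparent radius)², i.e. the true cross-section times
   lognormal noise;
2. a latent conspicuity score combines the standardized log apparent area
   with a *subtracted* standardized log-volume component (weight
   `prob_vol_decoupling`) plus N(0, `prob_noise_sd`) noise;
3. peak activation = 0.2 + 0.8 · logistic(0.5 + latent), a saturating map
   into (0.2, 1];
4. the tabulated mean probability is the analytic mean of a Gaussian blob
   with that peak over its 0.2 contour, (peak − 0.2)/log(peak/0.2).

The subtraction in step 2 deserves a note. The observed correlation pattern —
area–volume ≈ 0.58, area–probability ≈ 0.73, probability–volume ≈ 0.22 — is
*not* reachable if probability is any noisy monotone function of apparent
size alone: in that structure the ratio of the probability–volume to the
probability–area correlation is pinned at the area–volume rank coupling
(≈ 0.6), forcing probability–volume ≈ 0.45. The data say the activation
strength tracks the blob it sits on much more faithfully than it tracks true
volume, so the generator explicitly removes part of the volume signal from
the conspicuity score — physically, large masses are not proportionally more
"confident" detections than crisp small nodules.

The three noise defaults were tuned once, by simulation (mean Spearman over
60 replicate cohorts on a coarse-to-fine grid), to centre the three
correlations on their targets, and then frozen: `area_noise_sd = 1.14`,
`prob_vol_decoupling = 0.35`, `prob_noise_sd = 0.64` give mean correlations
(0.585, 0.737, 0.225). At n = 208 the sampling SDs of the three coefficients
are about 0.046, 0.033 and 0.067, which is why the calibration bands in the
tests are ±0.10, ±0.10 and ±0.12.

**Rendering.** Nodules are drawn as radial Gaussian blobs whose peak equals
the modeled peak activation and whose 0.2 iso-contour radius equals the
apparent radius; placement is rejection sampling with a minimum center
separation of twice the sum of contour radii (relaxed to 1.2× and then to the
best-separated configuration found, with warnings, for extreme draws on
small grids). Extraction on rendered maps recovers the forward-modeled area
to within 5% for contour radii ≥ 5 pixels at generic radii — radii whose
contour passes exactly through many lattice points (e.g. an integer radius
at integer pixel spacing) are degenerate for strict-threshold pixel counting
and can undercount by ~10%; the generator's continuous radii avoid this set
with probability one.

**What the generator does not emulate**: rib shadows, the mediastinum, or
any radiograph appearance (only probability-map statistics matter
downstream); detector false positives and false negatives (every nodule
renders a blob, every blob is a nodule); cross-manufacturer probability
shifts (a per-image multiplicative bias is available but off by default,
matching the same-manufacturer design of the reference cohort); and any
correlation between a patient's successive noise draws. Passing tests on
synthetic cohorts therefore validate the *pipeline machinery and the
statistical reasoning*, not clinical performance.

## Serial change and what concordance can show

Serial pairs are consecutive-timepoint observations of the same nodule.
Predicted and true volumes are classified with the same ±25% relative-change
band, so concordance isolates prediction error rather than threshold
mismatch. Note the relative-change rule is not mirror-symmetric under
swapping baseline and follow-up (a −23% change reversed is +30%); the
classification contract is defined forward in time.

Under the calibrated noise — the noise *required* to reproduce an
area–volume rank correlation of only 0.58 — volume predictions carry roughly
10 000 mm³ RMSE on a 9 370 mm³ mean, and three-class concordance settles
around 0.48 (Monte-Carlo mean 0.482, SD 0.040 over 40 cohorts), well above
the ⅓ chance level but far from perfect. This is a faithful consequence of
the study conditions, not an implementation shortfall: a method whose
predictor explains this much rank variance cannot classify ±25% changes much
better. The tests pin the measured band rather than an aspirational one.

## Numerical and design choices, collected

* Strict mask inequality (p > cutoff); inclusive positivity (≥ threshold).
* 8-connectivity for components; area ties break by descending maximum
  probability, then row-major centroid order — extraction output is a
  deterministic function of the map.
* WOAP is not defined in the source material beyond its name; the
  probability-weighted area is the only definition consistent with the name
  and with mm² units, and it degenerates to area under saturation.
* Univariable degree-1.5 uses the full ladder {1, √A, A, A^1.5}, by analogy
  with the complete multivariable basis (the alternative {1, A^1.5} is not
  distinguishable from the published material).
* Anisotropic pixel spacing is rejected, not averaged.
* Maps are stored as 16-bit grayscale TIFF (probability = value/65535);
  8/16-bit PNG and plain-text matrices are accepted on input.
* All randomness descends from a single integer seed per cohort; a fixed
  seed reproduces every table byte for byte.
* Problem sizes used throughout the test-suite: cohorts of 208 nodules
  (the reference composition), 10⁴–10⁵ volume draws for distributional
  checks, 20-instance oracle sweeps on 32×32 maps, and pipeline runs on the
  full 147-image default cohort.

## Limitations

The regression is calibrated and evaluated on training data by design
(matching the reference analysis); nothing here estimates out-of-sample
error. The frozen published models apply only within the parameter ranges
that produced them — the degree-1.5 polynomial extrapolates violently and
can go negative below ~300 mm² of area. The generator's correlation
calibration makes the synthetic cohorts statistically, not visually,
realistic, and any conclusion about clinical accuracy requires clinical
data the package deliberately does not contain.
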