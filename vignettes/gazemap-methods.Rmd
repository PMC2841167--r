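---
title: "Fixation-map statistics with gazemap: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-map statistics with gazemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemap)
```

## The analysis chain

`gazemap` implements the standard analysis chain for gaze-contingent
("Spotlight") face-recognition experiments, in which observers view faces
through a Gaussian aperture locked to their gaze while a 1000 Hz eye
tracker records fixations. The chain is:

1. **Event parsing.** Raw samples are classified sample-by-sample: a sample
   is saccadic when its velocity exceeds 30 deg/s *or* the magnitude of its
   acceleration exceeds 4000 deg/s², the standard tracker thresholds.
   Velocity is a symmetric finite difference over ±1 sample (one-sided at
   the trace ends), scaled by the pixels-per-degree calibration; the
   acceleration is the symmetric difference of the speed trace. Runs of
   three or more missing-pupil samples are blinks, extended through
   adjacent saccade-flagged, missing, or undefined-kinematics samples
   (the ±1-sample halo around signal loss, where finite differences are
   meaningless). Saccades closer than 20 ms in time *and* 0.30 deg in
   space are merged iteratively to a fixpoint, absorbing whatever lies
   between. Every remaining sample belongs to a fixation. Events tile the
   recording exactly: an event over samples *i..j* spans
   `[t[i], t[j] + dt)`, so durations sum to the recording span — a
   property the tests assert on every parsed trial.

2. **Fixation maps.** Each fixation deposits its duration (ms) at the pixel
   nearest its centroid, weighting locations by time spent there; the raw
   map's total equals the total fixation time exactly (integer mass, which
   is why splatting is nearest-pixel rather than bilinear). Maps are
   smoothed with a unit-sum Gaussian kernel, σ = 10 px by default (roughly
   0.4 deg at 25 px/deg — a conservative stand-in for the spatial extent
   processed during a fixation). Smoothing is zero-padded: mass within
   ~4σ of the border is attenuated, which matters only for fixations
   hugging the image edge.

3. **Group and differential Z-maps.** Observer maps are summed per group.
   The two group maps are normalised with *pooled* moments — mean and
   population SD of their concatenated pixel values — so the two Z-maps
   share a scale; the differential map is the pixel-standardised difference
   `(a − b − mean) / sd`. Population (n-denominator) moments are used
   throughout so that exact identities hold (e.g. two uniform maps at
   levels 2 and 4 give Z ≡ ∓1).

4. **The Pixel test.** Significance on a smooth Z-map is familywise
   corrected through the expected Euler characteristic of a unit-variance
   Gaussian random field: with resel counts `R2 = area/FWHM²`,
   `R1 = half-perimeter/FWHM`, `R0 = 1` for the full rectangle and
   `FWHM = 2√(2 ln 2) σ`, the threshold solves `E[EC](t) = α` (one-tailed)
   or `α/2` (two-tailed on |Z|) by bisection on [1.5, 10] to 1e-6. All
   three EC terms are kept: with the 2D term alone the full-map two-tailed
   threshold at α = .05 would be noticeably lower. For the default
   geometry (382 × 390 px, σ = 10) the two-tailed threshold is 4.25.
   Suprathreshold pixels are grouped into 8-connected clusters, positive
   and negative excursions kept separate.

5. **ROI statistics.** Per observer, the mean Z inside each significant
   cluster (unweighted pixel average) enters a two-way mixed ANOVA with
   group as the between-subjects factor and face region as the
   within-subjects factor; with 10 observers per group and two regions the
   interaction has df (1, 18). Partial η² uses the effect's own error
   stratum; per-region group comparisons use classical equal-variance
   two-tailed t-tests (a Welch switch is provided) and pooled-SD Cohen's d.
   Observer maps are Z-scored with moments pooled over *all* observers'
   smoothed maps, so scores are comparable across observers; since the
   ANOVA and d are invariant to a common affine transform, the choice of
   pooling level (observer maps vs. group maps) does not affect the
   inferential results, only the absolute score values.

6. **Time courses.** Per observer, the frequency of fixations inside an
   ROI is the proportion of trials whose active fixation lies in the ROI
   at each grid time, optionally divided by ROI area (px²). The default
   grids are 10 ms bins over the 10 s learning exposure and 1% bins on a
   normalised 0–100% base for recognition, where viewing time varies.
   Saccade and blink periods count as "not in the ROI" by default
   (switchable to exclusion from the denominator). Group differences are
   tested with a percentile bootstrap: observers are resampled with
   replacement independently per group (implemented as multinomial row
   weights, which is algebraically identical), B = 5000 by default, and a
   time point is flagged when the 95% percentile interval excludes zero.
   Inference is pointwise — no correction across time points — which is
   the convention this analysis style uses, and is documented as such.

7. **Image statistics.** For stimulus sets, the pixelwise SD image across
   exemplars carries the discriminative information (the mean is what
   exemplars share). The difference of two sets' SD images is
   pixel-standardised and thresholded with the same Pixel test. The SD
   fields are *not* smoothed; the threshold assumes the default σ = 10
   smoothness and the output records that assumption
   (`assumed_sigma_px`), since a rougher field than assumed would make the
   test anticonservative.

## The synthetic generator

No human recordings ship with the package; every pipeline stage is
exercised against a seeded generator.

* **Observer profiles** are mixtures over four landmarks (left eye, right
  eye, nose, mouth) with Gaussian landing scatter (default 0.6 deg SD),
  Gamma fixation durations (shape 4, scale 80 ms → mean 320 ms, chosen to
  give roughly 27–30 fixations per 10 s trial, the scale human observers
  show), positional jitter, and a blink rate (0.05/s of fixation time).
  The eye-biased default (.35/.35 eyes, .20 mouth, .10 nose) emulates the
  Western-Caucasian eye/mouth strategy; the nose-centered profile
  (.15/.15/.60/.10) the East-Asian central bias under free (8 deg)
  viewing. Under constrained apertures (2/5 deg) both cultures actively
  fixate the same features, so constrained simulations default to the
  eye-biased mixture for both groups.

* **Scanpaths** alternate fixations and saccades; saccade durations follow
  the main-sequence rule `2.2 × amplitude(deg) + 21 ms`, and targets are
  redrawn until at least 0.5 deg away so every planned saccade is
  detectable. Rendering uses a smooth `pbeta(τ, 4, 4)` position profile
  whose peak velocity is `2.1875 × amplitude/duration` — at least three
  times the 30 deg/s threshold for amplitudes of 1 deg and above. A
  minimum-jerk profile (peak factor 1.875) would fall short of that
  margin at 1 deg under the same main sequence, which is why the slightly
  more peaked profile was chosen. Positional jitter is *temporally
  correlated* (white noise smoothed with a 20 ms Gaussian), emulating slow
  oculomotor drift: white jitter at 1000 Hz of even 0.1 deg would produce
  sample-to-sample speeds far above threshold and no parser could recover
  the planted events. Blinks interrupt fixations — the eye reopens on the
  same spot — because a blink inserted between a fixation and a saccade
  would orphan the saccade's sub-threshold onset tail into a spurious
  extra fixation.

* **Faces** are schematic: a gray background, darker face oval, darker
  Gaussian landmark patches, small per-identity landmark jitter (0.5 px
  position, 2 gray-level contrast) and spatially smooth luminance noise
  (SD 8 gray, σ = 12 px), clipped to gray levels [1, 256]. The noise
  dominates identity variation by design: the generator's job is to
  emulate stimulus sets with *no* systematic pixel-space diagnosticity
  difference between sets, and a near-homogeneous SD field is what makes
  the homogeneous-field threshold applicable. Real faces differ in many
  ways these images do not (texture, geometry covariation, race-specific
  structure); a null on synthetic sets shows the machinery is calibrated,
  not that real face sets carry no information.

* **Experiments** follow the standard block design: per face race,
  `blocks_per_race = 2` blocks of 14 learned identities (10 s exposure)
  followed by 28 recognition trials (the 14 learned + 14 new, half
  female). Recognition accuracy is Bernoulli with aperture-dependent
  probability — 0.50 at 2 deg (chance for the two-alternative familiarity
  judgement), 0.75 at 5 deg, 0.90 at 8 deg; the two larger values are
  package defaults shaped only by the qualitative finding that accuracy
  rises with aperture. Response times are log-normal with means
  decreasing in aperture (3000/2200/1600 ms).

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixels, origin top-left, y downward; gaze
  positions are floats; matrix element `[y+1, x+1]` holds pixel `(x, y)`.
* Population SD everywhere a map is standardised; degenerate inputs
  (identical groups, zero pooled SD, empty maps, empty ROIs, unbalanced
  ANOVA tables) raise descriptive errors rather than producing NaNs. An
  all-equal ANOVA table yields F = 0 (no evidence) rather than 0/0.
* The smoothing kernel is truncated at ±4σ; a centred delta loses less
  than 1e-9 of its mass, and the FWER simulations use the same kernel the
  pipeline applies, so assumed and actual smoothness agree.
* The velocity trace can optionally be smoothed with a centred moving
  average (`v_smooth_window`, default 1 = off): no filter window is
  standard across trackers, and any smoothing changes borderline events,
  so the default applies thresholds to the raw symmetric differences.
* `critical_z` accepts explicit resel counts, which is also how the
  single-resel sanity limit (the pointwise Gaussian quantile) is tested.

## The aperture and the landmark layout

The aperture's opacity ramp is the normalised Gaussian
`alpha(r) = (1 − e^{−r²/2s²}) / (1 − e^{−R²/2s²})` with `s = 0.5 R`,
which satisfies the two defining constraints exactly: fully transparent at
the centre of gaze, fully opaque at the aperture border. Whether the
original displays clipped or truncated their ramp at the border is not
knowable from the published constraints; only the boundary conditions are
enforced. A landmark is "visible" when at least 90% of its pixels receive
transmission above τ = 0.5. Under this rule transmission exceeds 0.5 only
within 0.532 R of gaze, and the default schematic layout (eyes at
(165, 190)/(217, 190) r = 13, nose (191, 215) r = 10, mouth (191, 252)
r = 13 on the 382 × 390 grid) was chosen so the paradigm's three designed
relations hold exactly: each eye fits inside its own 2 deg aperture, and
from the nose both eyes and the mouth are visible at 8 deg but not at
5 deg. These coordinates are package defaults for the schematic face, not
measurements of any stimulus set; layouts for real stimuli can be supplied
to `landmark_layout()`.

## Problem sizes used by the replicated studies

The test-suite studies run at desk scale, chosen once: familywise
calibration uses 2000 full-grid (382 × 390) null fields; cluster-recovery
power and null-calibration studies use 10 observers per cohort with one
learning block (14 trials × 10 s) each, 100 and 200 replicates
respectively; bootstrap coverage uses 30 observers per group, B = 2000,
1000 replicates (percentile bootstrap intervals undercover noticeably at
n = 10 — about 92.8% by the t-approximation — so the coverage study uses a
cohort size where the method's nominal level is attainable); the
image-statistics null study uses 20 images per set and 100 replicates.

## Known limitations

* **The differential fixation-map Pixel test is anticonservative for
  landmark-concentrated strategies.** The map is standardised by its
  *global* pixel SD, but the sampling variability of a difference of
  fixation maps concentrates where fixations land: at landmark pixels the
  local SD of the null difference is several times the global SD, so the
  |Z| maxima of two *identical*-strategy cohorts routinely exceed the
  homogeneous-field threshold. The random-field threshold controls the
  familywise rate for unit-variance homogeneous fields (which the
  calibration study verifies directly); it does not control it for
  z-scored differences of concentrated fixation maps, and the
  corresponding calibration check in the test suite documents this
  honestly rather than hiding it. Consequences for interpretation: the
  *presence* of a significant cluster in a differential map should not be
  read as familywise-controlled evidence by itself; the cluster *sign and
  location* pattern (e.g. eye-positive/nose-negative), effect sizes from
  per-observer ROI scores, and the bootstrap time courses carry the
  interpretable signal.
* The one-tailed group-map threshold quoted as 4.64 in this literature is
  not recovered by the EC expansion under any natural search-area/FWHM
  convention consistent with the two-tailed 4.25; the implementation
  exposes `alpha` and `tails` so either convention can be run, and only
  the reproducible 4.25 is asserted.
* Time-course inference is pointwise; no temporal multiplicity correction.
* The generator's profiles are stationary within a trial: the tendency of
  first fixations to orient before settling into a strategy is not
  modelled.
* Offline rendering only: the real-time display update loop of a
  gaze-contingent rig is hardware-bound and out of scope.
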