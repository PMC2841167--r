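# gazemap

Fixation-map statistics for gaze-contingent ("Spotlight") face-recognition
experiments.

In a Spotlight experiment, observers learn and recognise faces while seeing
the stimulus only through a Gaussian aperture (2, 5 or 8 degrees of visual
angle) locked to their gaze, and a 1000 Hz eye tracker records where they
look. The scientific question is *which facial information different groups
of observers actively use*: duration-weighted fixation maps are built per
observer, smoothed (Gaussian kernel, sigma = 10 px), summed into group maps,
and compared. `gazemap` implements that full analysis chain plus a seeded
synthetic-data generator, so every stage is testable without human
recordings:

- **Event parsing** — saccade/blink/fixation segmentation from raw samples
  (velocity > 30 deg/s or |acceleration| > 4000 deg/s²; saccades closer
  than 20 ms and 0.30 deg merged; >= 3 missing pupil samples = blink).
- **Spotlight rendering** — the Gaussian-alpha aperture
  (`alpha(0) = 0`, `alpha(R) = 1`) and landmark-visibility queries.
- **Fixation maps** — duration-weighted accumulation, smoothing, pooled
  Z-scoring of group maps, differential Z-maps.
- **The Pixel test** — familywise-corrected thresholds for smooth Z-maps
  from the expected Euler characteristic of a Gaussian random field,

  `E[EC](t) = R0 (1 − Φ(t)) + R1 (√(4 ln 2)/2π) e^(−t²/2) + R2 (4 ln 2/(2π)^{3/2}) t e^(−t²/2)`,

  with resels `R2 = area/FWHM²`, `R1 = (w+h)/FWHM`, `R0 = 1` and
  `FWHM = 2√(2 ln 2) σ`; solving `E[EC](t) = α/2` for the default
  382 × 390 map at σ = 10 gives the two-tailed critical value **Z = 4.25**
  (α = .05). Signed 8-connected clusters are extracted above threshold.
- **ROI statistics** — per-observer mean Z in each significant region,
  two-way mixed ANOVA (Region within, Group between; df (1, 18) at 10 per
  group), partial η², Cohen's d, per-region t-tests.
- **Time courses** — frequency of fixations in an ROI over time and
  percentile-bootstrap group differences (observers resampled with
  replacement, B = 5000, pointwise 95% CIs).
- **Image statistics** — pixelwise mean/SD images of stimulus sets and the
  differential-SD Pixel test for inherent diagnosticity.
- **Synthetic data** — observer strategy profiles (eye/mouth-biased vs
  nose-centered), main-sequence saccade kinematics, schematic face images,
  and whole simulated experiments (14 learned faces per block, 28
  recognition trials of which 14 old; accuracy at chance for the 2 degree
  aperture, rising with aperture size).

## Worked example

Simulate two cohorts of 10 observers (eye-biased "WC" vs nose-centered
"EA") under the 8 degree aperture and run the whole chain:

```r
library(gazemap)
cfg <- list(
  seed = 42,
  simulate = list(groups = list(WC = list(n = 10, profile = "eye_biased"),
                                EA = list(n = 10, profile = "nose_centered")),
                  aperture = 8, n_learn = 7, blocks_per_race = 1, races = "WC"),
  timecourse = list(B = 2000))
rep <- run_pipeline(cfg)
print(rep)
#> <gazemap_report seed=42 config=58308defc2f3e68252e557f7711eaf27>
#>   420 trials, 10816 events, 20 observers
#>   differential Pixel test: z_crit 4.251, 2 cluster(s)
#>   Group x Region: F(1, 18) = 359.37, p = 2.42e-13, pes = 0.95
#>   timecourse: 226/1001 time points significant (B = 2000)
print(rep$clusters)
#> <cluster_set: 2 cluster(s) at |Z| > 4.251 on 390x382>
#>   sign +1, area 220 px, peak Z 4.89
#>   sign -1, area 1539 px, peak Z -12.66
```

Reading the output: the differential Z-map (WC minus EA group map,
pixel-standardised) exceeds the Pixel-test threshold 4.25 in a positive
cluster over the eye region (where the eye-biased cohort spent more
fixation time) and a negative cluster over the nose (the nose-centered
cohort's preferred landing site) — the signed topology that distinguishes
the two strategies. The mixed ANOVA on per-observer ROI scores quantifies
it: the Region × Group interaction is F(1, 18) = 359.37 with partial
η² = 0.95, and the per-region Cohen's d values are large and of opposite
sign:

```r
print(rep$region_tests)
#>   region         t df            p  cohens_d
#> 1   neg1 20.460548 18 6.499525e-14  9.150235
#> 2   pos1 -9.489861 18 1.986804e-08 -4.243995
```

(groups are ordered alphabetically, so `t` and `d` are EA − WC: positive
on the nose region `neg1`, negative on the eye region `pos1`).

See the methods vignette (`vignettes/gazemap-methods.Rmd`) for the models,
parameter defaults, generator design and known limitations — including why
the differential-map Pixel test should be read as descriptive rather than
familywise-calibrated for landmark-concentrated fixation strategies.

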