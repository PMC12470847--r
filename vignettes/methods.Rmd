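---
title: "Methods: simulating and estimating pRF size changes under spatial frequency adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and estimating pRF size changes under spatial frequency adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

A voxel's (or surface vertex's) population receptive field (pRF) is the
aggregate of many neuronal receptive fields. In early visual cortex,
neurons with small receptive fields tend to prefer high spatial
frequencies (SF) and neurons with large receptive fields low SFs. If that
coupling holds, adapting the cortex to a high-SF pattern should reduce
the responsiveness of the small-RF subpopulation and leave the aggregate
— the measured pRF — *larger*; low-SF adaptation should do the opposite.
This package implements the full computational chain needed to state,
simulate and test that prediction: stimulus construction, a generative
neural model, 2D Gaussian pRF estimation, reliability-based quality
control, group statistics, and the psychophysical staircase analysis that
quantifies the perceptual SF aftereffect the paradigm rests on.

Everything runs on synthetic data with known ground truth, so every stage
of the estimator can be judged against an oracle rather than against
another estimate.

# Stimulus model

`build_run_apertures()` renders one mapping run as binary visual-field
masks on a square raster (`field_grid()`): 25 volumes of baseline, 30 of
initial adaptation, eight 25-step bar sweeps with two 25-volume blanks
(after the fourth and the eighth sweep), and a closing 25-volume
baseline — 330 volumes at TR 1 s, of which the 250 between initial
adaptation and closing baseline are used for fitting. Bars are 1.15° wide
and half-overlapping (25 steps spaced 0.575°, centre travel 13.8°); sweep
one runs bottom-to-top and each next sweep is rotated 45° clockwise. Bar
frames are clipped to the adapter-covered region: an annulus between the
0.35° occluder radius and the 7.5° aperture, minus two 20°-wide wedges on
the vertical meridian (`adapter_region_mask()`). The mapping stimulus SF
is the geometric mean of the two adapter SFs,
`geometric_mean_sf(0.5, 3.5)` ≈ 1.3 cpd, equidistant from both adapters
in octave space.

Choices worth making explicit:

* Apertures are binary. The on-screen stimuli have soft (alpha-gradient)
  edges and a 0.5 s top-up adapter inside every volume, but the adapters
  stimulate the same region in every volume, so their contribution is a
  constant the time-series analysis cannot see; the estimator fits the
  bar, not the adapter.
* A pixel belongs to a region when its *centre* satisfies the defining
  inequality, half-open (`r < R_outer`, `r >= R_inner`, bar
  `u ∈ [c − w/2, c + w/2)`). This makes left/right hemifield masks exact
  mirror images and 90°-rotation identities exact on the lattice.
* All 25 steps of every sweep are generated and the region mask does the
  truncation; no step is dropped a priori.
* The default analysis raster is 0.25°/sample (61×61). Because simulator
  and estimator share the raster, raster coarseness cancels in recovery
  tests; 0.25° keeps a whole-dataset fit inside desk-scale runtimes while
  sampling the smallest default pRFs (σ ≈ 0.3°) with several pixels per
  SD. The stimulus module itself defaults to the display-resolution 0.1°
  raster.

# Generative neural model

`sample_population()` draws, per vertex, `n_subunits = 20` Gaussian
receptive subfields. Sizes are log-normal with median
`0.25 + 0.12 × eccentricity` (degrees; a V1-like size-eccentricity
scaling) and log-SD 0.5 — enough within-vertex size heterogeneity for
adaptation to act on, corresponding to roughly a 2-fold interquartile
size range. Centres scatter isotropically with SD 0.25 × median size.
Preferred SF is tied to size by `pref_sf = 0.65 / rf_size` (cpd·deg), so
a 0.5° subfield prefers the 1.3 cpd mapping SF. These constants are
simulation choices, not measured values: the hypothesis being emulated is
qualitative, and the package's claims are about the *direction* and
*detectability* of the effect, not its physiological magnitude.

Adaptation multiplies each subunit's gain by
`1 − A·exp(−d² / 2w²)` where `d` is the octave distance between the
subunit's preferred SF and the adapter SF (`adaptation_gain()`).
Defaults `A = 0.5`, `w = 1` octave put the 1.3 cpd mapping SF ~1.4
octaves from both adapters — inside the ≤ 2-octave range over which SF
adaptation is reported to transfer, and far enough that the mapping
stimulus itself is not differentially suppressed.

The ground truth each vertex is judged against is
`effective_sigma_oracle()`: the best least-squares single 2D Gaussian fit
to the gain-weighted sum of subunit profiles on the raster. This is the
quantity a perfect pRF estimator would report, and it is computed without
touching the time-series machinery.

`neural_timecourse()` sums normalised subunit overlaps with each
aperture frame; `bold_from_neural()` convolves with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6 — empirically derived per-site HRFs
are not portable, so the canonical SPM-style form is used and is
configurable) and adds iid Gaussian noise.

**Noise calibration.** Noise is specified relative to the clean per-run
signal SD. With the default 8 runs (4 per adapter condition, the middle
of the reported 6–10 even-count range) the odd/even halves average 2
runs each, so the split-half correlation is approximately
`1 / (1 + noise_rel² / 2)`; the default `noise_rel = 0.93` puts it near
0.7, typical of surface-vertex data and the regime in which the
estimator's noise robustness is assessed. Noise is white: the
correlation-based fitting statistic and the split-half reliability do not
model temporal autocorrelation, and adding an AR structure would change
effective degrees of freedom, not the point estimates. This is a known
simplification relative to real BOLD noise.

What the generator deliberately does *not* emulate: orientation tuning,
contrast-response nonlinearities, surround suppression, cortical
magnification of vertex density, and receptive-field shape beyond
isotropic Gaussians. Passing tests therefore show that the pipeline
recovers what this generative family produces — they do not certify
behaviour under real-data pathologies (motion, draining veins, non-Gaussian
pRFs).

# pRF estimation

The estimator is the standard two-stage coarse-to-fine scheme over the
plain isotropic 2D Gaussian (no compressive exponent, no surround):

1. **Forward model.** `predict_neural()` is the normalised overlap of the
   Gaussian with each binary frame (0 empty field, 1 full field);
   `predict_bold()` convolves with the HRF over the *full* run and then
   crops to the 250 mapping volumes, so HRF spill-over across
   blank/baseline boundaries is modelled. The whole map from pixel
   weights to mapping-volume predictions is one precomputed linear
   operator (`prf_model()`), which makes an objective evaluation a single
   matrix-vector product (implemented in C++).
2. **Grid stage.** `prf_search_grid()` crosses 12 eccentricities
   (0–8.25°, i.e. 1.1 × the aperture radius) × 24 polar angles × 16
   log-spaced sigmas (0.1–4°); `grid_stage()` returns the candidate whose
   z-scored prediction correlates best with the observed series
   (zero-variance predictions are excluded; ties resolve to the first
   candidate in deterministic grid order).
3. **Refinement.** Nelder-Mead on (x0, y0, σ) maximising the Pearson
   correlation, started from the top *two* grid candidates at distinct
   positions; the better basin is then polished by a restarted simplex.
   The two-start rule exists because the correlation surface can hold a
   collapsed small-σ local maximum near — but not at — the true position;
   a single start occasionally lands there, while the second basin
   recovers the global optimum. Relative convergence tolerance 1e-8,
   at most 500 iterations per simplex, σ unconstrained beyond a 1e-4
   degeneracy guard (implausible fits are left to the downstream filter,
   which is where the exclusion semantics live). If refinement fails to
   improve on its start, the grid parameters are returned flagged.
4. **Amplitude.** `fit_amplitude_baseline()` regresses the observed
   series on the prediction by OLS. In the pipeline the prediction is
   z-scored first, so `beta` is the amplitude per unit-variance
   prediction; on z-scored data this equals the fit correlation and is
   the scale on which the 0.01–3 plausibility band is interpreted.
   `R²` is the squared Pearson correlation.

On 200 noiseless single-Gaussian vertices drawn inside the stimulated
region (σ 0.3–2°, eccentricity ≤ 7°), the default grid + simplex
recovers all three parameters to well under 0.05°; positions inside the
occluded meridian wedges are excluded from that suite because a pRF that
never overlaps the stimulus is unidentifiable in principle, not an
estimator defect. At the calibrated split-half r ≈ 0.7 the σ estimator's
group bias is ~1%, though single-vertex estimates scatter widely — which
is exactly why the downstream statistics use medians.

One systematic property deserves emphasis. For *population* vertices —
mixtures of scattered, unequal subfields — the time-series fit reads
σ about 20–50% larger than the image-space least-squares oracle, even
without noise. The two are different summaries of a non-Gaussian
aggregate: the overlap objective integrates the profile's heavy mixture
tails through every bar position, while the L2 image fit is dominated by
the peak. The offset is shared by both adapter conditions and therefore
cancels in the H − L comparison that carries the scientific claim; it
does mean the `recovery_rmse` reported against the oracle mixes this
definitional offset with estimation noise.

# Reliability and quality control

Each run is linearly detrended and z-scored (`detrend_zscore()`; the
order of the trend is linear; scanner drift over a 5.5-minute run is
well captured by a line and nothing downstream requires more). Odd- and even-run averages are correlated
(`split_half_reliability()`, computed on the full run, i.e. before the
non-mapping volumes are discarded) and stepped up with the
Spearman-Brown formula at k = 2 — from half-session averages to the full
session (`spearman_brown()`; k is an argument for the general case). The
result is the noise ceiling: the maximum R² a correct model could reach.
Negative split-half correlations clamp the ceiling to 0 — an unreliable
vertex cannot bound goodness of fit, and such vertices are subsequently
excluded because `normalized_r2()` maps a zero ceiling to nR² = 0. The
ceiling is used directly (not squared) as the denominator of nR²,
following the reading that the reliability measure *is* the ceiling.

`filter_vertices()` applies the four exclusion rules: σ ≤ 0; x0 = y0 = 0
exactly; β < 0.01 or > 3; nR² < 0.2. Boundary values (β exactly 0.01 or
3, nR² exactly 0.2) are kept, since the exclusions are strict
inequalities. Removed vertices are *not* matched between conditions by
default (different neural subpopulations are expected to survive
adaptation in each condition); `size_difference()` intersects on vertex
id and therefore implements the matched-vertex control when fed
already-matched tables.

# Group statistics

* `moods_median_test()` — per participant, the high- vs low-adapted pRF
  size distributions (zero-bounded, skewed) are compared by counting
  observations above the pooled median; Pearson χ² on the 2×2 table,
  df 1, no continuity correction (the standard Mood convention; ties
  count as "not above"; both choices are switchable). The family of participant × ROI
  tests is Benjamini-Hochberg corrected at q < 0.05
  (`group_summary()`).
* `sliding_bins()` — H − L size differences (with the across-condition
  mean eccentricity, to mitigate regression-to-the-mean binning bias)
  are binned into 100 sliding 1°-wide bins over 0–8° (the plotted
  eccentricity range); per-bin medians with fewer than 10 vertices are
  dropped; `group_profile()` averages per-participant profiles and
  reports the between-participant SEM.
* `rm_anova_2way()` — the ROI × adapted-SF repeated-measures ANOVA on
  per-participant median sizes, through orthonormal effect contrasts;
  Greenhouse-Geisser ε from the contrast-score covariance
  ((tr S)² / (q tr S²), clamped to [1/q, 1]) corrects the df of effects
  with q > 1. A 2-level factor has ε = 1 by construction. An exactly
  absent effect yields F = 0 rather than a 0/0 of rounding noise.
* `proportional_difference()` — the symmetric percent change
  `(σ_H − σ_L) / mean(σ)`, used because absolute size differences are
  incomparable across visual areas whose baseline sizes differ tenfold.
  Several proportional-change conventions exist (ratio to one
  condition, log ratio, symmetric percent); the symmetric form was
  chosen for its antisymmetry under condition exchange and is stated
  wherever reported.

# Psychophysics

The behavioural arm measures the SF aftereffect the fMRI paradigm relies
on. `run_session()` runs six blocks (3 conditions × 2 adapted sides), the
two no-adaptation blocks always first to avoid adaptation carry-over, the
rest shuffled. Each block interleaves two 30-trial one-up-one-down
staircases starting at the extremes of a 30-level test set (0.2–3.8 cpd,
evenly spaced — the spacing, ~0.124 cpd, is what makes the terminal
staircase step sensible). The step starts at 0.5 cpd and is halved at
every response reversal down to a floor of 0.125 (= 0.5/2²; the level
set's own spacing), levels snapping to the nearest set member with ties
toward the reference. The simulated observer (`observer_model()`) has a
condition-dependent log-SF shift of the perceived reference — defaults
+ln 1.07 (low-SF adapt), −ln 1.15 (high-SF adapt), 0 (none), the
aftereffect magnitudes this paradigm reports — Gaussian decision noise
(0.25 log units, chosen to give psychometric slopes resembling published
curves) and a 2% lapse rate.

`fit_psychometric()` fits a cumulative Gaussian in log SF (= log-normal
in SF) by maximum likelihood with a single symmetric guess/lapse rate
bounded at 0.05; because the lapse is symmetric, the PSE is exactly the
half-proportion point. Sessions and sides are pooled per condition for
fitting; bias correction subtracts the same-side no-adaptation PSE
(`bias_correct()`), sides are then averaged, and
`aftereffect_percent()` converts log shifts to percentages. Group
inference is by one-sample t-tests on the log shifts, Bonferroni ×3 for
the raw family and ×2 for the bias-corrected family.

The contrast control task reuses the staircase engine on 30 contrast
levels (0.01 upward in steps of 0.031, the final level clamped to the
reference contrast 1.0 — the printed endpoints and step are mutually
inconsistent, and the clamp favours covering the full range). Because
the reference sits at the top of the level set, psychometric fits would
be one-sided; `reversal_pse()` instead drops the first three reversals,
excludes reversal levels beyond ±2 unscaled MADs of their median
(unscaled, i.e. no 1.4826 normal-consistency factor), and averages the
survivors; staircases with ≤ 3 reversals are rejected outright. The
contrast staircase's initial step (0.124, four level spacings, halved to
a floor of one spacing) is a package choice, as no step is printed for
that task.

# Problem sizes, seeds, determinism

The package-default dataset — 8 participants × 300 vertices × 8 runs,
A = 0.5, w = 1 octave — is the configuration under which the headline
claims are tested: median σ_high > σ_low for ≥ 7 of 8 participants and a
binned H − L profile above zero in ≥ 95% of valid bins, with the effect
vanishing at A = 0 (checked at 4 participants, which is ample for a null
that is symmetric around zero). The analysis scripts under `analysis/`
demonstrate the same chain at 4 × 80 vertices; `scripts/acceptance.R`
recomputes the headline quantities at 8 × 60. These sizes are the
package's own desk-scale choices; every claim scales with the default
configuration.

All randomness flows from one root seed through `stage_seed()` (a stable
per-stage hash), so a dataset, a behavioural experiment, or an entire
`run_pipeline()` is bit-reproducible from `(config, seed)`; the pipeline
writes its summary as JSON and reproducibility is testable by byte
equality.

# Known limitations

* White Gaussian noise; no temporal autocorrelation, motion, or
  physiological structure.
* Isotropic Gaussian pRFs in both generator and estimator; the estimator
  inherits the usual blindness to pRF elongation and surround
  suppression.
* The adaptation model acts multiplicatively on gain only; it does not
  change subunit tuning width or position, which real adaptation might.
* The effect *size* in degrees is a function of invented population
  heterogeneity constants; only its direction and statistical
  detectability are meaningful claims.
* The contrast-control observer is a convenience for exercising the
  reversal-PSE machinery, not a model of contrast perception.
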