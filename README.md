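# prfadapt

Simulation and analysis of population receptive field (pRF) mapping under
spatial frequency (SF) adaptation.

## The problem

In early visual cortex, neurons with small receptive fields tend to
prefer high spatial frequencies and neurons with large receptive fields
low ones. A voxel's measurable quantity — the pRF, modelled as an
isotropic 2D Gaussian with centre (x0, y0) and size σ — aggregates over
that whole subpopulation. If the size–SF coupling holds, *adapting* the
cortex to a high-SF pattern should suppress the small-RF units and leave
the measured pRF larger, while low-SF adaptation should shrink it. This
package implements the complete computational chain needed to simulate
and test that prediction, for anyone who wants a ground-truthed testbed
for pRF analysis choices or a reference implementation of the
adaptation-pRF paradigm:

* **Stimulus design** — binary bar-sweep apertures for a 330-volume
  mapping run (eight 45°-rotated sweeps of 25 half-overlapping 1.15°
  bars, two blank blocks, baselines), clipped to the adapter-covered
  annulus minus the vertical-meridian wedges.
* **Generative neural model** — each vertex is a population of Gaussian
  subfields with log-normal sizes (median 0.25 + 0.12 × eccentricity
  deg), preferred SF tied to size by `pref_sf = 0.65 / rf_size`, and
  adapter-tuned gain suppression `g = 1 − A·exp(−d²/2w²)` in octave
  distance `d` (defaults A = 0.5, w = 1 octave); multi-run BOLD via a
  double-gamma HRF plus calibrated white noise. A least-squares oracle
  (`effective_sigma_oracle()`) gives the ground-truth effective σ per
  condition.
* **pRF estimator** — coarse-to-fine fitting of the 2D Gaussian:
  correlation-maximising grid search (12 ecc × 24 angles × 16 log-spaced
  σ) followed by multi-start Nelder-Mead refinement and OLS
  amplitude/baseline, `R² = r²`.
* **Reliability / QC** — per-run linear detrend + z-score, odd/even
  split-half reliability, Spearman-Brown noise ceiling, noise-normalised
  `nR²`, and the four-rule vertex filter (σ ≤ 0; origin fits;
  β outside [0.01, 3]; nR² < 0.2).
* **Group statistics** — per-participant Mood's median tests with
  Benjamini-Hochberg FDR, 100 sliding 1°-wide eccentricity bins of the
  H − L size difference, symmetric proportional change, and a
  Greenhouse-Geisser-corrected ROI × SF repeated-measures ANOVA.
* **Psychophysics** — interleaved one-up-one-down staircases over 30
  test SFs (0.2–3.8 cpd), maximum-likelihood log-normal psychometric
  fits with the PSE at the half-proportion point, bias correction and
  aftereffect percentages, plus the reversal-based PSE with ±2 MAD
  outlier rejection used for the contrast control task.

Everything runs on synthetic data with known ground truth; no external
data are needed. See `vignettes/methods.Rmd` for the model, its
assumptions, and every numerical choice.

## Worked example

The numbered scripts under `analysis/` run the chain as a narrative
(each is a thin driver over package functions and writes tables under
`results/`):

```sh
Rscript analysis/01_design.R        # aperture/run arithmetic
Rscript analysis/02_simulate.R      # ground-truthed dataset (4 x 80 vertices)
Rscript analysis/03_fit_prf.R       # coarse-to-fine fits + QC
Rscript analysis/04_group_stats.R   # Mood tests, bins, ANOVA
Rscript analysis/05_psychophysics.R # staircases, PSEs, aftereffects
Rscript analysis/06_reproduce.R     # one-command pipeline + summary.json
```

`analysis/02_simulate.R` and `analysis/03_fit_prf.R` print, for the
default adaptation model:

```
Simulated 320 vertices (4 participants x 80, 8 runs each).
Oracle effective pRF size: median 0.631 deg (high-SF adapted) vs 0.536 (low);
the high-SF-adapted aggregate is wider for 100% of vertices (median gap 0.072 deg).
...
QC kept 640 / 640 (100.0%); exclusion reasons: none
Median split-half reliability 0.70; median nR2 1.03.
Recovery against the oracle: r = 0.86, RMSE = 0.230 deg, median bias = +34.4% ...
```

The generative mechanism widens the effective pRF after high-SF
adaptation for essentially every vertex, and the fitted sizes track the
oracle (r = 0.86) at the calibrated reliability (split-half r ≈ 0.7).
The positive offset against the oracle is a definitional property, not a
bug: for mixture aggregates the time-series overlap fit reads wider than
the image-space least-squares Gaussian, identically in both conditions,
so it cancels in the H − L comparison (see the methods vignette).
`analysis/04_group_stats.R` then finds the effect in the fitted sizes
(at this compact demo size the direction is unanimous while the
per-participant median tests are underpowered; at the default 300
vertices/participant, 8 of 8 reach FDR significance — see below):

```
4 / 4 participants show a larger median pRF size after high-SF adaptation (0 significant at FDR q < 0.05).
Binned H - L profile: 93% of 87 valid bins above zero (mean 0.064 deg).
Median proportional size change: +8.3%.
```

and `analysis/05_psychophysics.R` recovers the behavioural aftereffects
the observer model generates (perceived SF up ~7% after low-SF
adaptation, down ~13% after high-SF adaptation, unbiased without
adaptation):

```
Perceived SF of the reference: +7.8% (low-SF adapt), -13.7% (high-SF adapt), -0.67% (none).
Contrast control: 3 of 216 staircases rejected (reversal rule).
Paired t-test, high vs low adapter effect on perceived contrast: t(8) = 0.58, p = 0.58.
```

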