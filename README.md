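# diveforage

Fine-scale foraging analysis for diving seabirds from combined GPS,
time-depth and tri-axial acceleration records, built around guard-stage
African penguins foraging over a mixed benthic/pelagic shelf.

Field studies of this kind ask where and how often a diving predator
captures prey, and at what cost: animal-borne video can validate capture
signals but only for a few hours, so a classifier trained on the
validated window is used to detect captures across whole foraging trips.
`diveforage` implements that chain end to end:

* **Track conditioning** — land filter, 12.4 km/h speed filter
  (forward-sequential, great-circle), 1-min linear interpolation.
* **Dive analysis** — rolling-quantile zero-offset correction of depth
  drift, dive segmentation at the 1.5 m surface threshold, descent /
  bottom / ascent phases (bottom = samples ≥ 80% of max depth), post-dive
  intervals, trip-level dive statistics.
* **Effort** — static/dynamic separation by a 1 s running mean and
  per-sample VeDBA (`sqrt(x_dyn^2 + y_dyn^2 + z_dyn^2)`), totalled per
  dive.
* **Benthic/pelagic typing** — two-step rule against a bathymetry
  raster: bathymetric depth ratio (max depth / seafloor depth) > 0.8
  *and* max depth within 10% of an adjacent dive; dives over seafloor
  < 15 m or within 2 km of the colony are excluded.
* **Prey-capture detection** — 24 summary features over a rolling
  8-sample window, 5:1 swim:capture downsampling, radial-kernel SVM
  (built-in SMO solver) tuned by grid search under 10 random 70:30
  splits, and consolidation of window predictions into discrete capture
  events assigned to dives.
* **Foraging metrics** — per-dive success (Bernoulli), capture rates,
  Foraging Efficiency Index (captures / total VeDBA), Dive Efficiency
  (captures / duration), capture-depth vs max-depth correlation, grouped
  summary tables, and a model-ready per-dive export for external
  mixed-model software.
* **Synthetic data** — a seeded simulator (bathymetry, track, depth,
  acceleration, ground truth) with the statistical structure the
  analysis assumes, so the whole chain is testable without field data.

## Worked example

```r
library(diveforage)

bathy <- generate_bathymetry(seed = 1001)
sim   <- simulate_trip(sim_config(seed = 1, trip_duration_h = 2), bathy)
res   <- process_trip(sim$trip, bathy, pipeline_config(),
                      truth = sim$truth)

res$type_counts
#> benthic pelagic excluded
#>       7      40        0

res$detector
#> <capture_detector> RBF SVM: cost 100, gamma 0.01, 409 SVs, 24 features
#>   CV accuracy: 97.0% +/- 0.15
#>   CV recall: 83.4% +/- 0.84
#>   CV fpr: 0.4% +/- 0.06

capture_rates(res$metrics)
#>      type n_animals n_dives capture_rate capture_rate_se pct_successful
#> 1 pelagic         1      40          0.4               0       25.00000
#> 2 benthic         1       7          1.0               0       57.14286
```

The detector reports window-level cross-validated skill (accuracy,
capture recall, false-positive rate, mean ± SE over ten 70:30 splits).
`capture_rates()` recovers the per-type capture intensities and success
fractions the generator planted (1.2 and 0.4 captures/dive; 60% and 23%
successful) — on a single short trip the small-sample wobble is visible,
over a cohort they converge. `res$metrics` is the per-dive table
(success, n_captures, FEI, DE, log transforms, covariates) that
`export_model_table()` writes for GLMM/LME fitting elsewhere.

A command-line driver is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/diveforage.R", package="diveforage"))')" \
    all --out /tmp/demo --seed 1 --hours 2
```

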