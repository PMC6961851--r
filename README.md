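# handkin

Kinematic analysis of rodent food-handling behavior from markerless
pose-tracking.

Mice eating a seed alternate several times per second between an
**oromanual** phase (item manipulated at the mouth with the digits) and a
**holding** phase (item held below the mouth while chewing), punctuated by
two fast stereotyped maneuvers: ~20 ms bimanual **regrips** and ~100 ms
**sniffs** that bring the item under the nares. handkin reconstructs this
behavioral architecture from DeepLabCut-style tracking tables and phase
ethograms, for behavioral neuroscientists who need the maneuver-level
statistics without the original rig.

Per frame, two features span the postural state space — the inter-D3
(hand) distance *D* = |RD3 − LD3| and the snout-to-hands distance
*L* = |nose − (RD3 + LD3)/2|, both in mm — plus the inter-D3 angle θ.
On top of them the package implements:

* **Postural modes** — k-means over (L, D) with L-method knee selection
  of k; phase statistics (switch rate, oromanual duty cycle, interior-
  segment durations); per-animal and average kernel-density maps on
  [0, 20] mm² with 10%-of-max contours; holding-to-oromanual rise times
  (10–90% line-fit method).
* **Maneuver detection** — regrips as peaks in D with topographic
  prominence ≥ 0.75 mm and both flank slopes > 88 mm/s; sniffs as dips in
  the ventral L reaching ≤ 2.5 mm with prominence ≥ 1 mm and ≥ 250 ms
  separation (head-fixed variant: prominence ≥ 2.5 mm, width ≤ 600 ms);
  amplitude and FWHM against pre/post baseline windows (−300..−100,
  +100..+300 ms); peak-aligned averages; rates and phase-relative timing.
* **Regrip microstructure** — burst periodicity from mean
  autocorrelograms of ≤ 300 ms-interval regrip groups; signed bimanual
  asymmetry index (right − left)/(right + left) of 40 ms peri-peak path
  integrals; rolling CV of D and θ; grip-angle changes around regrips.
* **Head angle** — Pratt's algebraic circle fit to the tracked eye's
  rotation arc; four-quadrant head pitch angle (head-down negative).
* **Statistics** — first-within-then-between-animal aggregation, median ±
  unscaled m.a.d., exact Wilcoxon signed-rank (smaller-sum W, exact to
  n = 25 with ties), exact small-sample Mann–Whitney U, Spearman's rho,
  Benjamini–Hochberg and Bonferroni flags.
* **Synthetic sessions** — a generator that emits ground-truth-annotated
  sessions in the exact input dialects (tracking CSV, ethogram CSV, truth
  JSON), so every stage is validated by parameter recovery without any
  video data.

## Worked example

```r
library(handkin)

# simulate a 60 s session (or read your own tracking CSV + ethogram)
s    <- generate_session(generator_params(duration = 60), seed = 42)
traj <- calibrate(s$front, s$truth$calibration)   # px -> mm, 294.1 fps
f    <- compute_features(traj)                    # L, D, theta per frame

cl <- cluster_phases(f, rng_seed = 1)
cl$k_selected
#> [1] 2
round(cl$centroids, 2)
#>      L    D
#> 1 2.84 6.10
#> 2 4.97 5.34
cl$phase_labels
#> [1] "oromanual" "holding"

ev <- peak_metrics(f, detect_regrips(f), 294.1)
nrow(ev); round(median(ev$fwhm, na.rm = TRUE) * 1000, 1)
#> [1] 128
#> [1] 21.4

ps <- phase_statistics(s$truth$ethogram, 294.1)
round(c(switch_hz = ps$switch_rate, duty = ps$duty_cycle), 2)
#> switch_hz      duty
#>      3.52      0.46
```

The two centroids recover the generator's posture levels (holding hands
~5.1 mm from the snout, oromanual ~2.7 mm); 128 regrips in 60 s is the
generator's ~2 Hz regrip rate; the 21.4 ms median FWHM reflects the
17 ms pulses measured against baselines that mix the two phase levels.

The numbered scripts under `analysis/` run the same pipeline as a
narrative workflow — `01_simulate.R` writes a cohort of eight sessions
under `results/sessions/`, `02`–`06` compute modes, maneuvers, regrip
microstructure, head angle and group statistics, writing tables under
`results/`.

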