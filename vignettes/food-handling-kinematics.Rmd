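---
title: "Quantifying rodent food-handling from markerless tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rodent food-handling from markerless tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handkin)
```

## The measurement problem

Mice handling a food item alternate rapidly (a few times per second)
between two postural modes: an *oromanual* phase, in which the item is
manipulated at the mouth with the digits, and a *holding* phase, in which
it is held below the mouth while the animal chews. Within the oromanual
phase, two fast stereotyped maneuvers occur: *regrips*, ~20 ms bimanual
grip readjustments while the item is bite-held, and *sniffs*, ~100 ms
movements that bring the item under the nares near the end of a holding
phase.

handkin turns markerless pose-tracking output (DeepLabCut-style CSV
tables of per-frame body-part positions with confidence scores) plus
manually annotated phase ethograms into quantitative descriptions of this
behavior. The whole state space is spanned by two scalar features
computed per frame from the snout tip and the two D3 knuckles:

* `D = |RD3 - LD3|`, the inter-hand distance (mm);
* `L = |nose - (RD3 + LD3)/2|`, the snout-to-hands distance (mm);
* `theta`, the orientation of the left-to-right D3 vector (degrees,
  y-up). Only *changes* in theta enter any analysis, so its reference
  axis is a free convention.

## Pipeline stages and their models

### Tracking I/O and calibration

Tracking tables use the three-header-row dialect (scorer / bodyparts /
coords); columns are located by name. Positions start in pixels; a
ruler-derived mm-per-pixel factor converts them once, and the unit state
is explicit so pixel and mm data can never be mixed. Samples can be
masked by a likelihood floor (default 0 — i.e. off, because the source
workflow excluded poorly tracked *sections* rather than thresholding
confidence) and by explicit exclusion intervals. Masked samples propagate
as missing values through every downstream feature; nothing is imputed.

Ethograms are ordered `(start_frame, phase)` rows; segments are the
half-open intervals between consecutive starts, phases must alternate,
and the first and last segments are flagged non-interior because their
true durations are unknown — they are excluded from duration and
switch-rate statistics (but not from the duty cycle, which is a ratio of
total times and needs no complete segments).

### Postural modes

Each frame is a point in (L, D) space. k-means (k = 1..10, ten random
restarts per k, lowest within-cluster SSE kept, on unscaled mm) is
followed by L-method knee selection: for every candidate knee c the SSE
curve is split into points 1..c and c..k_max, a least-squares line is fit
to each side, and the candidate minimizing the length-weighted sum of the
two residual RMSEs wins (ties to the smaller c, so featureless curves
collapse to the simplest answer). With k = 2 the cluster with the smaller
L centroid — hands at the mouth — is labeled oromanual.

Mode occupancy is visualized as Gaussian-kernel densities on a shared
grid over [0, 20] mm² (128² cells), each map normalized to a maximum of
1, averaged across animals, and contoured at 10% of maximum. Bandwidths
follow a normal-reference rule per dimension. The kernel is plainly
truncated at the support boundary rather than boundary-corrected; for
handling data, which sits several millimetres from 0, the 10% contour is
insensitive to this choice.

### Maneuver detection

Both detectors are peak finders with topographic prominence (height above
the higher of the two minima separating a peak from higher terrain):

* **Regrips**: local maxima of D with prominence ≥ 0.75 mm whose rising
  *and* falling flanks (peak to prominence base) each contain a
  single-frame slope exceeding 88 mm/s. Requiring both flanks encodes the
  spike-like symmetry of the maneuver; an `either`-flank variant is a
  configuration switch.
* **Sniffs**: local maxima of −L_ventral reaching −2.5 mm or above (the
  item comes within 2.5 mm of the snout), prominence ≥ 1 mm, pairwise
  separation ≥ 250 ms (conflicts keep the more prominent dip, then the
  earlier). A head-fixed mode raises the prominence threshold to 2.5 mm
  and caps the width at half-prominence at 600 ms, countering the false
  positives that looser settings produce in those recordings.

Event metrics reference a baseline defined as the pooled mean of the
samples 300–100 ms before and 100–300 ms after the peak; amplitude is the
absolute peak-to-baseline difference and FWHM the time between the
linearly interpolated crossings of the halfway level adjacent to the
peak. Events whose baseline windows leave the trace are flagged invalid
rather than erroring. No smoothing is applied before detection.

### Regrip microstructure

Regrips arrive in bursts. Groups with inter-event intervals ≤ 300 ms are
autocorrelated (the D segment from 300 ms before the first to 300 ms
after the last event, mean-subtracted, zero-lag-normalized, to ±300 ms
lag); the across-group mean is min-max normalized and the burst rhythm is
the reciprocal of the lag of the largest local maximum beyond the central
peak (delimited by the first positive-lag local minimum). Mean
subtraction before averaging is essential: the raw trace's DC offset
otherwise swamps the interior structure.

Bimanual asymmetry is the signed index (right − left)/(right + left) of
the two hands' 2D path integrals over the 40 ms window centered on the
peak, using each hand's D3 as its proxy point (the only consistently
tracked bilateral landmark): 0 for equal paths, ±1 for a unimanual
regrip. Local variability is the rolling coefficient of variation (40 ms
windows), compared between windows within 20 ms of a regrip peak and all
others; windows with non-positive mean return a missing CV rather than
exploding. Grip-angle changes take the median theta over [−60, −20] ms
before the peak as baseline and report the median absolute deviation from
it during that epoch and during [+20, +60] ms.

### Phase-transition rise time

For a holding-to-oromanual transition, the baseline is the mean of L from
750 to 250 ms before the transition; a line through the last
pre-transition crossings of 10% and 90% of the baseline-to-transition
difference is extrapolated back to the baseline, and the rise time is the
interval from that intercept to the transition. On a pure linear ramp
this recovers the ramp duration exactly, for any slope and offset; a step
at the transition frame collapses the crossings into one frame; a flat
trace signals an undefined result.

### Head angle

When the head can rotate in the sagittal plane, the tracked eye sweeps an
arc. Its circle is estimated by Pratt's algebraic fit — minimizing the
algebraic distance under the constraint b² + c² − 4ad = 1, solved as a
generalized eigenproblem of the centered moment matrix (the eigenvector
of the smallest non-negative eigenvalue) — which is exact on noiseless
circles and nearly unbiased on short arcs. The head angle is the
four-quadrant arctangent of the eye's displacement from the center, with
image y converted to up-positive so 0° points toward the animal's front
and head-down postures are negative (around −70° in hunched feeding); an
optional flip mirrors x for optics that place the eye on the other side.

### Statistics

All group statistics are nonparametric and aggregate first within and
then between animals; summaries are the median ± unscaled median absolute
deviation across animal medians. Paired comparisons use the Wilcoxon
signed-rank test with W reported as the *smaller* signed-rank sum; for
n ≤ 25 the two-sided p-value is exact, computed by convolving the null
distribution over the observed (doubled, mid-) ranks — identical to
enumerating all 2ⁿ sign assignments, and correct under ties, which the
textbook tables are not. Independent comparisons use the Mann–Whitney U
with exact enumeration of group-label arrangements up to n₁+n₂ = 14 and a
tie-corrected normal approximation beyond. Correlations are Spearman's
rho. Benjamini–Hochberg and Bonferroni flags at alpha = 0.05 mark which
p-values survive multiple-comparison correction.

## The synthetic-session generator

Because the original videos are not needed to validate any of the above,
the package ships a generator that produces sessions with the statistical
structure the analysis assumes, with full ground truth, in the exact
input dialects of the readers. Its defaults are the study conditions:

| parameter | default | note |
|---|---|---|
| fps | 294.1 | acquisition rate |
| phase duration medians | 0.30 s holding / 0.25 s oromanual | lognormal, sdlog 0.3 |
| L levels | 5.1 / 2.7 mm (holding / oromanual) | the mode separation axis |
| D levels | 5.3 / 6.0 mm | modest widening during handling; the modes separate mainly along L |
| transition ramp | 50 ms (10–90%, logistic) | |
| regrip pulses | 1.5 mm, sigma 7.2 ms (FWHM ≈ 17 ms) | bursts of 1 + Poisson(0.7) pulses at 65 ± 5 ms, 75% of oromanual phases, ~2 Hz overall |
| per-pulse asymmetry | Uniform(−0.8, 0.8) | splits the pulse between hands as (1±a)/2 |
| sniff dips | 3 mm deep, sigma 34 ms (FWHM ≈ 80 ms) | 30% of holding phases ≥ 0.3 s, 120 ms before phase end, never closer than 300 ms |
| tracking noise | 0.02 mm isotropic | |
| dropout rate | 0.001 per sample | masked, low likelihood |

Values without a stated source above are the package's own choices of
realistic magnitudes (slow posture jitter 0.08 mm on a ~0.3 s timescale,
theta wander sd 3°, mm_per_px 0.05) made once and kept.

The embedding is constructed so that recomputing L, D and theta from the
emitted noiseless coordinates reproduces the latent series *exactly*
(≤ 1e-9 mm): the snout is fixed, the D3 midpoint is placed L below it,
and the D3s sit ±D/2 along the direction given by theta; each regrip
pulse displaces the two D3s along the inter-D3 axis with shares (1+a)/2
and (1−a)/2, which both adds the pulse to D exactly and makes the
asymmetry index recover a exactly in the noiseless limit. The ventral
view is an independent projection whose latent trace is a holding-level
baseline carrying the sniff dips — the geometry the sniff analysis
operates on — rather than a re-projection of the front view's phase
alternation (the views are analyzed independently, and the original
workflow's manual curation of sniff candidates is not part of the
automated detector).

### What passing tests do and do not show

The generator emulates two-state alternation, burst transients, dips,
tracking noise and dropouts. It does not emulate occlusions with
structured (non-isotropic) errors, pro/supination of the hands, seed-size
effects, slow drifts of the animal in the frame, or inter-animal
variability beyond seed-to-seed sampling noise. Parameter recovery on
synthetic sessions therefore validates the *computations* — detectors
recovering planted events, clustering recovering planted modes,
statistics matching exact enumerations — not the biological claims about
real mice.

Detector benchmarking uses one protocol worth stating: ground-truth
events whose peri-event samples fall in masked (dropped-out) data are
excluded from the recall denominator, because masked sections are
excluded from analysis by design and an event recorded only in masked
data is unobservable. Precision counts every detection.

## Numerical choices and degenerate inputs

* Frame indexing is 0-based; segment intervals are half-open; frame i is
  at time i/fps.
* Angles are degrees in (−180, 180]; exact −180 wraps to +180, and D = 0
  (coincident D3s) gives a missing theta.
* Crossing detection (FWHM, rise time) interpolates linearly between
  samples; "last crossing before the transition" disambiguates multiple
  crossings.
* Slopes are maximum absolute single-frame finite differences times fps —
  the simplest estimator at ~3.4 ms per frame.
* k-means on fewer distinct points than k is truncated; an all-identical
  sample is flagged degenerate with k forced to 1. Quick-TRANSfer
  warnings from heavily duplicated data are muffled (the lowest-SSE
  replicate is kept regardless).
* The signed-rank test drops zero differences and mid-ranks ties; an
  all-zero difference vector signals an undefined result rather than a
  fabricated p-value.
* The exact Mann–Whitney enumeration cap (n₁+n₂ ≤ 14) keeps the
  combinatorics at ≤ 3432 arrangements; beyond it the tie-corrected
  normal approximation with continuity correction takes over.

## Problem sizes in the shipped analyses

The numbered scripts under `analysis/` simulate eight 120 s sessions
(~35,000 frames each) and push them through every stage; the test suite
uses 10–120 s sessions and closed-form or enumerated oracles at small n.
These sizes give stable medians (hundreds of regrips, tens of sniffs per
session) while keeping any single script in the seconds-to-a-minute
range.

## Known limitations

* No 3D reconstruction: each camera view is analyzed independently.
* The ethogram text dialect is fixed (`frame,phase,grip_left,grip_right`,
  codes O/H); annotation files from other tools need a one-line
  conversion.
* HDF5 tracking containers are not read; export the CSV dialect.
* Sniff candidates are not curated automatically; an exclusion list can
  be applied downstream where manual review is part of a workflow.
* The bounded-support density estimator uses plain kernel truncation;
  contours hugging 0 mm would differ slightly under a boundary-corrected
  transform.
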