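---
title: "Classifying dredge fishing activity and mapping landings-value exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dredge fishing activity and mapping landings-value exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dredgetrack)
```

## The problem

Offshore wind planning needs to know how much fishing revenue is at stake
inside candidate lease areas. The available fishery-dependent data differ
wildly in resolution: AIS transponders report positions roughly once a
minute but only for part of the fleet; VMS polls arrive every 30–60 minutes;
a vessel trip report (VTR) carries a *single* self-reported location for an
entire trip, typically the first or last tow and therefore biased toward
shore. None of these says directly when the vessel was actually fishing.

`dredgetrack` implements a layered answer for a scallop-dredge fleet:

1. classify each 1-minute AIS position as *fishing* or *transit* with a
   random forest trained on observer-verified hauls;
2. fall back to a 5-knot speed rule on VMS polls for trips without AIS, and
   to a probability-raster "fishing footprint" around the VTR point for
   trips with neither;
3. spread each trip's landed ex-vessel value evenly over its fishing
   locations, rasterize everything onto a common 500 m grid, and summarize
   dollars inside lease polygons.

## The classifier

For each resampled ping the package computes eleven candidate features on a
centered 15-minute window: mean and SD of speed over ground, straight-line
(geodesic) and cumulative travel distance, mean and SD of sampled depth,
mean absolute consecutive course change, signed start-to-end course change,
moon illumination, month, and day of week. A dredge vessel tows at 4–5
knots while turning hard and retracing ground; a steaming vessel holds
course near 9 knots — so speed variability and turning statistics carry
most of the signal.

The forest follows the standard recipe: K trees, each grown on a bootstrap
sample of size N, each split choosing the best of `m_try` randomly drawn
features, nodes grown to `min_node`; prediction is a majority vote and
out-of-bag (OOB) error is computed from trees that did not see each sample.
The ensemble is backed by `ranger`; `fishing_forest()` pins down the
contract (vote fractions, tie handling, normalized importances) and the
test suite verifies predictions against explicit traversal of the stored
trees.

Three methodological choices deserve emphasis because they are easy to get
wrong:

* **Cross-validation is grouped by trip.** Adjacent 1-minute pings are
  near-duplicates; folds that split a trip leak and inflate accuracy. All
  tuning, feature-elimination and holdout statistics in this package use
  trip-grouped folds.
* **Class-vote ties classify as fishing.** The downstream use is value
  attribution; over-attributing is preferable to silently dropping a
  trip's value.
* **Recursive feature elimination** drops the least-important feature
  iteratively and returns the smallest subset within 0.005 of the best
  cross-validated accuracy. With strongly informative speed features the
  curve is flat, so the rule tends to keep most candidates; that is the
  intended behavior, not a failure to prune.

Hyperparameters are tuned by grouped-CV AUC over a grid of ensemble size
and depth, with ties broken toward fewer trees and shallower depth. The
reporting metrics are accuracy and balanced accuracy from the 2x2
confusion table.

## Exposure accounting

`triage()` assigns every trip to exactly one tier — AIS if usable
high-resolution coverage exists, else VMS, else VTR — which is what makes
the final raster free of double counting. Two further rules keep dollars
conserved end to end:

* a trip whose classifier (or speed rule) finds *no* fishing locations is
  demoted to the next tier rather than losing its value;
* footprint rasters are normalized to sum to one after truncation and
  clipping, so multiplying by trip value conserves it exactly.

The exposure grid is a metric UTM grid (zone of the study-area centroid,
hand-implemented transverse Mercator verified against an independent
series expansion to sub-millimetre), origin snapped to 500 m multiples,
cells half-open, polygon membership by cell center. All of these are
conventions the cell sums genuinely depend on, so they are fixed and
documented rather than left to a library default. Rasters travel as plain
ESRI ASCII grids; polygons as GeoJSON.

## Comparison diagnostics

* `cutoff_accuracy()` scores the 5-knot rule against observer labels.
* `haul_raster()` + `footprint_ols()` evaluate a trip's footprint against
  the cells its observed hauls actually crossed, by no-intercept OLS of
  the binary haul indicator on the footprint probability. The predictor is
  rescaled by the haul-cell count so that a footprint concentrated
  uniformly on exactly the haul cells scores slope 1 and a fully misplaced
  one scores 0; the fleet-mean slope then reads as a fraction correct.
  The regression's variable roles and scaling are a documented package
  choice reproducing those limiting cases. Note that a no-intercept slope
  is not bounded by 1: a broad footprint centered exactly on compact hauls
  scores above 1, which arises for synthetic footprints whose reported
  point is itself a haul start.
* `intrusion_analysis()` compares, trip by trip, the dollars the point
  product and the footprint product place in each lease (difference =
  footprint minus point product; trips match when all per-lease
  differences are under $0.01; summary SD uses the sample convention).
* `cell_value_kde()` estimates the density of positive cell values inside
  a lease (Gaussian kernel, Scott's rule-of-thumb bandwidth). Display
  thresholds used in maps are plotting options, not part of the statistic.

## The synthetic fleet

Real inputs of this kind are confidential, so the package ships a
generator that emulates them and serves as the fixture for every test.
Each trip is a two-state semi-Markov walk at 1-minute resolution:

* speeds are AR(1) around the state mean (transit 9 ± 1 kn, dredging
  4.5 ± 1 kn, lag-1 correlation 0.6 — the stationary marginal is exactly
  the configured normal, so the 5-knot rule's error rate is analytic);
* headings are a correlated random walk, 2°/min noise while steaming
  against 25°/min while towing, with a weak tether toward the tow-ground
  center;
* dredging bouts last Exp(170) minutes (min 20) separated by Exp(4)-minute
  repositioning legs; 60-minute steaming legs open and close the trip;
  trips last 10–16 h. Tow grounds sit 4–13 km seaward of the state-waters
  line and tow targets are capped 2.5 km south of it, since the fishery
  operates under the federal plan.

Observation products are then degraded from the truth: AIS is the 1-minute
track with 3% random dropout (for AIS-equipped vessels, 45% of the fleet);
VMS keeps the first ping of each 60-minute bin; observers cover 7% of AIS
trips by default; the VTR point is the first haul's start (the
shoreline-biased convention); landed value is the sum of per-haul values
(normal, $4000 ± $1200, truncated at $200); footprints are isotropic
Gaussians (SD 8 km) around the VTR point. A bathymetry grid (positive
down, deepening offshore), a synodic moon-illumination table, square lease
polygons over the grounds and a state-waters exclusion strip complete the
inputs.

Under these defaults the speed distributions overlap enough that the
5-knot rule misclassifies over a quarter of analyzed locations, while the
windowed forest stays near-perfect away from state-transition boundaries —
the qualitative contrast the method exists to demonstrate. What the
simulator deliberately does *not* model: port geography and harbor
steaming, drifting or gear-handling states beyond the binary pair,
currents, transponder physics, scallop biology. Passing tests therefore
show the pipeline's accounting and the classifier's behavior under
controlled overlap, not field performance on real fleets.

## Numerical choices and degenerate inputs

* Course interpolation unwraps headings to a continuous angle before
  linear interpolation (midpoint of 350° and 10° is 0°, not 180°).
* Resampling never interpolates across gaps longer than 30 minutes
  (configurable); segments split instead, and a single-ping trip is
  returned unchanged with a warning.
* Rolling SDs from cumulative sums clamp variances below the two-pass
  cancellation floor to exact zero, so constant windows report SD 0.
* Windows are centered, clipped at segment ends, and flagged invalid below
  5 pings; flagged pings are excluded from training and prediction.
* Exclusion masking removes strictly-interior points; boundary points are
  retained. Duplicate (vessel, timestamp) rows keep the first occurrence.
* Timestamps are UTC throughout; calendar features use a configurable
  timezone (default UTC).

## Problem sizes used by the validation suite

The packaged checks run a 216-trip fleet (18 vessels, 12 trips each, all
AIS-equipped, 55% observer coverage, about 110 labeled trips and 10^5
one-minute pings), tune over a {100, 300} trees x {8, unlimited} depth grid
on a 40-trip subsample with 3 grouped folds, and sweep five seeds for the
recovery checks. These sizes were chosen so the full suite exercises every
stage at statistically meaningful scale while staying comfortable on a
single CPU; the generator accepts larger fleets unchanged.

## Known limitations

* The two-state behavior model cannot reproduce the much lower speed-rule
  accuracies reported for real fleets, where slow non-fishing activity
  (drifting, gear work) dominates the rule's errors; on synthetic fleets
  the rule fails mostly on slow-tail dredging pings.
* Even value distribution within a trip concentrates estimate error where
  classification errors cluster (bout boundaries); in-lease exposure can
  run a few percent high for leases abutting masked areas.
* Footprints here are synthetic Gaussian stand-ins for externally modeled
  products; when real footprint rasters are available they should be read
  in as ASCII grids and used directly.
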