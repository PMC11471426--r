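---
title: "Modeling squamate climate-niche change with nichecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling squamate climate-niche change with nichecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The problem

Lizards and snakes are ectotherms whose range limits are strongly set by
temperature and moisture, which makes their *fundamental climate niche* —
the region of climate space in which persistence is physiologically
plausible, ignoring biotic interactions and dispersal — a tractable and
management-relevant quantity. `nichecast` implements a complete pipeline for
estimating per-species climate-niche space from occurrence records and
monthly climate surfaces, projecting it under alternative climate
scenarios, and summarizing how niches move: pixel-level gain/loss
accounting, expansion/shift/contraction classification, centroid
displacement, stacked richness, and state-level turnover and elevation
shifts.

Because the real inputs (millions of occurrence records, continental 1-km
climate rasters) are large and external, the package pairs the analysis
pipeline with a first-class synthetic-data module: spatially autocorrelated
monthly climate grids across six time-by-climate scenarios, virtual species
with *known* niches, and occurrence samples seeded with realistic data
defects. Every downstream stage is exercised and validated against that
known ground truth.

## The model

### Single models and the true skill statistic

For a species with presence cells $P$ on the recent-scenario grid, we draw
two replicates of pseudo-absence cells uniformly from the background
(excluding presence cells), and split presences and pseudo-absences 70/30
into train/test partitions twice per replicate — four evaluation runs. Each
registered technique is fitted per run on the 24 monthly predictors
(`tmean_01..12` in °C, `prec_01..12` in mm):

* `glm` — logistic regression, linear in the 24 predictors;
* `rf` — a probability random forest (`ranger`);
* `sre` — the surface range envelope, a rectilinear climate envelope that
  scores a cell 1 iff every predictor lies within the $[q, 1-q]$ quantile
  interval of the training presences (default $q = 0.025$);
* `gam` — optional: a binomial GAM smoothing the predictors most correlated
  with the response.

The registry is open: `register_technique()` accepts any
fit function returning an object that predicts suitabilities in $[0,1]$.

Each fit is scored on its held-out split by the **true skill statistic**,
$\mathrm{TSS} = \text{sensitivity} + \text{specificity} - 1$, maximized
over candidate thresholds (the sorted unique predicted values, cells
counted present at scores $\ge$ the threshold; ties break toward the
smaller threshold, preferring the wider predicted range). TSS is
prevalence-insensitive, which matters when absences are pseudo-absences.

### The TSS-weighted ensemble

Single models with $\mathrm{TSS} > 0.7$ become ensemble members (at least
three are required; otherwise the species is flagged non-ensembleable).
The ensemble prediction is the weighted mean
$\hat p = \sum_i w_i p_i$ with $w_i = \mathrm{TSS}_i / \sum_j \mathrm{TSS}_j$.
The source methodology says only "weighted means" — proportionality to TSS
is the simplest faithful reading, and the weights are stored on the model
object so any run can be audited. Envelope members contribute their binary
scores to the mean. The ensemble is evaluated on the pooled held-out data
of all four runs; the threshold that maximizes pooled sensitivity +
specificity is fixed there, once per species, and reused unchanged for
every scenario projection (a model fitted to recent climate is projected,
not refitted).

Permutation **variable importance** is $1 - \mathrm{cor}(\hat p,
\hat p_{\pi(v)})$, averaged over permutations of variable $v$ and clipped
to $[0,1]$; it is measured on a capped (1000-row) seeded subsample of the
modeling data, where the scores are already stable.

### Range change accounting

Binary maps of two scenarios decompose into pixel counts Loss (suitable
only before), Gain (suitable only after), and Maintain (both). With
$C = L + M$ the current and $F = G + M$ the future range size:

$$\text{lost\%} = 100\,L/C,\qquad \text{gained\%} = 100\,G/C,\qquad
\text{range change} = \text{gained\%} - \text{lost\%} = 100\,(F - C)/C.$$

Percentages are carried unrounded and rounded to 2 decimals only at export
— required to reproduce the published table (e.g., a range change of
−75.15 that is *not* the difference of the rounded percentages). Change
classes use a ±10% dead band on net change and a 50% turnover cut:
net ≥ +10% is *expand* (turnover ≤ 50%) or *shift* (turnover > 50%);
net ≤ −10% is *contract*; within the dead band, a centroid displacement
beyond 100 km (configurable; the source gives no value) distinguishes
*stable_shift* from *stable*. Centroids are unweighted means of suitable
cell centers (binary maps carry no abundance), and bearings are measured
clockwise from grid north.

Richness maps stack binary projections; richness change under *no
dispersal* masks each species' gains outside its recent range (so the
change layer is nowhere positive), while *full dispersal* counts them.

### Jurisdiction summaries

Jurisdictions tile the grid; a species is *present* in one when strictly
more than 50 suitable pixels fall inside. Turnover compares presence calls
between scenarios (gained / lost / maintained / absent). Elevation shifts
within a jurisdiction compare the 25th–75th percentile interval of the
suitable cells' elevations between scenarios: disjoint intervals are a
significant increase or decrease, overlapping ones are "similar".
Quantiles use the linear-interpolation convention (R's default), stated so
results are reproducible.

## The synthetic world

`generate_climate_grids()` builds the recent scenario from smooth Gaussian
random fields (white noise convolved with a Gaussian kernel whose standard
deviation is the configured autocorrelation length, 10 km by default, via
circular FFT convolution): monthly temperature is a sinusoidal annual
cycle (July warmest, amplitude 11 °C) over a northward-cooling
(0.05 °C/km), elevation-lapsed (6.5 °C/km) mean surface plus shared and
month-specific autocorrelated noise; precipitation is a winter-wet
log-normal surface. Elevation is a west–east ramp (100–1600 m) with smooth
relief. Sharing the noise fields across months yields the realistic,
strongly correlated predictor set that ensemble SDMs face in practice.

Every other scenario differs from recent *only* by a constant temperature
offset and precipitation multiplier, so scenario deltas are exact by
construction. The source does not state its scenarios' climate deltas, so
they are configuration with defaults chosen once at realistic magnitudes:
past −0.5 °C; mid-century +1.5 / +2.0 °C and late-century +2.0 / +3.0 °C
for the moderate / high pathways, with precipitation multipliers 1, 1,
0.98, 0.95, 0.95, 0.90.

Virtual species respond to a few named climate variables with Gaussian
curves combined by product, so true suitability is 1 at the joint optimum
and declines monotonically away from it. `calibrate_virtual_species()`
places optima at chosen quantiles of the recent climate and bisects a
common breadth factor until the *true-suitable region* (suitability ≥ 0.5)
matches a target prevalence. Occurrence sampling draws cells without
replacement with probability proportional to suitability within that
region — so a no-artifact sample lies entirely inside the true niche while
still concentrating in its core — and injects defects at configured rates:
duplicate cell records, missing years, records snapped within 300 m of a
jurisdiction centroid, and far outliers placed ≥ 200 km outside the
species' true-suitable hull. Ground-truth labels ride along, so the QC
filters can be audited record by record.

What the generator does *not* emulate: observation bias correlated with
accessibility, spatial clustering of survey effort, taxonomic error beyond
the grouping map, non-Gaussian niche shapes, and climate-change patterns
more structured than uniform offsets. Passing recovery tests therefore
demonstrate that the pipeline recovers known niches under clean,
well-specified conditions — not that real occurrence data meet those
conditions.

## Validation experiments and problem sizes

Two experiment drivers validate the pipeline end to end at desk scale:

* `recovery_experiment()` — 200 × 200 grids, species with prevalence drawn
  from 0.1–0.3, 500 presences, 2000 pseudo-absences per replicate, three
  techniques, five seeds. It reports the ensemble's pooled held-out TSS
  and the Jaccard overlap between the recovered binary map and the true
  suitable region.
* `directional_experiment()` — 100 × 100 grids, a cold-limited species
  (thermal optima at the cooler 30th percentile), four techniques (the
  GAM's smooth terms are what carry the bell-shaped response across
  scenarios; without it the recovered future ranges undershoot), ten
  seeds. It reports
  whether the recovered niche's centroid moves north under the +3 °C
  late-century scenario and whether within-state suitable elevations shift
  significantly upward. Elevation is judged per jurisdiction: a 16-region
  Voronoi partition mirrors the real analysis' state-to-domain size ratio
  (47 states from Canada to Mexico), and grid-wide elevation distributions
  of a diagonally oriented suitable band are too wide for the
  interquartile test even on the true niche — the state scale is where
  that test has resolution. A seed counts as an elevation increase when at
  least one state where the species stays present (> 50 pixels in both
  scenarios) shifts significantly up and none shifts down.

These sizes are the package's demonstration scale; all of the machinery
(50,000 pseudo-absences, eight techniques, 130 species) scales by
configuration.

## Numerical and design choices

* **Deduplication tie-break** (unstated in the source): keep the earliest
  year, then the lexicographically smallest source label — deterministic
  and auditable.
* **Distance conventions**: "within 300 m" of a centroid is strict (<);
  "≥ 200 km" from a range polygon is inclusive, matching the source's
  symbols. All distances are planar Euclidean in the km coordinate system;
  the synthetic grids are equal-area by construction.
* **Binarization** is inclusive (suitable at values ≥ threshold) and the
  threshold, chosen on recent-scenario held-out data, is clamped away from
  {0, 1} before reuse.
* **Pseudo-absences exclude presence cells** — at desk scale the label
  noise from sampling presences as background is material, and exclusion
  keeps the permutation null clean.
* **Degenerate cases are flagged, not guessed**: all-equal prediction
  scores give TSS 0 with a degeneracy flag; empty niches make centroids
  and elevation comparisons "undefined"/"not comparable"; an empty current
  range makes the change class "undefined".
* **Determinism**: every stochastic step takes an explicit seed; the
  pipeline's manifest records the seeds and thresholds that produced its
  outputs, and rerunning a config reproduces its tables byte for byte.

## Known limitations

Projection to future climates applies no extrapolation mask: cells with
climates outside the training envelope are scored by each technique's
native extrapolation behavior (the envelope scores them 0, the forest
saturates, the GLM extrapolates its logit). The ensemble weighting,
variable-importance algorithm, and pseudo-absence/presence overlap policy
are explicit substitutes for choices the source methodology leaves
unstated. The centroid is an unweighted binary-map mean rather than a
suitability-weighted center of gravity. None of the paper-scale results
that depend on the real occurrence and climate data (continental richness
patterns, state agreement rates, absolute shift distances) are
reproducible from the synthetic world, and the package does not attempt
them.
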