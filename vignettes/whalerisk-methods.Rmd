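---
title: "Methods: ensemble habitat suitability and whale-vessel encounter risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat suitability and whale-vessel encounter risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(whalerisk)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical conventions used throughout.

## Grids and spatial conventions

Analyses run on two regular grids: a fine modelling grid (the 10 km-scale
grid on which sightings are binarized and suitability is projected) and a
coarse 1° analysis grid (incidents, vessel hours, risk). Cells are half-open
intervals `[west, east) × [south, north)`, so a point on an interior cell
boundary belongs to the cell whose west/south edge it lies on, and the
outermost east/north boundary belongs to the last cell; every point in the
extent therefore maps to exactly one cell, independent of input order. Cell
ids are 1-based and row-major from the south-west corner — the natural
convention in R, and invisible externally because all file output carries
centroid longitude/latitude rather than indices. The fine grid can be
declared in degree or planar-km mode; the mode only labels units (tests use
degree mode so results are projection-free), and regridding across modes is
refused rather than guessed.

Regridding fine → coarse takes the mean of fine-cell values whose centroids
fall in each coarse cell (mean ensemble HSV per 1° cell); coarse cells that
receive no fine centroid are masked out rather than zero-filled.

Surfaces interchange as long-format CSV (`cell_id, lon, lat, value`),
written at full precision so a round-trip is bit-stable.

## The synthetic study system

Every externally sourced input of the real analysis has a generator with
known ground truth, each a pure function of its parameters and a seed:

* **Environment** — SST, SSS and NPP as Gaussian random fields
  (FFT-smoothed white noise; the kernel sd in cells is the autocorrelation
  length, default 4) plus a deterministic south-to-north SST gradient and a
  western coastline with a shelf sloping to abyssal depths. Future periods
  are `present + delta + small-scale noise`; the default deltas (+1/+2 °C
  SST, −0.2/−0.4 ppt SSS, −5/−10 g C m⁻² yr⁻¹ NPP for the near and mid
  future) are plausible magnitudes for a doubling-CO₂ trajectory over a few
  decades. The fields are periodic at the domain boundary, which is
  harmless at the domain sizes used and keeps the smoother exact.
* **Species truth** — logistic suitability on z-standardized covariates.
  The default coefficients give each species a sharply defined, relatively
  rare niche (roughly 10–25% of ocean cells appreciably suitable).
  This sharpness is deliberate: discrimination between presences and a
  random background is bounded above by one minus the suitable fraction of
  the domain, so a system in which ensemble members score high TSS — as the
  emulated system does — is necessarily one where each species' suitable
  habitat is a small part of a large modelled domain. Early, broader-niche
  defaults capped member TSS near 0.65 regardless of sample size.
* **Sightings** — cells drawn with probability proportional to
  suitability × effort, jittered uniformly within the cell. Effort decays
  with distance to the nearest land cell as `exp(-d/λ)` (λ = 25 cells),
  emulating the coastal bias of opportunistic observation.
* **Vessels** — a sum of Gaussian hotspots times lognormal noise with mean
  one; optionally rescaled to an exact target total.
* **Incidents** — zero-inflated negative binomial counts whose log-mean is
  either the covariate form `β0 + β1·V + β2·HSV` or the risk form
  `a + b·E`, so both downstream regressions have matched truths. The
  realized parameters ride along as an attribute for recovery tests.
* **Acoustic receivers** — Bernoulli detections with success probability
  equal to the local suitability.

What the generator does *not* emulate: ocean circulation, actual
climate-model statistics, whale movement and migration, seasonal structure
within a period, and reporting lags in incident locations. Tests passing on
this synthetic system therefore validate the statistical machinery and its
implementation — not the ecological fidelity of any particular real-world
fit.

## Ensemble species distribution models

Covariates with pairwise |r| above 0.7 are removed greedily (largest mean
absolute correlation first, ties alphabetical — a deterministic rule, since
greedy collinearity pruning is otherwise order-dependent). Pseudo-absences
(default 10,000) are drawn uniformly without replacement from ocean cells
excluding presences, once per species and shared across members and
cross-validation repeats; sharing isolates differences between member
families from background-sampling noise. Covariate standardization (z-score)
is computed once on the training cells and reused for all projections.

The three members are a binomial GLM with linear and quadratic terms; a
probability random forest (class-1 vote fraction, 300 trees by default);
and a maximum-entropy model in its penalized-logistic form — an L1-regularized
logistic regression of presences against the background with linear,
quadratic and pairwise-product features, regularization strength chosen by
internal cross-validation. All members emit scores in [0, 1].

Cross-validation is stratified 80/20, repeated five times. The TSS
threshold is optimized on each evaluation split (the source protocol names
no threshold); the optimizer scans the unique score values, classifying
`score ≥ t` as presence. Members with mean TSS above 0.7 enter the
ensemble, weighted by mean TSS normalized to sum one; if none qualifies the
fit fails loudly, naming the best member and its score. The ensemble's own
TSS is computed by the same repeated-split protocol applied to the weighted
score (refitting members per split), because the provenance of a single
"ensemble TSS" number is otherwise ambiguous.

Variable importance generalizes random-forest mean-decrease-accuracy to the
ensemble: permute one covariate across rows, record the drop in ensemble
TSS at the fixed optimized threshold, average over ten shuffles; rank 1 is
most important, ties break by larger raw decrease then name.

Projection onto a period standardizes that period's covariates with the
*training* statistics and flags any cell where a covariate leaves its
training range (clamping report); fitting on the whole domain and cropping
afterwards is the supported way to keep that report small.

## Encounter risk

`W = HSV/ΣHSV` and `B = V/ΣV` are discrete occupancy distributions over the
masked study cells only, under the assumption that suitability scales
linearly with relative occupancy probability. `E = W·B` elementwise. Both
normalizations of E are implemented because both are legitimate readings of
the method: min-max (`range01`) for hotspot maps, sum-to-one (`sum1`) for
comparing surfaces as distributions; the mode is recorded on the output.
Normalization is per species × period (not joint across periods), which
keeps each map self-contained; cross-period comparisons should use `sum1`.
Future periods reuse the present vessel surface — the stable-vessel-activity
assumption, made explicit by passing a period label.

## Incident models

The count regression is zero-inflated negative binomial (log link,
intercept-only logit zero component, fitted via `glmmTMB`), with a plain NB
fit available side by side — the over-dispersion and zero excess in
incident counts motivate ZINB, but the nested NB fit is the natural check
that zero inflation is doing real work (their likelihoods must nest, and
with π = 0 truths the count coefficients agree within sampling error).
Covariates enter untransformed; coefficients are reported on the original
scale. An optional outlier pass (drop |Pearson residual| > 4, refit) is off
by default and logged when used — the source protocol removed outliers
without stating a rule, so ours is explicit and opt-in.

The risk regression is Poisson on cells with at least one incident —
zero cells are unidentifiable against absent observer effort. Restricting
to occupied cells is a zero-truncation, which biases estimates when the
mean count is small; simulation settings for calibration tests therefore
keep per-occupied-cell means comfortably above one. Explained variance is
the deviance pseudo-R², `1 − D_model/D_null`, a documented choice among
several pseudo-R² definitions.

Moran's I uses row-standardized queen contiguity (all eight neighbours) and
a two-sided permutation p-value (999 reshuffles of residuals across cells)
rather than the normal approximation; with row-standardized weights
`I = Σ w_ij z_i z_j / Σ z_i²` and `E[I] = −1/(n−1)`.

## Overlap statistics and the permutation null

Schoener's D and Warren's I internally renormalize both inputs to sum one,
so they are invariant to positive rescaling and symmetric. The incident
surface is compared as a distribution (counts normalized to sum one)
against sum-normalized E — the two must be on the same footing for |p − q|
to mean anything. Spearman's ρ uses average ranks for ties and, by default,
only cells with ≥ 1 incident, matching the Poisson regression's
restriction.

The significance test permutes the *vessel* values across study cells
(sampling without replacement), recomputes `B → E → normalized E` and the
statistic each time (1,000 permutations), and declares significance when
the observed value falls outside the 2.5–97.5 percentile range — the
percentile rule exactly, with no smoothing. Permutation happens on the 1°
surface (permuting raw point data before aggregation would break the
cell-level exchangeability the null requires). Degenerate situations — a
constant vessel surface, too few permutations to place the 2.5% tails, or
undefined statistics — are flagged `unstable` and never reported
significant.

## Pipeline orchestration

`run_pipeline()` drives the full chain from one validated config (list or
YAML): schema violations name the offending field; every stochastic stage
derives its seed deterministically from the master seed; outputs are CSV
tables and surfaces plus a JSON manifest of md5 checksums. A rerun with an
unchanged config and intact outputs is skipped wholesale, which is the
coarse but honest reading of incremental re-execution: stage-level
memoization would require hashing intermediate objects whose serialized
form is not guaranteed stable across R versions.

## Problem sizes and test design

The test suite and acceptance script run at deliberately scaled-down sizes
chosen to exercise every code path at comfortable margins: the demo
pipeline uses a 45 × 36 fine grid, 1,500 sightings and 900 pseudo-absences;
suitability-recovery checks use a 160 × 160 domain with 2,000 presence
cells and 10,000 pseudo-absences (the niche-rarity regime described above);
ZINB recovery uses 100 simulated 400-cell grids; permutation calibration
uses 200 outer replicates of 100 permutations; null-p uniformity uses 500
replicates. Member forests use 150–300 trees in tests; accuracy is
insensitive to this at these covariate counts.

## Known limitations

* The MaxEnt member is the penalized-logistic formulation, not a port of
  the reference Java implementation; equivalence is structural, not
  numerical.
* Pseudo-absence contamination (background cells that are truly suitable)
  caps attainable TSS; the package reports what the data support rather
  than correcting for contamination.
* The effort model is a single exponential coastal decay; real observation
  effort has structure (ports, survey tracks) the generator does not
  represent.
* Cell areas are treated as equal within a grid; at 1° over the latitudes
  of interest the distortion is modest but real, and no geodesic
  correction is applied.
* Winter occurrence is out of scope: the emulated sightings regime is
  spring–fall.
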