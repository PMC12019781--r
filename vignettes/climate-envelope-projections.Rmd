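---
title: "Climate-envelope projections of tree species under AMOC-collapse scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-envelope projections of tree species under AMOC-collapse scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envelopeshift)
```

## The problem

Forests respond to climate on the scale of decades, so the question of which
tree species will still find a suitable climate at a given place by the end
of the century is central to forest planning. A collapse of the Atlantic
Meridional Overturning Circulation (AMOC) would superimpose a strong,
north-weighted cooling and drying on top of greenhouse-gas warming,
producing combinations of conditions that neither trend alone would reach.
`envelopeshift` implements a complete projection chain for this question —
from monthly temperature and precipitation grids to per-species occurrence
probabilities and assemblage-level change statistics — together with a
synthetic-data generator that makes every stage testable without any
external downloads.

## The model chain

### Climate preparation

Observed monthly climate on a coarse grid is transferred to a fine analysis
grid by **change-factor downscaling**: temperature anomalies relative to a
coarse 12-month climatology are added to a high-resolution climatology;
precipitation uses the analogous ratio, capped at 5 and forced to 1 where
the coarse climatology is below 1 mm so that arid months cannot blow up the
ratio. Climate-model series are then bias-corrected per cell and calendar
month by **empirical quantile mapping**: quantiles of the model and observed
series over a calibration window (default 1951–2014) are paired on a ladder
of 99 probabilities (0.01–0.99) with linear interpolation in between.
Values beyond the calibrated range receive a constant additive correction
(temperature) or a constant ratio (precipitation); this keeps projected
trends intact — a +4 degC model signal stays a +4 degC corrected signal —
while avoiding unstable extrapolation. Twelve independent transfer
functions per cell preserve the monthly resolution of the correction. The
mapping dialect (empirical, 99-point ladder, constant-boundary tails) is a
declared choice: it is the standard empirical dialect that is stable at
30–64 samples per month.

### AMOC anomalies

A collapse is represented by twelve monthly additive surface-air-temperature
anomaly fields (SAT, degC) and twelve relative precipitation anomaly fields
(RPA, a fraction, never below −1). They are regridded (bilinear by default;
the source maps are coarse and smooth) and applied as a step change over one
climate normal, by default 2071–2100: temperature gains the matching month's
SAT, precipitation is multiplied by `1 + RPA`. Whether a real collapse
would ramp in earlier is unknowable from the data the overlay consumes; the
step-change convention is documented and confined to `superimpose_anomalies()`.

### Bioclimatic variables

From each corrected series the package derives 17 bioclimatic variables per
30-year climate normal: nine temperature aggregates (annual and
meteorological-season means, warmest- and coldest-month means, and the SD
and range of the twelve monthly means as continentality measures) and eight
aggregates of the climatic water balance CWB = P − PET (annual and seasonal
sums, driest-month CWB, SD and range). PET follows Thornthwaite: heat index
`I = sum((T/5)^1.514)` over the climatological months with `T > 0`,
exponent `a = 6.75e-7 I^3 − 7.71e-5 I^2 + 1.792e-2 I + 0.49239`,
`PET = 16 (10 T / I)^a` for positive `T` and 0 otherwise, scaled by the
standard day-length/month-length factor from solar geometry. The heat index
is computed from the period climatology — Thornthwaite's standard usage —
so that single anomalous years do not destabilise the exponent. Seasons are
meteorological; DJF borrows December from the preceding year (the first
year of a period uses the last pre-period December when the series provides
it, and otherwise drops that DJF from the average). Extremes (warmest and
driest months) are located per year and then averaged, because period-mean
climatologies mask exactly the extremes that limit species. Fourteen
scenario-periods are projected: two historic normals (1951–1980, 1991–2020),
three scenarios crossed with three future normals, and three AMOC-collapse
variants of 2071–2100.

The membership of the 17-variable catalogue is a configurable default: the
set above satisfies every constraint the method imposes (seasonal
temperature and CWB integration, two continentality measures for each, the
driest-month water balance), and `compute_bioclim()` accepts a subset
catalogue where fewer variables are wanted.

### Climate envelopes

A species' envelope is built from its presence records only. For each
candidate variable the presence values define a Gaussian-kernel-smoothed
CDF (bandwidth by Silverman's rule); the per-variable envelope probability
is the two-sided tail probability `p = 2 min(F(x), 1 − F(x))`, which is 1
at the smoothed median, falls towards the tails, and is exactly 0 outside
the presence range extended by one bandwidth. Probabilities of 2–3
variables are conflated with **Fisher's combined probability test**
(`chi² = −2 Σ ln p_i`, df = 2k). Because a zero component forces the
conflated probability to zero, projections are constrained to the historic
climate envelope by construction — the property that distinguishes this
model from regression-style SDMs, which can happily project occurrences
into climates never observed for the species.

Variable selection is exhaustive: every 2- and 3-variable subset of the
17 candidates (816 subsets) is scored by the **True Skill Statistic**
(sensitivity + specificity − 1) against balanced pseudo-absences (a
uniform, seeded sample of non-presence cells of presence size), with the
presence/absence threshold chosen on a 99-point ladder (ties to the lowest
threshold). The subset with maximal TSS wins. Subsets whose TSS lies
within `tss_tolerance` (default 0.01) of the maximum are treated as tied,
and ties resolve to fewer variables, then lexicographic order. The
tolerance matters: TSS is estimated on a few hundred points, so its
resolution is a few multiples of 1/n, and without the tolerance the
in-sample threshold optimisation lets three-variable supersets beat the
true two-variable envelope by one or two quanta of pure noise. Validation
is a single calibration with background resampling; a seeded 80/20 holdout
can be enabled by splitting the records before calling
`calibrate_envelope()`, but is not the default because verification scores
on synthetic data are already optimistic in known ways (see Limitations).

Per-model projections are averaged into ensemble means per
species × scenario-period.

### Evaluation

All assemblage statistics operate on the ensemble probability fields:

* `delta_p()` — relative change `(p_fut / p_hist − 1) · 100%`, with cells
  classified `changed` / `extinct` (to zero from presence; delta pinned at
  −100) / `expanded` / `absent`.
* `distribution_center()` — probability-weighted center of a species'
  distribution. The geometric mean is taken in a strictly positive frame
  (lon + 180, lat + 90) because geometric means of signed longitudes are
  ill-defined; an arithmetic variant is provided since neither
  interpretation can claim to be canonical.
* `dominant_species()`, `dominance_change_maps()`, `replacement_tally()` —
  which species locally dominates, how the dominant's probability changes
  (historic- and future-anchored, with `newly_colonized` and `none`
  classes), and which species replaces a locally extinct dominant.
* `shannon_h()` / `diversity_change()` — Shannon H' over each cell's
  normalised occurrence probabilities (natural log; `H' ≤ ln k`), and its
  absolute change with `disappeared` / `colonized` classes.
* `percentual_sd()` — the across-model SD in percent of the across-model
  mean (sample SD, divisor n − 1); zero-mean cells are masked.
* `anova_partition()` — per cell, a balanced two-way ANOVA of `p` against
  model and scenario; main-effect and residual sums of squares as shares of
  the total. With one observation per model × scenario combination the
  residual is the interaction. The closed form is cross-checked against
  `aov()` in the test suite.

"Zero" in the evaluation means `p ≤ zero_eps` with `zero_eps = 1e-3` by
default: kernel-smoothed envelopes rarely produce exact zeros inside the
support, and classifying on exact zeros would make the extinct/expanded
classes depend on floating-point noise. Outside the support, zeros are
exact and the epsilon is irrelevant.

## The synthetic world

`synthetic_world_config()` defines a fully seeded world: temperature
follows a latitude gradient (−0.6 degC per degree), an elevation lapse
(−6.5 degC/km over a fixed harmonic ridge surface, 0–1.5 km), a seasonal
sinusoid whose amplitude grows eastward (4–12 degC, a continentality axis),
a +0.1 degC/decade historical trend, month-specific smooth spatial
patterns (1.5 degC scale), and iid monthly noise (1 degC). Precipitation
is a smooth positive field (45–110 mm/month scale) increasing with
elevation, modulated seasonally and by month-specific patterns, with
multiplicative lognormal noise. The month-specific patterns are what make
the 17 bioclim aggregates genuinely distinct fields: without them, every
seasonal aggregate is a linear combination of two latent gradients and
variable selection cannot be well-posed. Pseudo-climate-models add known
additive temperature offsets, multiplicative precipitation factors, and
per-scenario warming/drying trends from 2015 on. AMOC anomalies follow a
power-law north–south gradient anchored at the configured maximum cooling.

Synthetic species occupy known envelopes: suitability is a product of
independent Gaussians over 2–3 named bioclim variables — deliberately the
same conflated-independent structure the envelope model assumes, so that
parameter recovery is a well-posed test. Records are distinct cells drawn
without replacement with probability proportional to suitability.

What the generator does **not** emulate: real geography and coastlines,
spatially correlated (weather-regime) noise, observation and thinning
biases in forest inventories, planted occurrences outside the natural
range, and model genealogy within the pseudo-ensemble. Passing tests
therefore demonstrate that the machinery is correct and self-consistent,
not that real-data projections are accurate.

## Study conditions and problem sizes

The default pipeline world is a 12 × 10 coarse grid (5–17°E, 44–54°N)
refined fivefold to 60 × 50 cells, with 3 pseudo-models, 3 scenarios, 6
synthetic species of 350 records; a full run takes a few minutes and is
bit-reproducible from its three seeds. The parameter-recovery experiment
(`recovery_experiment()`) uses a twelvefold refinement (144 × 120 cells)
and 20 species of 300 records — at coarser grids the suitability core of a
species holds only a few hundred distinct cells, and sampling without
replacement then saturates the core and widens the fitted envelopes
artificially. The quantile-mapping check (`qmap_match_experiment()`) uses
a 40 × 40 grid over 60 years with +2 degC / ×1.3 biases, where the
corrected calibration-period ECDFs match the observed ones to the 1/60
granularity of the empirical CDFs.

## Numerical choices and degenerate inputs

* Probability ladders (quantile mapping, thresholds) are 99-point,
  0.01–0.99; linear interpolation between entries; threshold ties resolve
  to the lowest value.
* A degenerate (constant) model quantile table — an always-dry month —
  falls back to the boundary convention; corrected precipitation is always
  floored at 0.
* Constant candidate variables are excluded from envelope fitting with a
  warning; fewer than two usable variables is an error.
* The Thornthwaite guard: cells whose climatological heat index is zero get
  PET 0 even for transiently positive months.
* All randomness flows through named seeds; no function touches the global
  RNG state without restoring it.
* Computation is double precision throughout; grid artifacts are written
  with `%.17g`, which round-trips doubles exactly.

## Known limitations

* Verification TSS is computed on the calibration sample with an optimised
  threshold, so it is biased upward; the recovery experiment shows the
  selection is nonetheless consistent under the generator's conditions.
* The TSS-optimal threshold is a classification optimum, not a
  region-calibration optimum: the `p ≥ threshold` region tends to be wider
  than the 2-tolerance truth region of a synthetic species (per-species
  Jaccard overlaps of ~0.5–0.8, mean ~0.7 under the default recovery
  conditions).
* Fisher conflation treats per-variable probabilities as independent;
  strongly correlated selected variables make the conflated probability
  overconfident. The exhaustive search mitigates this only indirectly
  (correlated pairs discriminate worse and lose).
* The AMOC overlay is a step change over one normal; composition of
  repeated overlays is multiplicative in precipitation and is not meant to
  represent a gradual collapse.
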