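---
title: "Building cumulative risk indicators: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building cumulative risk indicators: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskgrid)
```

## The model

`riskgrid` implements a screening model for cumulative environmental health
risk. The quantity of interest is a per-cell composite score

$$ C_i = \sum_{d \in \{soil, air, water, noise\}} S_d(i), $$

where each $S_d$ is a dimensionless standardized sub-indicator in $[0, 1]$.
The model is a *screening* construction, not a dose–response model: high
composite cells are candidates for multi-stressor concern, to be confirmed
by finer assessment. Three assumptions shape everything downstream:

1. **Common support.** All layers are discretized on one referent grid
   (default 1 km² cells) before any combination. Regular grids avoid the
   small-number instability of irregular administrative units.
2. **Equity.** Every dimension enters the composite with the same mean and
   range over the modelling domain, so the composite flags *co-occurrence*
   of stressors rather than the dimension with the widest raw scale.
3. **Independence of action.** Hazard quotients are summed across
   pollutants without target-organ grouping — a simplification that errs
   conservative for screening.

## From raw layers to sub-indicators

**Spatialization.** Four operations move data onto the grid, all based on
exact planar overlap areas: surface-ratio aggregation between misaligned
grids (intensive quantities are overlap-weighted means; extensive
quantities are split proportionally, which conserves totals to rounding),
zone rasterization (overlap-weighted attribute means), buffer partitioning
(each cell scores the summed fraction of its area inside 300 m discs around
sites — overlapping buffers from distinct sites *accumulate*, making the
score a site density, not a coverage indicator), and point interpolation.
For point samples we provide inverse-distance weighting (power 2 by
default) and ordinary kriging with an isotropic exponential variogram
fitted by weighted least squares; the kriging is a deliberately simple,
well-documented interpolator, not a substitute for hybrid area-to-point
geostatistics.

**Exposure transforms.** The soil concentration indicator sums
ingestion-pathway hazard quotients $HQ = ADD/RfD$ with
$ADD = C \cdot IR \cdot EF / BW$ per age class, then keeps the **maximum
over age classes** per cell. The cross-age rule is a design choice (the
natural alternatives — population-weighted or summed — understate risk for
the most exposed group in a screening context). The dose model is
single-pathway soil ingestion; richer multimedia doses can be plugged in as
precomputed fields. The air concentration indicator is
$\sum_p C_p / \mathrm{standard}_p$. The emission score min–max scales three
components (total, cancer-weighted, non-cancer-weighted emissions) to
$[0,1]$ and averages them with equal weights; the weights are exposed
because no single reading of "combining" is canonical. The water score is
the multi-year mean exceedance count per distribution unit; sub-threshold
concentrations contribute nothing, so water is hotspot-only by
construction. Noise passes the Lden field through unchanged.

Air (concentrations + emissions) and soil (proximity + topsoil HQ) are each
combined into one dimension by standardizing both components and summing —
the equity principle applied one level down — and the combined field is
then re-standardized before entering the composite, which restores a common
$[0,1]$ scale across all four dimensions.

## Standardization: transforms, ties, background

Both transforms are functions of ranks alone. With $n$ cells and fractional
rank $r$:

- percentile rank: $(r - 0.5)/n$ — the Hazen plotting position, chosen so
  scores are symmetric in $(0,1)$ and an all-distinct field has mean
  exactly $0.5$;
- normal score: $z = \Phi^{-1}\!\big((r - 0.375)/(n + 0.25)\big)$ — the
  Blom approximation to the expected standard-normal order statistic
  (within $5 \times 10^{-3}$ of the numerically integrated exact values
  after rescaling, checked in the test suite) — followed by a linear rescale
  to $[0, 1]$.

**Rescaling anchor.** The normal-score rescale is anchored at the $z$
values of ranks $1$ and $n$, not at the minimum and maximum of whatever
ranks are present. The distinction only matters when ties exist: a tied
background block sitting above rank 1 then keeps a strictly positive score,
preserving the *gap* between background and the first measured cell. Had we
rescaled over present ranks, the background would always map to exactly 0
and the gap diagnostic below would be degenerate.

**Background rule.** Cells where no measurement is possible (nodata) and —
for hotspot-type dimensions (water, noise, site proximity) — cells with
exposure exactly zero form the background. Background cells are never
dropped: they occupy the bottom $k$ ranks and each receives the averaged
rank $(k+1)/2$, so $\sum r = n(n+1)/2$ always. Zeros in concentration-type
dimensions (air, soil) are ordinary low values; the per-dimension rule is
configurable. $n$ always includes background cells: dropping them would
re-scale each dimension to a different effective domain and silently break
equity.

**Heteroscedasticity diagnostic.** Assigning one shared background score
creates a gap below the first measured cell. We measure it as
`heteroscedasticity_ratio` = background score / smallest non-background
score. Under the percentile transform this ratio has the closed form
$k/(2k+1)$ — essentially constant near $\tfrac12$ — so the informative
version uses the normal-score scale, where the ratio declines strictly as
the background fraction grows from 0.1 to 0.9 (the tied block drifts toward
the middle of the rank grid faster than the first measured cell) and tends
to 1 along growing domains with vanishing background. Both behaviours are
asserted in the test suite.

## What the two transforms do and do not change

Because both transforms see only ranks, any two tie-free sub-indicators
carry *identical score distributions* regardless of their raw marginal
shape — a heavy-tailed and a bounded dimension are exchangeable after
standardization, and their expected top-decile contributions are equal
under either transform. The transform choice therefore cannot re-weight
dimensions through marginal tail weight alone. What it does change:

- the **score-vs-raw curve**: the percentile transform smooths the extreme
  raw values (its sliding-window slope over the top raw decile is smaller
  than the normal-score slope in every tested replicate), so analysts
  reading scores against raw concentrations lose contrast among the highest
  exposures;
- the **background block's score**: middle-rank scores compress toward 0.5
  under the normal transform, so heavily background-inflated dimensions
  (noise, water) contribute systematically *more* to top-decile cells under
  normal scoring than under percentile ranking — in pipeline runs the noise
  dimension gains about 2–3 contribution points, consistently across seeds.

`transform_slope`, `contribution_above_percentile` and
`fit_rank_distribution` (moment fits of uniform/normal/logistic candidates
ranked by the Kolmogorov–Smirnov statistic, with Anderson–Darling reported
alongside) are the tools for making this choice on a given dataset.

## The synthetic region

`generate_region()` draws a complete study region with known truth, so
every stage is testable without external data. Defaults were fixed once as
the package's study conditions:

- extent 60 km × 40 km at 1 km cells (a 40 × 60 grid — large enough for
  stable decile statistics, small enough for sub-second generation);
- 800 topsoil point samples and 40 contaminated sites, matching the
  sampling density of a regional monitoring network of ~8000 points and
  ~320 sites scaled to this domain's area;
- sites clustered along a random linear "furrow" axis, emulating the
  historical co-location of industry and infrastructure along a valley;
- 2 hotspots per dimension, the first co-located across dimensions
  (an industrial source elevating several stressors at once) with peak
  height 5× the background level and radii 2–3 km;
- smoothed-white-noise background surfaces with a 5 km length scale —
  cheap, seedable, spatially autocorrelated; not an exact Gaussian-process
  draw, which matters to none of the rank-based machinery;
- noise values on exactly 10% of cells, along road corridors (the corridor
  half-width is set to the distance quantile that covers exactly the
  configured fraction); Lden between 55 and 80 dB(A);
- zero-inflated water exceedance counts over 4 years, so most units score 0;
- a heavy-tailed (lognormal) 200 m population raster concentrated near the
  furrow, and rectangular slice-and-dice district / water-unit / census
  layers that tile the extent exactly with zero overlap.

What the generator does *not* emulate: atmospheric dispersion or noise
propagation physics, geochemical covariance between metals, population
mobility, or calibration to any real region's statistics. Passing tests
demonstrate the *machinery* — discretization accuracy, equity, recovery of
injected multi-stressor hotspots (the co-located cell exceeds the composite
90th percentile in effectively all of 50 seeded replicates under both
transforms) — not realism of any single layer.

## Numerical choices

- Half-open grid cells, row-major top-left indexing: no double counting on
  shared edges.
- Polygon–cell overlaps by Sutherland–Hodgman clipping against the cell
  rectangle (exact for simple polygons against a convex window); buffer
  discs as 512-gon polygons with the radius inflated so the polygon area is
  exactly $\pi r^2$ (boundary error < $10^{-4} r$); all overlap code is
  cross-checked against a $10^5$-point Monte-Carlo sampling oracle in the
  tests.
- Kriging: variogram parameters are clamped (range ≤ 3× the maximum binned
  lag, sill ≤ 10× the sample variance) and the covariance diagonal carries
  a $10^{-6}$ relative ridge — unbounded fits explain short lags equally
  well but make the kriging system numerically singular.
- Duplicate sample locations are averaged (with a warning) before kriging.
- Empirical quantiles use R's default type 7; cells *strictly above* the
  threshold are selected, ties at the threshold excluded.
- Census-block aggregation assigns each cell to the single block with the
  largest overlap (no fractional splitting); zero-population blocks fall
  back to the unweighted mean and are flagged rather than dropped.
- Contributions are the mean over selected cells of the cellwise share,
  which preserves the sum-to-100 property exactly; a pooled-sums variant is
  available.
- Correlation diagnostics default to standardized sub-indicators (any
  raster fields can be passed to use raw ones instead); Spearman, because
  the standardized scales are ordinal constructions.
- Equity checks use a $10^{-9}$ tolerance on ranges and (for
  background-free fields) means; background-inflated fields report their
  mean deviation without failing, since the tie rule shifts their mean by
  construction.

## Interfaces and scope

The package is a programmatic toolkit: the tidyverse-style functions,
`run_pipeline()` and this vignette are the interface, with plain-text
formats (CSV rasters with JSON sidecars, GeoJSON vectors) for
interoperability; there is no shell command-line tool. Cartographic
rendering beyond `autoplot()`, multimedia fate-and-transport modelling,
dose pathways other than soil ingestion, noise exposure–response
conversion, reprojection and geodesy are out of scope. Test and diagnostic
problem sizes — 40 × 60 grids, 50-replicate batteries, $10^5$-point
Monte-Carlo oracles — were chosen to give stable decile statistics at
interactive runtimes.
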