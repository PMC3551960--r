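---
title: "Multi-model projection of marine range shifts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model projection of marine range shifts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seashift)
```

# The problem

When the ocean warms, the environmental conditions a marine species can
tolerate move — typically poleward — and the species' realised range is
expected to follow. For species already depleted by fishing, two secondary
questions matter as much as the shift itself: does the species' range overlap
more or less with the ranges of commercially targeted species (a proxy for
bycatch exposure), and do the protected areas designated for it remain
suitable habitat?

`seashift` implements this assessment as a reproducible pipeline on a regular
latitude–longitude grid (0.5° by default): three species distribution models
(SDMs) of deliberately different character are fitted to presence-only
occurrence records and a baseline climatology, projected onto a future
climatology, post-processed (clipping, thresholds, dispersal scenarios), and
summarised with a small set of impact statistics. Because multi-decadal
projections cannot be validated against observations, the package leans on a
synthetic study system — virtual species with *known* environmental envelopes
sampled over generated climate scenarios — so that every stage of the chain is
testable against ground truth.

# The three distribution models

All three models consume the same inputs: a binary presence grid (occurrence
records aggregated to cells after quality control) and an environmental stack
(SST, SBT, salinity by default; bathymetry is handled separately, see
*Clipping*). All three emit a per-cell relative habitat suitability in
\[0, 1\]. They differ in how much structure they impose.

## Trapezoidal envelope model

`fit_envelope()` describes a species by one trapezoid per variable:
suitability 0 outside absolute limits $(a, d)$, 1 on a preferred plateau
$(b, c)$, linear ramps between. The preferred bounds are the 10th/90th
percentiles (linear interpolation) of the variable at presence cells; the
absolute limits are the observed presence min/max, optionally widened by a
`buffer` fraction of the preferred-range width. Published envelope models of
this family differ in these constants, so both the percentile pair and the
buffer are configuration knobs; the 10/90, buffer-0 defaults are our
reconstruction, not a quotation of any specific implementation.

Per-variable suitabilities are combined by geometric mean by default — this
keeps the output scale comparable when models use different numbers of
variables — with the plain product (the canonical envelope rule, harsher with
many variables) available via `combination = "product"`.

## Maximum-entropy model

`fit_maxent()` is a minimal, self-contained reconstruction of the
maximum-entropy principle for presence-only data: a Gibbs distribution
$q(i) \propto \exp(\sum_j \lambda_j f_j(i))$ over background cells (all sea
cells by default), with the L1-penalised presence log-likelihood
$\sum_{\text{presences}} \log q - \beta \sum_j |\lambda_j|$ maximised by
proximal gradient ascent with backtracking. Design choices, made once:

* **Features**: linear and quadratic transforms only, standardised to mean
  0 / sd 1 over the background. Hinge/threshold/product features of the
  reference software are out of scope; quadratic terms already allow interior
  optima in each variable.
* **Regularisation**: `beta = 0.1` by default; `beta = 0` recovers the exact
  maximum-entropy moment conditions and is used by the parameter-recovery
  tests.
* **Output scale**: raw Gibbs scores rescaled by their maximum over
  non-missing cells. The common "logistic output" needs a prevalence
  assumption we have no basis to set; relative suitability is all the
  downstream metrics require.
* **Extrapolation**: at prediction time standardised features are clamped to
  ±6 sd so that projected climates outside the training range cannot
  overflow the exponential; suitability saturates instead.
* **Convergence**: the objective never decreases (backtracking), and fitting
  stops when an accepted step improves it by less than `tol`. With strongly
  collinear features (e.g. a bottom temperature that is a constant offset of
  surface temperature, as in shallow-sea scenarios) the likelihood has a flat
  ridge and the first-order optimizer may hit `max_iter` before the formal
  criterion; the fit records `converged = FALSE`, and predictions are
  unaffected because all points on the ridge induce the same $q$.

## Dynamic bioclimate envelope model (DBEM)

`run_dbem()` is a simplified dynamic model: mechanistic enough to produce
transient, dispersal-limited responses, small enough to verify.

1. **Preference profiles** (`derive_profiles()`): each variable's values over
   sea cells are binned into `n_bins = 20` equal-width bins; each bin is
   scored by the suitability-weighted cell count of a *seed* distribution
   (the pipeline uses the clipped envelope-model baseline prediction as the
   seed — the filter-based "current distribution" products used for this
   purpose elsewhere are out of scope), normalised so the best bin is 1.
2. **Carrying capacity** (`carrying_capacity()`): per cell, `K_scale` times
   the geometric mean of profile values; 0 on land and wherever a variable
   falls outside every bin.
3. **Annual steps** (`step_dbem()`): logistic growth
   $A' = A + rA(1 - A/K)$ (where $K = 0$: decay $A' = \max(A(1-r), 0)$),
   then dispersal as a *symmetric exchange*: each pair of 4-neighbour sea
   cells swaps a fraction $d/4$ of each member's post-growth abundance. The
   exchange formulation — rather than the naive "replace with the
   neighbourhood mean" — is what makes total abundance conservation exact
   (to 1e-9 relative in the tests) and gives no-flux boundaries at land and
   domain edges for free.
4. **Forcing**: each environmental layer is interpolated linearly in time
   between the baseline and future stacks (the two period-average states are
   the only climate inputs; yearly climate-model output is out of scope;
   hooks for an advection term are deliberately left out of this minimal
   core). Abundance starts at the baseline carrying capacity and steps from
   `start_year` (1985) to `end_year` (2050).

Defaults `r = 0.5`/yr, `d = 0.1`/yr, `K_scale = 1` are declared, not
estimated — the source analyses do not publish species-level values. What
matters for the comparative conclusions is the *qualitative* regime: with
`d < 1` the dynamic model's centroid shift lags the instantaneous envelope
shift under identical forcing, which the test suite asserts directly.

Larval advection by currents, oxygen/pH effects and body-size growth — parts
of full published dynamic envelope models — are omitted; they require ocean
circulation and biogeochemistry fields that are not part of this package's
inputs.

# Post-processing

* **Clipping** (`apply_clip()`): suitability is zeroed outside allowed
  region masks and where bathymetry exceeds `max_depth × 1.5`. The 50%
  inflation of a species' reported depth limit allows for the observed
  deepening of demersal species under warming; applying the *same* rule to
  both periods prevents the clip itself from manufacturing range change.
* **Thresholds** (`apply_threshold()`): values below `t` become 0; values at
  or above are kept (the map stays continuous in its core range). Fixed
  thresholds {0.05, 0.5, 0.7} span lenient to restrictive core ranges, and
  `select_max_ss_threshold()` picks the data-driven threshold maximising
  sensitivity + specificity on the held-out 25% of presence cells, with all
  sea cells outside the test presences acting as pseudo-absences (the data
  are presence-only; specificity needs some notion of absence). Candidates
  are the unique predicted values at test cells; ties go to the smallest,
  most inclusive threshold; a constant map is reported with a
  no-discrimination flag rather than an arbitrary cut. The 75/25 split is by
  *cell*, not record, so spatially duplicated records cannot leak between
  training and evaluation.
* **Dispersal scenarios** (`apply_dispersal_scenario()`): `full_dispersal`
  admits all newly suitable habitat; `no_dispersal` zeroes the future map
  outside the thresholded current range. The no-dispersal range is provably
  a subset of both the current range and the full-dispersal range, which the
  suite checks on random maps.

# Impact metrics

* **Latitudinal centroid**: suitability-weighted mean cell-centre latitude,
  $\bar L = \sum_i L_i \cdot \text{Abd}_i / \sum_i \text{Abd}_i$. Weights are
  the raw suitabilities — not area-weighted — matching the centroid
  definition used in this literature; an area-weighted variant is available
  (`area_weighted = TRUE`) and documented as a deviation. The between-period
  difference is converted to kilometres with a single package-wide constant,
  `KM_PER_DEG` = 111.32 km/°; positive = poleward (northern hemisphere).
* **Range change**: membership = thresholded suitability > 0; loss is
  current-minus-future area (the loss realised even with no dispersal), gain
  is future-minus-current area (realised only under full dispersal), both as
  percentages of the baseline area; cell areas scale with cos(latitude).
* **Schoener's D** (`schoener_d()`): each map is first normalised to sum to
  1 over the cells where both are observed — model outputs are relative
  suitabilities, not probabilities, so normalisation is a requirement of the
  index, not a convenience — then $D = 1 - \tfrac12\sum_i |p_{x,i} -
  p_{y,i}|$, 0 for disjoint supports, 1 for identical distributions. The
  percent change between periods divides by the baseline D **plus 0.1**
  (`overlap_change_pct()`) so that near-zero baseline overlaps cannot
  explode the percentage.
* **Protected areas**: polygons are rasterised by cell-centre-in-polygon
  with boundary points counting as inside (a deterministic convention);
  suitability is min–max standardised over the pooled set of all
  protected-area cells from *both* periods per species and model — pooling
  both periods keeps the per-cell deltas comparable and bounded in
  \[−1, 1\], at the cost that a single extreme future cell can compress the
  baseline scale. Per-area reports carry the mean baseline value and mean
  delta; the overall summary reports both averaging orders (mean of area
  means, and the pooled-cell mean), which differ when areas have unequal
  sizes.

# The synthetic study system

`make_env_scenario()` emulates a temperate shelf sea on a 0.5° grid
(45–70° N, 10° W–10° E by default): baseline SST falls linearly from 14 °C at
the equatorward edge to 4 °C at the poleward edge plus N(0, 0.5 °C) cell
noise; SBT = SST − 0.5 °C (a shallow, well-mixed column — mean depth is
≈ 90 m, a 50 m shelf deepening at 2 m per cell offshore); salinity,
productivity and distance-to-coast vary with distance from a land band along
the eastern 10% of columns; sea ice is a deterministic ramp below 0 °C
(zero in these scenarios). The future stack adds a uniform warming delta to
the *same* SST field — 1.27 °C by default, with 0.77 °C as the second demo
scenario, spanning the range of mid-century shelf-sea projections — so the
period difference is exact by construction, and, because the baseline
gradient is linear, a uniform delta is *identical* to a poleward translation
of the thermal field. That identity is the package's core end-to-end oracle:
translate the environment by k cells and a correct projection chain must
report a centroid shift of k × 0.5° × 111.32 km.

Virtual species (`virtual_species()`) carry known trapezoidal envelopes;
`sample_occurrences()` draws presence records with probability proportional
to true suitability × detectability, jitters them within cells, and stamps
them with uniform 1971–2000 years (the training window of period-averaged
climatologies) and database-style source labels.
`make_protected_areas()` places non-overlapping rectangles of 2–5 × 2–5
cells (≥ 4 cells each, matching the scale at which such polygons are
meaningful on a 0.5° grid).

What the generator does **not** emulate — and therefore what green tests do
not certify about real data: spatial sampling bias and variable survey
effort, interannual climate variability and trends within a period,
ocean-current transport, covariance structures among variables beyond the
built-in SST–SBT offset, irregular coastlines, and taxonomic noise in
occurrence databases. Conclusions about the *pipeline's correctness* transfer
to real inputs; conclusions about *ecological realism* do not.

# Numerical choices and degenerate inputs

* One RNG stream per operation call, seeded explicitly; global RNG state is
  saved and restored, so identical seeds give bit-identical outputs (the
  pipeline determinism test compares file hashes across reruns).
* Gridded layers are exchanged as ESRI ASCII grids written with 17
  significant digits, so write–read round trips reproduce doubles exactly;
  polygons as GeoJSON; tables as CSV. All writers produce files the
  package's own readers accept.
* Grid cells are half-open boxes `[edge, edge + res)`; a record exactly on a
  lower edge belongs to the cell whose lower edge it matches. Nearest-
  neighbour regridding breaks exact distance ties toward the lower latitude,
  then lower longitude.
* Degenerate cases have declared behaviours rather than accidents: a
  constant variable fits a point envelope (suitability 1 at that value, 0
  elsewhere); a constant suitability map returns its value from threshold
  selection with a warning flag; an all-zero map is an error for centroids
  and overlap (both are undefined); zero detectability is an error for the
  occurrence sampler; unstable dynamic-model abundance (non-finite) raises
  an error naming the remedy (reduce `r` or `d`).
* Problem sizes: the demo matrix is 4 species × 3 models × 2 climate
  scenarios on a 50 × 40 grid with 65 annual dynamic-model steps, and the
  parameter-recovery experiments use 60 × 400-cell backgrounds with 500–2000
  samples — sizes chosen so the full suite exercises every stage in seconds
  while keeping estimation error well inside the asserted tolerances.

# Known limitations

* The maximum-entropy model is a principled reconstruction, not a numerical
  replica of any released Maxent version; its outputs should be compared in
  rank/overlap terms, not cell-by-cell against other software.
* The dynamic model's ecophysiology is reduced to logistic growth plus
  neighbour diffusion; absolute abundances are relative quantities with no
  biomass interpretation.
* Linear time-interpolation of climate between two period averages removes
  interannual variability, so the dynamic model's trajectory is smoother
  than one forced by yearly climate output.
* The overlap percentage's +0.1 damping offset makes changes at near-zero
  baseline overlap conservative by design; comparisons across species pairs
  with very different baseline D should use the raw D values alongside the
  percentages.
* Maps are geographic (plate carrée) only; area weighting uses the
  cos(latitude) spherical approximation with one constant, 111.32 km/°.
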