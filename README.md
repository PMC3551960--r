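# seashift

Multi-model projection of climate-driven range shifts for marine species on a
regular latitude–longitude grid.

Warming oceans move the conditions a species tolerates poleward, and its
range tends to follow. For species threatened by bycatch, the ecological
question is rarely the shift alone: it is whether the species' range will
overlap more with commercially fished species, and whether the protected
areas designated for it will still contain suitable habitat. `seashift`
implements that assessment end-to-end with an ensemble of three species
distribution models of deliberately different structure, so that agreement
and disagreement between models is itself a result:

* a **trapezoidal bioclimatic envelope model** — per variable, suitability is
  0 outside absolute limits, 1 on the preferred plateau between the 10th and
  90th percentiles of presence conditions, with linear ramps between;
* a **maximum-entropy model** — a Gibbs distribution
  `q(cell) ∝ exp(Σ_j λ_j f_j)` over background cells, fitted by maximising
  the L1-penalised presence log-likelihood with linear + quadratic features;
* a **dynamic bioclimate envelope model (DBEM)** — carrying capacity from
  binned preference profiles, then annual logistic growth
  `A' = A + rA(1 − A/K)` with mass-conserving neighbour dispersal, stepped
  from 1985 to 2050 under linearly interpolated climate forcing.

Projections are clipped by region and by 1.5× the species' depth limit,
thresholded (fixed cuts 0.05/0.5/0.7 plus the max sensitivity + specificity
threshold selected on a held-out 25% of presence cells), and run under
no-dispersal and full-dispersal assumptions. Impacts are summarised as:

* **latitudinal centroid shift**, `L̄ = Σ L_i·Abd_i / Σ Abd_i`, converted to
  km with 111.32 km/degree (positive = poleward);
* **range-area change**, loss/gain/net as % of the baseline area with
  cos(latitude) cell areas;
* **Schoener's D overlap** between threatened and commercial species,
  `D = 1 − ½ Σ|p_x − p_y|` on per-map-normalised distributions, with percent
  change damped by a +0.1 offset on the baseline value;
* **protected-area suitability change**, min–max standardised across all
  protected-area cells from both periods, per cell and per area.

Because multi-decadal projections cannot be validated against observations,
the package ships a synthetic study system: shelf-sea climate scenarios with
a known warming delta, virtual species with known envelopes, occurrence
samplers and protected-area generators. Every stage is tested against this
ground truth — most importantly, a k-cell poleward translation of the
environment must be recovered as a centroid shift of k × 0.5° × 111.32 km.

## Worked example

The three numbered scripts under `analysis/` run the whole study on the
synthetic system:

```sh
Rscript analysis/01_fixtures.R 1 results/demo_data   # generate the study system
Rscript analysis/02_pipeline.R results/demo_data/config.yaml
Rscript analysis/03_summaries.R results/demo_data/results
```

The first script writes a baseline (1985) climatology, two 2050 scenarios
(+0.77 °C and +1.27 °C mean SST), 1600 occurrence records for four virtual
species (two "threatened", two "commercial") and six protected-area
polygons. The second runs the full species × model × scenario × threshold ×
dispersal matrix (36 suitability maps, 96-row centroid and overlap tables).
The third prints the headline summaries; with seed 1:

```
Median poleward centroid shift (1985 -> 2050), by model and scenario:
    model      scenario median_shift_km km_per_decade
     dbem 2050_moderate        195.4945      30.07607
 envelope 2050_moderate        208.7598      32.11689
   maxent 2050_moderate        209.7066      32.26256
     dbem   2050_strong        330.7323      50.88189
 envelope   2050_strong        344.5622      53.00957
   maxent   2050_strong        344.6986      53.03056
```

Reading this: all three models agree the virtual species track the imposed
warming poleward; the dynamic model shifts least because dispersal
(`d = 0.1`/yr) makes its response lag the instantaneous envelope models —
the qualitative fingerprint of model structure the multi-model design is
meant to expose. The same run reports median range-change percentages per
model, median overlap changes within ±2% (both species groups shift
together, so bycatch exposure barely changes), small negative mean
protected-area suitability deltas, and centroid shifts that vary by less
than ~20 km across thresholds — i.e. conclusions robust to the threshold
choice.

The same machinery is callable directly:

```r
library(seashift)
sc  <- make_env_scenario(scenario_params(seed = 1))
sp  <- virtual_species("skate", list(sst = c(6, 8, 11, 13)), depth_limit = 150)
occ <- sample_occurrences(sp, sc$baseline, 400, seed = 2)
pg  <- aggregate_to_grid(qc_filter(occ, sc$baseline)$records, sc$baseline$spec)
fit <- fit_envelope(pg, sc$baseline)
shift <- centroid_shift_km(
  latitudinal_centroid(predict_envelope(fit, sc$baseline)),
  latitudinal_centroid(predict_envelope(fit, sc$future))
)
```

## Layout

```
R/                  grid/IO, synthetic generators, occurrence prep, the three
                    SDMs, post-processing, impact metrics, protected areas,
                    pipeline orchestration
analysis/           01_fixtures.R, 02_pipeline.R, 03_summaries.R
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          range-shift-methods.Rmd — models, assumptions, design
```
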