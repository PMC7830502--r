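# rangerisk

Ensemble habitat-suitability modelling and projected extinction-risk
assessment for narrow-range species under climate change.

Conservation assessments of range-restricted (e.g. montane endemic)
species increasingly rely on species distribution models: occurrence
records and gridded climate predictors are turned into a habitat-
suitability surface, the surface is projected under future climate, and
the projected contraction of the species' occupied area is translated
into an IUCN-style threat category. `rangerisk` implements that whole
workflow as composable R functions around one central fitted object, and
ships a virtual-species simulator so every stage can be exercised and
validated without downloading any data.

## The method

For one species with presence records `y` and predictors `x` (bioclim-style
layers on a common grid, nominally 2 km):

1. **Cleaning & collinearity.** Occurrences are deduplicated to one per
   grid cell and filtered by extent and land cover. Predictors are
   filtered iteratively until all pairwise |Pearson r| ≤ 0.75 and all
   variance inflation factors VIF_j = 1/(1 − R²_j) ≤ 5.
2. **Ensemble SDM.** Pseudo-absences are sampled at 10 background points
   per presence; the sample is split 70/30; four learners — logistic GLM
   (linear + quadratic terms), GAM, random forest, and boosted regression
   trees — are fitted and combined with weights
   w_i = max(TSS_i, 0) / Σ_j max(TSS_j, 0), where TSS = sensitivity +
   specificity − 1 is each member's held-out True Skill Statistic. The
   ensemble suitability of a cell is the weighted mean of member
   probabilities.
3. **Thresholds.** Suitability maps are binarized under three rules:
   MTP (minimum training presence — the lowest ensemble score at any
   training presence), MTSS (the score maximizing training sensitivity +
   specificity), and a fixed 0.5.
4. **Range metrics.** The extent of occurrence (EOO) is the alpha-hull of
   the occurrences (Delaunay triangulation, triangles with circumradius
   > α discarded) with a 0.1° outward buffer. Binary maps are masked by
   land cover and by the EOO; the area of occupancy (AOO) is the count of
   suitable cells × 4 km². Current and future binaries give
   loss/stable/gain change maps under full-dispersal (gains count) and
   no-dispersal (gains discarded) scenarios.
5. **Risk categories.** Projected AOO loss maps to
   LC (< 15), NT (≥ 15), VU (> 30), EN (> 50), CR (> 80), EX (= 100, %)
   and is compared with the current Red List status (up-/down-listed).

## Worked example

A virtual montane-type specialist (gaussian niche on a temperature-range-
like layer, optimum 25, breadth 3 on a 0–100 scale) on a 100×100 grid of
2-km cells, with a +10-unit warming applied to the driver:

```r
library(rangerisk)
vs <- virtual_study(seed = 1)                       # stack, niche, 40 records
future <- apply_climate_delta(vs$stack, climate_delta(offset = c(bio7 = 10)))
res <- run_pipeline(vs$occurrences, vs$stack, list(rcp45 = future),
                    landcover = make_landcover(default_grid(), 0.7, seed = 1),
                    config = list(species = "virtual", current_status = "VU",
                                  seed = 1))
print(res)
round(res$importance, 1)
```

```
Habitat-suitability extinction-risk pipeline result

TSS-weighted ensemble habitat-suitability model
  members: glm (w=0.26), gam (w=0.26), rf (w=0.24), brt (w=0.25)
  predictors: bio7, bio3, bio12, elev
  held-out AUC 0.887, TSS 0.647 (n train 269, test 116)
  thresholds: MTP 0.232, MTSS 0.232, fixed 0.50

Extinction-risk assessment: virtual (current status VU)
 scenario threshold_rule dispersal change_pct loss_pct proposed_status
    rcp45            mtp      full     -68.84    68.84              EN
    rcp45            mtp      none     -95.69    95.69              CR
    rcp45           mtss      full     -68.84    68.84              EN
    rcp45           mtss      none     -95.69    95.69              CR
    rcp45       fixed_05      full     -93.07    93.07              CR
    rcp45       fixed_05      none    -100.00   100.00              EX
 listing_change
      up-listed
      ...
Note: 'EX' is a projected A3-style status label, not a formal extinction declaration.

 bio7  bio3 bio12  elev
 76.7  17.2   2.2   3.9
```

Reading the output: the four members discriminate held-out presences
from background well (AUC 0.89) and are weighted near-equally; the true
driver (`bio7`) dominates the permutation importance (77%); a 10-unit
warming removes 69–100% of occupied cells inside the buffered EOO
depending on the threshold rule and dispersal assumption, so a currently
Vulnerable species is up-listed under every scenario — most severely
(EX) under the fixed-0.5 rule with no dispersal.

The same workflow is scriptable from a shell via
`inst/scripts/run_pipeline.R` (`simulate` and `assess` verbs).

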