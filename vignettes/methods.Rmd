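---
title: "Methods: ensemble habitat-suitability models and projected extinction risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat-suitability models and projected extinction risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangerisk)
```

## Scope and model

`rangerisk` assesses how much of a narrow-range species' occupied area a
projected climate removes, and what IUCN-style category that loss
implies. The statistical core is a stacked presence/background
classifier: given a table of presence cells (label 1) and randomly
placed pseudo-absence cells (label 0) with predictor values attached,
four member models — a logistic GLM with linear and quadratic terms per
predictor, a binomial GAM with a thin-plate smooth per predictor, a
random forest, and stochastic gradient-boosted trees with logistic
loss — each estimate the probability that a cell is a presence. The
ensemble suitability of a cell is the convex combination of member
probabilities with weights proportional to each member's positive part
of the held-out True Skill Statistic (TSS = sensitivity + specificity −
1). Members with non-positive held-out skill get zero weight; if no
member has positive skill the weights fall back to equal, with a
warning.

The assessment chain that follows is deterministic geometry and
arithmetic: binarize the suitability surface, intersect it with a
land-cover mask and with the buffered alpha-hull extent of occurrence
(EOO), count cells to get the area of occupancy (AOO, at a nominal
4 km² per cell), difference current and future maps into
loss/stable/gain classes, apply a dispersal scenario, and convert the
percentage AOO change into a risk category.

Assumptions worth making explicit:

* Pseudo-absences are an unbiased background sample, not true absences;
  member probabilities are therefore calibrated to the sample prevalence
  (1/11 at the default 10:1 ratio), not to an absolute occupancy
  probability. Threshold rules that adapt to the score scale (MTP,
  MTSS) are unaffected; the fixed 0.5 rule is a deliberately
  conservative convention, not a calibrated probability cutoff.
* Binarization thresholds estimated from training data transfer
  unchanged to future surfaces — standard practice, and the only option
  when the future holds no observations.
* AOO uses a fixed nominal cell area (4 km²) with no latitude
  correction, mirroring grid-cell-counting occupancy assessment.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pa_ratio` | 10 | background : presence | standard background-sample size for presence-only SDMs |
| `train_fraction` | 0.7 | — | 70/30 split; evaluation on the held-out 30% |
| `r_max` | 0.75 | \|Pearson r\| | pairwise-correlation cutoff for predictor filtering |
| `vif_max` | 5 | — | variance-inflation cutoff |
| `buffer_deg` | 0.1 | decimal degrees | EOO outward buffer (~12 km at the equator) |
| `alpha` | 2 × median NN distance | degrees | circumradius cutoff of the alpha hull; logged, overridable |
| `cell_area_km2` | 4 | km² | nominal 2-km occupancy cells |
| threshold rules | mtp, mtss, fixed_05 | — | liberal, conservative, and fixed operating points |
| dispersal | full, none | — | bracketing assumptions on colonization of gains |
| member hyperparameters | GLM quadratic; GAM k≈8; RF 500 trees; BRT 1000 rounds, η=0.01, depth 3, subsample 0.5 | — | conventional SDM practice; overridable per family |

Risk categories on projected AOO loss (percent): LC below 15, NT at or
above 15, VU above 30, EN above 50, CR above 80, EX at exactly 100.
The published verbal rule uses strict inequalities that leave the
boundary points 15/30/50/80 formally unassigned; we resolve boundaries
precautionarily (an exact boundary value takes the more threatened
category where the rule can be read as ≥, hence 15 → NT) and expose the
mapping through `classify_risk()` so the convention is testable. "EX"
is a projected-status label under a criterion-A3-style assessment, not
a formal extinction declaration; printed reports carry that caveat.

## What the virtual-species generator emulates

`make_random_field()` builds each predictor as gaussian-smoothed white
noise (separable kernel, sd = `correlation_range` cells, truncated at
3 sd, edge-renormalized), min–max rescaled to a caller-chosen range —
smooth, spatially autocorrelated surfaces that can mimic observed
bioclim ranges exactly. `virtual_niche()` + `true_suitability()` define
ground-truth suitability as a product of gaussian or logistic responses;
`sample_presences()` draws presence cells without replacement with
probability proportional to suitability (at most one record per cell,
like deduplicated herbarium data), with an optional uniform
contamination rate for observation error (default 0; no detection-error
model is claimed). `apply_climate_delta()` creates futures as per-layer
`x·factor + offset`; `make_landcover()` thresholds a smoothed field into
a forest class of prescribed areal fraction plus grassland/water/urban
classes.

The generator does **not** emulate: the covariance structure among real
bioclim variables (layers are independent), anisotropy or elevational
lapse structure, spatial sampling bias in occurrence records, or
GCM-like spatial heterogeneity in climate change (deltas are spatially
uniform). Passing recovery tests therefore demonstrates that the
pipeline recovers known truth under clean assumptions — not that any
real species' assessment is correct.

### The reference study conditions

`virtual_study()` fixes the package's canonical conditions: a 100 × 100
grid of 2-km cells, four predictors, a single gaussian driver ("bio7")
with optimum 25 and breadth 3 on a 0–100 scale, 40 presences, and
10× pseudo-absences. Two properties of this design were chosen by
computing on the *true* surface before any model fitting:

* Because presences are drawn proportional to suitability, the design
  itself caps achievable discrimination (the Bayes-optimal AUC). A
  niche optimum near the mode of the field's value distribution makes a
  third of the landscape suitable and caps AUC near 0.79 regardless of
  the model; a narrow niche in the distribution's tail (≈5% of the
  landscape suitable) raises the cap to ≈0.92–0.98. A narrow-range
  specialist is a *tail* species.
* The optimum sits on the **cool** tail. A warming offset then pushes
  conditions into the densely sampled warm bulk of the landscape, where
  every member has abundant background support to learn the decline.
  The mirrored design (warm-tail optimum) exhibits the classic
  truncated-niche pathology — almost no background above the niche, so
  tree-based members clamp "suitable" when extrapolating and projected
  losses become unidentifiable. That pathology is real and worth
  knowing about; it is simply not the regime in which a recovery test
  is informative.

A side effect of a tail optimum is a small warm-ward bias (< one
breadth) in the mean driver value at presence cells, because more
landscape is available above the optimum than below; the niche-recovery
test asserts the Monte-Carlo mean within half a breadth and individual
replicates within one breadth.

In the contraction experiment the future offset is *solved* per
replicate from the true surface: the offset (grid-searched at 0.25-unit
steps) that leaves 40% of the currently true-suitable cells inside the
buffered EOO suitable. The pipeline's estimated loss is read from the
MTSS rule under full dispersal — MTSS because it adapts to the
prevalence-scaled probability axis (a fixed 0.5 on that axis is a
different, more conservative operating point than true-suitability 0.5)
and is the rule this kind of assessment projects AOO with; full
dispersal because the engineered truth counts newly suitable cells
inside the EOO. The elimination experiment uses a +60-unit offset,
which places every EOO cell far beyond optimum + 4 breadths, inside the
well-learned unsuitable range.

## Numerical and procedural choices

* **Cell membership** is half-open — `[x0, x0+w) × (y0−h, y0]` — so an
  edge point belongs to exactly one cell; extraction, polygon masking
  and AOO counting share the rule, preventing double counting.
* **Classification convention**: a score equal to the threshold is
  suitable. This makes the MTP guarantee exact: binarizing at the
  minimum training-presence score keeps every training presence.
* **MTSS candidates** are the unique observed scores (exact optimum,
  cheap at these sizes); ties resolve to the smallest threshold.
* **Member evaluation**: binarization thresholds (MTP, MTSS) come from
  ensemble scores on the *training* rows, as the names imply;
  discrimination metrics (AUC, TSS) and the member TSS used for
  weighting are computed on the held-out 30%, with each member's TSS
  maximized over thresholds there. Deriving member thresholds from
  training scores instead would hand strongly overfit members (random
  forests score training presences near 1) useless held-out operating
  points and collapse their weights for the wrong reason.
* **Predictor filtering order**: the pairwise-correlation rule runs
  first (removing, from the most-correlated pair, the member with the
  larger VIF), then the VIF rule removes the largest VIF until all are
  ≤ 5; statistics are recomputed after each removal and ties break by
  removing the lexicographically later name, so the procedure is
  deterministic.
* **Alpha hull**: classical alpha shape — Delaunay triangulation
  (incremental Bowyer–Watson; cocircular grid degeneracies broken by a
  deterministic 1e-9-of-extent jitter) with triangles of circumradius
  > α discarded. The hull may be multipart, tracking disjunct ranges.
  Fewer than 3 usable points, collinear sets, or an alpha below the
  smallest circumradius degenerate to buffered points, flagged with a
  warning. The 0.1° buffer is applied analytically (a point is inside
  if within buffer distance of the triangle set), so no polygon
  buffering engine is needed; the GeoJSON export carries the unbuffered
  triangles with `alpha` and `buffer_deg` as properties, and buffered
  areas are computed by grid integration when needed.
* **Degenerate model inputs**: a training table whose predictors are
  all constant degenerates every family to the training prevalence
  (tree learners cannot split such data and some implementations stall
  on it); constant ensemble predictions make permutation importance
  undefined, reported as zeros with a warning.
* **Seeding**: every stochastic step takes an explicit seed; pipeline
  stages derive seeds from the master seed and the stage name, so runs
  are bit-reproducible and adding a stage does not reshuffle the
  others.
* **Problem sizes**: tests and the acceptance script run the reference
  100×100-cell landscape, 40 + 400 samples, 5 contraction replicates —
  the scale at which all recovery properties are measured in this
  package.

## Limitations

* Probabilities are prevalence-scaled, not absolute occupancy
  probabilities; compare suitability across cells, not across studies.
* No spatial cross-validation: the 70/30 split ignores spatial
  autocorrelation, so held-out AUC is optimistic relative to spatially
  blocked evaluation.
* The EOO buffer and alpha are in degrees while AOO uses nominal
  kilometre cells; neither is latitude-corrected.
* Only criterion-A3-style loss categories are implemented — no EOO-area
  (criterion B) thresholds, population criteria, or generation-length
  scaling.
* Projections into climates outside the training support inherit each
  member's extrapolation behavior (quadratic GLMs collapse, trees
  clamp); the truncated-niche regime discussed above is the practical
  warning case.
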