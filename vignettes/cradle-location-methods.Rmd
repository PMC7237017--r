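---
title: "Locating allopolyploid cradles with ensemble SDMs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating allopolyploid cradles with ensemble SDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Allopolyploid plant species arise by hybridization between two parental
taxa followed by genome doubling. A body of observations suggests that
unreduced-gamete formation — the raw material of polyploidy — is more
frequent where plants live under climatic stress, i.e. at the
low-suitability periphery of a species' bioclimatic range. If that is
true, the places where the *low-suitability margins of both parents
overlap* should have been unusually productive of hybrids: potential
formation centers, or *cradles*, of the allopolyploid. For strict soil
specialists (here, gypsophytes) the candidate cells are further
restricted to the suitable-soil map.

This package implements that localization procedure end to end, for any
pair of parental taxa and their hybrid:

1. fit presence/background suitability models for each taxon under
   current conditions, as bootstrap ensembles over four algorithm
   families;
2. project them to past climates (Last Glacial Maximum, Mid-Holocene)
   under several circulation-model (GCM) variants and average those into
   a consensus;
3. read the suitability distribution of each parent at its current
   occurrences and derive a *low-suitability interval*;
4. map each parent's low-suitability area (LSA) in a past period,
   intersect the two, and intersect with the soil mask: the cradles;
5. track the hybrid's suitability at each cradle through subsequent
   periods against a *survival threshold*, keeping the sequential
   survivors as the expected present-day distribution under no
   dispersal.

Because the real inputs (GBIF records, paleoclimate layers, a digitized
gypsum-soil map) are not redistributable, the package ships a
synthetic-landscape module that generates all inputs with *known* ground
truth, so every stage is testable as a recovery problem.

## The interval rule

For one taxon, read the model's current-conditions suitability at the
cells where the taxon currently occurs and take the minimum and the
first quartile of those readings. "Low but occupied" suitability for
that taxon is the band between them. For a parental pair the package
implements two rules:

* **combined** (the default for cradle finding):
  `[max(min_A, min_B), max(Q1_A, Q1_B)]`. Below the higher minimum one
  parent is absent, so interbreeding is impossible; between the two
  first quartiles only one parent is in its low band, but triploid
  intermediates can still bridge to the tetraploid, so the band extends
  to the higher first quartile.
* **union** (used for drawing per-taxon LSA maps):
  `[min(min_A, min_B), max(Q1_A, Q1_B)]`, the widest band in which at
  least one parent sits in its periphery.

Both bounds are inclusive — the printed endpoints are themselves
observed, occupied values. Quartiles use linear interpolation between
order statistics (the `h = (n-1)p + 1` convention, R's type 7), fixed
so that tests are exact. For valid summaries the combined band can
never be empty: the higher first quartile always dominates the higher
minimum.

With the two parental summaries used throughout the worked examples,
`(min, Q1) = (0.07603, 0.52207)` and `(0.1306, 0.4447)`:

```{r}
library(cradlefinder)
a <- new_suitability_summary("tomentosa", min = 0.07603, q1 = 0.52207)
b <- new_suitability_summary("struthium", min = 0.1306, q1 = 0.4447)
combined_interval(a, b)   # [0.1306, 0.52207]
union_interval(a, b)      # [0.07603, 0.52207]
```

## Suitability models

Presence-only data are handled as presence-versus-background
classification: each taxon's thinned presences (one record per raster
cell, first record kept — the duplicate-retention rule is a fixed
convention, since any choice is defensible) against a uniform random
background sample, by default 10 background points per presence with a
floor of 1000. The background scheme, evaluation partition and ensemble
weighting are all decisions of this package, exposed as configuration;
none is dictated by the procedure itself.

Four algorithm families are fitted, 30 bootstrap replicates each
(in-bag rows train, out-of-bag rows evaluate):

* **GLM** — logistic regression with linear + quadratic terms per
  variable. For a Gaussian niche this is the correctly specified model
  family, since log suitability is quadratic in the predictors.
* **RF** — a `ranger` probability forest (300 trees), predicted
  presence-class fraction. Terminal nodes are kept large
  (`min.node.size` = 2% of rows, at least 20): with class-frequency
  leaves a forest effectively memorizes its training presences, which
  would inflate exactly the readings the interval rule is built from.
* **MARS-style hinge regression** — forward selection of mirrored hinge
  pairs by residual sum of squares with backward pruning by generalized
  cross-validation, least squares on the 0/1 label, output clipped to
  [0, 1]. Written in the package: no MARS implementation is part of the
  package's dependency set, and the fitting contract (seeded, in-[0,1],
  deterministic) is what downstream stages rely on.
* **Maxent surrogate** — its log-linear formulation: lasso-regularized
  logistic regression (`glmnet`, 5-fold CV, scored at `lambda.min`) on
  linear + quadratic + pairwise-product features.

Replicates are combined as a weighted average with weights = out-of-bag
TSS floored at zero (AUC optionally), and the weighted standard
deviation is kept as the uncertainty map. Projection to a past period
repeats the prediction on that period's stack per GCM; the GCM
consensus is the unweighted cellwise mean with the across-GCM standard
deviation as its uncertainty layer.

AUC is computed by pairwise concordance with ties counted one half
(midranks); TSS is maximized over the sorted unique scores as
thresholds, predicting presence at score ≥ threshold. The "ensemble
out-of-bag AUC" aggregates, for every training row, the weighted mean
prediction of the members for which that row was out-of-bag, and takes
one AUC of those scores — the standard bagged-ensemble construction.

## The survival filter

The hybrid's own summary at its current occurrences defines the
threshold: its minimum by default (the weakest climate the hybrid
demonstrably endures), with the first quartile and the min–Q1 midpoint
as stricter alternatives. A cradle survives a period iff the hybrid's
suitability there is **≥** the threshold (the minimum itself is an
observed value, so sitting exactly at it counts as surviving), and
survival is sequential: an LGM cradle that fails at the Mid-Holocene is
failed for good, because the analysis deliberately assumes no
dispersal. Three monotonicity laws follow and are enforced by tests:
raising the threshold never grows the surviving set; min-mode survivors
contain mid-mode contain Q1-mode; and survivors to the present are a
subset of survivors at the Mid-Holocene.

A note on an apparent rule that is *not* implemented: low-suitability
survivors (suitability below ≈ 0.25) may be ecologically doubtful, but
no formal cutoff beyond the threshold modes above is applied.

## The synthetic landscape

Each predictor layer is a deterministic linear gradient (continentality
west→east, winter temperature north→south, rainfall gradients) plus a
spatially autocorrelated Gaussian random field (white noise smoothed by
FFT convolution with a Gaussian kernel, periodic boundary), on a 120 ×
150 cell grid of 5-arc-minute cells — an Iberian-scale extent at a desk
scale that keeps a full run in minutes. Past periods add a per-variable
shift (colder, drier, more seasonal at the LGM; the Mid-Holocene at 40%
of the LGM shift); each of three pseudo-GCMs perturbs that shift with
an independent seeded jitter, emulating circulation models that
disagree about the same past climate. The soil mask is a union of
seeded circular patches covering roughly 8% of the grid, emulating
scattered gypsum outcrops. All stochastic steps draw from named seeds;
identical configuration gives bit-identical output.

Virtual taxa have product-Gaussian (unimodal, separable) responses —
the simplest form whose geometry matches the assumed
allopatric-with-margin setting. Presences are drawn without replacement
with probability proportional to true suitability, one per cell, i.e.
already in the post-thinning world the models see.

**Calibration of the defaults.** The default niche breadths are set
against an information limit computed from the ground truth alone: the
AUC obtained when the *true* suitability itself is used to score the
presence/background sample (the best any model could do). Breadths are
chosen so this limit is ≈ 0.94 — a strong-signal regime in which a
competent ensemble can be expected to exceed 0.9 — and the past-period
shifts are scaled in niche-breadth units so that the parental margins
still overlap at the LGM and Mid-Holocene (126 and 68 ground-truth
cradle cells respectively under the default seeds). The parents' optima
are displaced mainly along the continentality and summer-drought axes;
the hybrid is intermediate and narrower.

What the generator does *not* emulate: real spatial sampling bias in
occurrence data, coordinate error, non-Gaussian or interacting niche
responses, dispersal limitation, and biotic interactions. Passing
recovery tests therefore shows the pipeline recovers truth under its
own assumptions, not that those assumptions hold for real data.

## Numerical conventions and degenerate inputs

* Grid cells are half-open, `[west, east) × (south, north]`, 0-based
  `(row, col)` with row 0 at the north; a point on a shared edge belongs
  to the cell to its east/south. A coordinate within 1e-9 cells of an
  edge is snapped to it before flooring.
* Rasters are exchanged as ESRI ASCII grids (plain-text, full double
  precision, explicit nodata sentinel); all inputs must share one CRS
  and no reprojection is performed — a mismatch is an error.
* A bootstrap resample containing a single label is retried with the
  next seed (up to 10, logged); an out-of-bag set lacking a label falls
  back to full-table evaluation (logged). Constant-feature tables give
  intercept-only fits that predict the training prevalence.
* Zero-variance layers in the correlation sample are reported as r = 0
  with a warning. Variable-selection ties break by variable name.
* Suitability summaries require at least 4 usable readings; extraction
  with no usable point is an error rather than an empty vector.

## Problem sizes used by the tests

Unit tests run on a 40 × 50 scaled-down scenario with small ensembles;
the recovery acceptance test runs the full default scenario (120 × 150
grid, 500 presences per parent, 30 replicates × 4 algorithms, 3
pseudo-GCM LGM consensus) — these sizes are the package's chosen
desk-scale study conditions. Brute-force oracles (pairwise AUC
enumeration, exhaustive TSS thresholds, cellwise mask loops,
containment scans) are kept independent of the implementation paths
they check.

## Known limitations

* The four algorithm shapes differ in how they rank the deep
  suitability tail; since the interval's lower endpoint is an extreme
  order statistic, fitted bands are systematically a little narrower or
  shifted relative to truth-scale bands. The recovery test quantifies
  this end to end (Jaccard of fitted vs ground-truth cradles).
* GCM consensus averages maps, not parameters; disagreement enters only
  as the SD layer and does not propagate into the survival filter.
* The survival filter is deterministic in the threshold; no demographic
  or dispersal stochasticity is modeled.
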