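---
title: "Uncertainty-aware species distribution modelling with reefsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware species distribution modelling with reefsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Marine spatial planning often needs a map of where a rare benthic assemblage
— here, a staghorn-coral-like community observed at roughly 4.5 % of survey
sites — is likely to occur, together with an honest statement of how
uncertain that map is. `reefsdm` implements a complete workflow for this:
a boosted regression tree (BRT) occurrence model fitted on a fine (2 m)
predictor grid, a bootstrap ensemble that turns the single prediction into a
mean probability surface and a per-cell precision (coefficient of variation)
surface, four ROC-based rules for converting probabilities into
presence/absence maps, and a 3 × 3 table of probability-by-precision
combination maps whose areas are accounted inside and outside
management-zone polygons.

Because real survey rasters of this kind are rarely public, the package
ships a first-class synthetic seascape generator with a *known* true
probability surface, so every stage of the workflow can be tested end to end
against planted truth.

## The model

Occurrence $y_i \in \{0, 1\}$ at site $i$ is modelled through the Bernoulli
log-odds

$$\operatorname{logit} p(x) = f(x) = \beta_0 + \sum_{m=1}^{M} \nu\, T_m(x),$$

a stagewise sum of $M$ shallow regression trees $T_m$, each fitted to the
gradient of the Bernoulli deviance on a random `bf`-fraction subsample of the
training rows and shrunk by the learning rate $\nu$ (`lr`). Tree complexity
`tc` bounds the interaction depth of each tree. Model fit is summarised by
percent deviance explained,

$$\mathrm{PDE} = 1 - \frac{D(y, \hat p)}{D(y, \bar y)},
\qquad D(y, p) = -2\sum_i \big[y_i \log p_i + (1-y_i)\log(1-p_i)\big],$$

and discrimination by AUC, the probability that a random presence outranks a
random absence.

Three choices are cross-validated or ensembled rather than assumed:

* **Tree count.** For each fold of a 10-fold class-stratified CV, the
  ensemble is grown to `max_trees` and held-out deviance is recorded every
  `step_size` trees; the count minimising the mean held-out deviance is
  selected, and the cross-validated PDE uses the training-fold prevalence as
  the null. This mirrors the staged-CV convention popularised by the
  `gbm.step` tradition (`step_size` 50, `max_trees` 10 000 by default).
* **Hyperparameters.** `tune_grid()` crosses `lr` ∈ {0.01, 0.001, 0.005},
  `tc` ∈ {2, 3, 4, 5, 10, 20} and `bf` ∈ {0.5, 0.75} — 36 combinations — and
  keeps the one with the highest mean cross-validated PDE (ties: fewer
  trees, then grid order). Tuning models are discarded; only metrics are
  kept.
* **Uncertainty.** `bootstrap_ensemble()` refits the tuned model on 100
  resamples (with replacement, size $n$) of the training sites. The per-cell
  mean of the 100 predicted surfaces is the probability map; the per-cell
  sample standard deviation over the mean is the CoV precision map. A cell
  with probability 0.5 and CoV 0.1 "could vary by" 0.5 × 0.1 = ± 0.05.

Tree *fitting* is delegated to xgboost (exact mapping: `eta` = `lr`,
`max_depth` = `tc`, `subsample` = `bf`, `lambda` = 0 so leaf values are
plain Newton steps); tree-count selection, tuning, evaluation metrics,
thresholding and all downstream analysis are implemented in this package.
Fitted trees are parsed into a rule table that the package can evaluate
itself — serialized models predict through this traversal, which is
cross-checked against the backend in the test suite (inputs are rounded to
float32 so split-boundary routing is identical).

## Thresholds and the nine combination maps

On the spatially independent test set, `optimize_thresholds()` scans every
candidate threshold of the ROC curve (classification rule: presence iff
$\hat p \ge t$) and selects:

| rule | objective |
|------|-----------|
| SES | sensitivity = specificity (argmin of their absolute difference) |
| MSS | maximum sensitivity + specificity |
| PPOP | predicted prevalence = observed test prevalence |
| max-kappa | maximum Cohen's kappa |

Ties resolve to the *lowest* threshold, the over-predicting (precautionary)
direction. With a well-performing model (AUC ≥ 0.8) SES and MSS often
coincide, leaving three distinct thresholds: low, moderate and high.

Each threshold defines a probability footprint. Within each footprint the
CoV values are split at their empirical 1/3 and 2/3 quantiles
(interpolated order statistics, position $1 + (n-1)p$) and the footprint
maximum. "Terciles" are interpreted as *equal-frequency* (quantile)
breakpoints, not equal-width bins: quantile breakpoints reproduce the
observed pattern that the cutoffs sit near the mean ± 0.43 sd of an
approximately normal CoV field, which equal-width thirds of the range do
not. The three cumulative cutoffs (high precision = strictest) crossed with
the three footprints give the nine combination masks; by construction, high
⊆ moderate ⊆ low precision within a level, and the low-precision mask
equals its footprint exactly.

`zonal_area()` assigns a presence cell to a management zone when its centre
lies inside the zone polygon (zones must not overlap), so inside areas plus
the outside area reproduce each mask's total area as exact cell counts times
the cell area.

## The synthetic seascape

`generate_seascape()` emulates the data-generating situation the workflow
targets:

* a 2 m grid (64 × 64 cells by default; the paper-scale extent is emulated,
  not reproduced) with a smooth bathymetry, 0.3–20 m positive-down, a gentle
  southward deepening trend and 0.08 m fine-scale seabed texture;
* 15 spectral-like layers = own smooth field + a depth (attenuation)
  loading; bands 2, 4, 6 and 12 are noisy monotone copies of bands 1, 3, 5
  and 11, so the Spearman filter (|ρ| ≥ 0.9, later-ordered member dropped)
  always has designed redundancy to find;
* 9 topographic derivatives of the depth grid (slope by Horn's method,
  eastness/northness aspect components, Zevenbergen–Thorne curvatures,
  triangulated-surface rugosity, focal standard deviation, topographic
  position index) — any cell whose 3 × 3 window touches nodata is nodata;
* 4 geographic proxies: x, y, and distances to a reef-crest feature (an
  L-strip along the north and west edges) and a mid-lagoon channel feature;
* a true surface $\operatorname{logit} p = \beta_0 + a\,(3.5\,
  g(\text{depth}) + 1.2\, \text{band}_1 + 2.5\, e^{-d_{\text{crest}}/\ell})$,
  where $g$ is a smooth shallow-water preference (high at ~1.5–6.5 m) and
  $\ell$ is 30 % of the grid extent. The intercept $\beta_0$ is calibrated
  by root finding so the spatial mean equals the target prevalence (0.045);
  amplitude $a = 0$ yields a flat landscape whose truth is exactly the
  target everywhere.

The amplitude default (2.2) makes the assemblage a strong habitat
specialist: under the study sample sizes (292 training sites, 273
stratified-random test sites) the tuned model recovers test AUC ≈ 0.85–0.96
and cross-validated PDE ≈ 0.1–0.45 across seeds, the performance regime the
workflow is designed for. Training sites are a simple random sample of
valid cells; test sites are stratified by terciles of the *true*
probability with equal allocation, from cells disjoint with the training
cells — stratification by truth guarantees presences in the test set even
at 4.5 % prevalence, and equal-frequency strata keep the expected test
prevalence equal to the target. Presence is a single Bernoulli draw per
site; there is no detection error.

What the generator deliberately does **not** emulate: satellite image
physics (the spectral layers are statistical stand-ins), tides or exposure
masking, spatially autocorrelated residuals beyond the smooth fields, and
detection error in the response. Tests that pass on this synthetic world
therefore establish the *mechanics* of the workflow (the estimators, the
selection rules, the accounting identities) and its behaviour in a
known-truth regime, not field performance on any real lagoon.

## Numerical choices and conventions

* Grid convention: row 1 is the north edge; cells are half-open intervals
  `[x, x + cell)`, so a site on a boundary belongs to exactly one cell.
  Depth is positive downward.
* Probabilities are clipped to `[1e-9, 1 - 1e-9]` in all deviance work.
* CV folds are class-stratified so every fold holds presences at rare-event
  prevalence; held-out null deviance uses the training-fold mean.
* Sample (n − 1) standard deviation in the CoV; CoV at cells with zero mean
  is nodata rather than infinite (such cells never enter a presence
  footprint).
* Single-class bootstrap resamples are redrawn, not aborted — a ~1e-6 event
  at n = 292, prevalence 0.045 — and the redraw count is reported.
* AUC is computed both as the Mann–Whitney rank statistic and as the
  trapezoid on the ROC; a disagreement beyond 1e-9 is treated as an internal
  error.
* One global seed fans out to per-stage seeds by a fixed arithmetic rule
  (`split_seed()`), so `run_sdm_pipeline()` is bit-reproducible and stages
  can be re-run independently.
* Grid IO is the plain-text ESRI ASCII grid dialect (nodata −9999); zones
  travel as GeoJSON FeatureCollections in grid coordinates; models serialize
  to a JSON rule table that reloads without the fitting backend.

Problem sizes in the shipped tests and acceptance script — 32–64 cell grids,
500–1500 tree caps, ensembles of 4–100 — are the package's chosen
demonstration scale; the estimators themselves have no such limits.

## Known limitations

* The nine topographic metrics are a reasonable standard set; the source
  workflow does not name its nine, so conclusions tied to a specific terrain
  metric should re-derive it.
* The greedy later-dropped rule for correlated predictors reproduces the
  "drop the later spectral bands" outcome but is order-dependent by design.
* Bootstrap members may select their tree count per resample (`"cv"`, the
  default, matching the staged-CV rule) or reuse the tuned count
  (`"fixed"`, cheaper); the CoV surface is mildly narrower under `"fixed"`.
* Zones are arbitrary simple polygons, but the generator emits rectangles so
  the area arithmetic in tests is exact by construction.
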