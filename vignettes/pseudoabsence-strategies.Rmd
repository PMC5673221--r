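---
title: "Comparing pseudo-absence strategies for boosted regression tree distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing pseudo-absence strategies for boosted regression tree distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most occurrence data for amphibians and other poorly surveyed taxa are
presence-only: we know where a species was recorded, not where it is absent.
Presence–absence learners such as boosted regression trees (BRT) therefore
need artificial absences ("pseudo-absences"), and how those are generated
changes what the model learns. `tgbsdm` implements and compares the three
generation strategies most relevant to survey data from a single protected
area, end-to-end on a synthetic landscape where the truth is known:

* **UTGB** — unweighted target-group background: the pseudo-absences for a
  focal species are the presence points of the *other* surveyed species in
  the same taxonomic group. Because all records come from the same field
  campaigns, the background inherits the survey's sampling bias. With `D`
  pooled records and `p_k` focal presences, the non-overlapping background
  has `a_k = D − p_k` points (exactly, when no other-species record shares a
  raster cell with a focal presence).
* **WTGB** — the same points, but each pseudo-absence carries weight
  `W_ik = p_k / a_k`, so the summed pseudo-absence weight equals the summed
  presence weight: `sum_i W_ik = p_k`. This balances the effective class
  prevalence at 0.5 without discarding data.
* **RDM** — `p_k` pseudo-absences drawn uniformly at random from the study
  area excluding the focal presence cells, replicated (four replicates by
  default) and averaged downstream.

## The boosting engine

The engine (`fit_boosted_trees()`, C++ core) is Bernoulli-loss stochastic
gradient boosting with regression-tree base learners:

* Start from `F_0 = logit(sum(w y) / sum(w))`. Weights are first normalized
  to mean one, as the classical implementation does; only weight ratios can
  matter, and with the normalization that invariance is exact.
* At each iteration, fit a tree to the current gradient `y − p` by weighted
  least squares on a `bag_fraction` subsample drawn without replacement.
  Trees grow *best-first* by split gain, up to interaction depth
  `tree_complexity` and at most `2^tree_complexity` terminal nodes, with at
  least `min_obs` rows per side of a split. A depth-`k` tree can express up
  to `k`-way interactions.
* Terminal values are the weighted Newton step
  `sum(w (y − p)) / (sum(w p (1 − p)) + 1e-6)`; the `1e-6` stabilizer
  guards pure nodes. Every tree's contribution is shrunk by
  `learning_rate`.

Numerical conventions worth knowing: split points are midpoints between
consecutive distinct values; candidate splits are scanned in predictor
order and accepted only on *strictly* greater gain, so ties resolve to the
lowest predictor index and lowest split value; gains below `1e-10` are
treated as zero (they are floating-point noise around a mathematically zero
gain, e.g. in a node with constant residuals) so a node is never split on
noise. Rows with `x` equal to the split value go right, consistent with the
half-open cell conventions elsewhere in the package.

`gbm_step_fit()` selects the ensemble size the way the familiar stepwise
cross-validation routine does: class-stratified folds, trees added in
`step_size` increments, the mean held-out deviance tracked per step, the
search stopped after `patience` steps without improvement (or at
`max_trees`), the argmin candidate selected, and the returned model refit
on all rows at that size. A warning is raised when fewer than 1000 trees
are selected, the conventional sign that the learning rate is too
aggressive for the data. Fold assignment, bagging and the refit all derive
from `params$seed`, and the caller's RNG state is left untouched.

`select_bag_fraction()` tries the candidate bag fractions (0.5 and 0.75 by
default) and keeps the one with the lowest mean held-out deviance, ties
going to the smaller fraction.

## Evaluation conventions

**Two deviance normalizations exist, and the distinction is load-bearing.**
`weighted_deviance()` defaults to the per-unit-weight form
`−2 sum(w ll) / sum(w)`, a weighted mean that is invariant to rescaling all
weights. But every *reported* cross-validation deviance in this package
(`gbm_step_fit()`, `collect_cv_metrics()`, `run_study()`) uses the
per-observation form `−2 sum(w ll) / n` (`average = "obs"`), which is the
convention of the classical BRT cross-validation toolchain. Under that
convention a weighted background with `sum(w) = 2 p_k` over `n = D` rows has
a near-null deviance of roughly `(2 p_k / D) · 2 log 2` — for presence
counts 73/24/55 in a 320-record group, about 0.63/0.21/0.48 — which is why
weighting the background produces the large apparent calibration gain over
the unweighted scheme (null deviance ≈ 1.08 at prevalence 0.23) and why the
balanced random scheme sits highest (null ≈ 1.386 at prevalence 0.5). The
per-observation choice is deliberate: it is the only reading under which
the published pattern of scheme differences is reproducible, and the
multi-seed study in `analysis/05_multiseed_pattern.R` reproduces exactly
that ordering (WTGB < UTGB < RDM for every species and seed).

Other conventions: AUC is the rank-based (Mann–Whitney) statistic with
midrank ties, identical to trapezoidal ROC integration; per-fold AUC is
unweighted. The TSS sweep uses thresholds 0.00–1.00 in steps of 0.01 with
"presence iff score ≥ threshold" (ties count as presence), reports the
maximizing threshold (lowest on ties) and the 10th percentile of presence
scores (type-7 linear interpolation) with its TSS; TSS is computed on
training predictions, matching the protocol of comparing the binary
training labels with the model output. The comparison cascade runs
Shapiro–Wilk on each sample and Levene (centred on the mean) across the
pair, then a two-tailed pooled-variance t-test if all p > 0.05 and a
two-sided Wilcoxon–Mann–Whitney otherwise; the pooled t-test is safe
because homoscedasticity was verified one step earlier. Samples are
per-fold values (n = folds) for the target-group schemes and per-replicate
mean CV values (n = replicates) for the random scheme — deliberately
unbalanced, as in the protocol being modelled.

## Interpretation

Relative influence is the per-predictor sum of split gains over the used
trees, normalized to percentages (ties broken alphabetically). Partial
dependence uses a weighted tree traversal that is *exact*: at splits on a
target predictor the branch is dictated by the grid value, at other splits
the training rows descend both branches according to their own values, and
each leaf contributes its value times the weight mass reaching it. This
equals brute-force "clamp the predictor, average the predictions" to
machine precision (asserted at 1e-9 in the tests) while touching each
tree once per grid set. Curves use an evenly spaced grid over the observed
range; surfaces use a lattice of within-range quantile levels (20 by
default).

The pairwise interaction size fits, by least squares, the additive
row-plus-column model to the two-predictor partial-dependence surface on
the logit scale and reports 1000 × the mean squared residual — the
departure of the joint response from additivity. Two caveats are
documented deliberately. First, the score measures the *fitted model's*
non-additivity, which for small samples includes spurious interaction
learned by depth ≥ 2 trees; separating additive from interactive
ground truths therefore needs adequately resourced fits (the tests use
n = 600, learning rate 0.04, 250 trees, where a strong product term scores
30–80 times higher than an additive one). Second, the score does *not*
tend to zero as the lattice is refined — it converges to the model's
intrinsic non-additivity; only a structurally additive ensemble (depth-1
trees) scores numerically zero at every resolution.

## Projection and discretization

`project()` predicts every cell of the layer stack, flags cells with any
missing predictor as no-data, and `average_replicates()` means the random
replicates cell by cell before mapping. `discretize_and_areas()` cuts the
0–1 suitability scale into the five classes 0–0.2, …, 0.8–1.0 with
half-open intervals (a value exactly on a boundary joins the upper class;
1.0 stays in the top class) and converts cell counts to hectares via an
explicit `cell_area_ha` (default 86 ha in the study configuration,
imitating 30 arc-second cells) — the boundary and area conventions are
stated because neither is forced by the class definitions.

## The synthetic study system

`make_env_stack()` builds each layer as a mix of a shared latent field and
a layer-specific field (mixing weight `sqrt(correlation)`), each being
Gaussian-smoothed white noise plus a planar gradient of random orientation,
standardized. The last two layers become topography: `SLOPE = 10 |z|`
(degrees) and `ASPECT = 110 z mod 360` (degrees); the non-linear transforms
mean the correlation target applies to the climatic layers. Presences are
sampled at cell centres without replacement, proportional to a logistic
suitability surface, and species occupy distinct cells by default so the
`a_k = D − p_k` identity holds exactly.

The default community (`default_species_set()`) mirrors the study
conditions: a 320-record target group whose focal species have 73, 24 and
55 presences — a generalist (broad climatic preferences, no dominant
driver), a slope specialist (steep, north-east-facing, wet cells: strong
`SLOPE`, negative `ASPECT`, positive `BIO3`) and a lowland specialist
(flat, wet cells) — plus a 168-record filler group. Effect sizes were
calibrated once so that the fitted models sit at the reported operating
points of the system being emulated (generalist random-background AUC
≈ 0.71 and deviance ≈ 1.25; specialist AUCs ≈ 0.83–0.85), and are not
revisited. The landscape is 20 × 20 cells with 8 layers at correlation
0.6; the boosting defaults for this scale are learning rate 0.01, tree
complexity 5, 10 folds, 25-tree steps, at most 500 trees, bag fraction
chosen from {0.5, 0.75}. These sizes keep a full three-species,
three-scheme, five-seed replication in the low minutes on one core; the
full-scale parameterization (learning rate 0.001, at least 1000 trees,
landscape-sized grids) is available by overriding `study_config()` and
`brt_params()`.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: real bioclimatic layers are physical quantities
with long-range structure and units, not standardized Gaussian fields;
occurrence data carry observer bias, GPS error and imperfect detection;
real species' responses are not exactly linear-logistic; and a 400-cell
landscape cannot express the environmental distance effects of a 160,000-cell
park. The synthetic system is a test bench for the *methods* — count and
weight identities, engine correctness, metric identities, and the
qualitative scheme pattern — not a substitute for real-data validation.

## Moran's I screening

Occurrence sets are screened for global spatial autocorrelation before
modelling: points are aggregated onto a coarsened count grid (half-open
cells) and Moran's I is computed with binary queen contiguity by default
(rook and inverse-distance weights are available; the scheme is recorded in
the result because the index depends on it). Significance uses the
randomization null `E[I] = −1/(n−1)` with the kurtosis-corrected
randomization variance and a two-sided normal p-value; a permutation mode
(≥ 999 relabelings) validates the analytic null in the tests. Exact
reproduction of any particular published index value is out of scope: the
original weight convention is not recoverable, and the screening decision
(is there clustering worth worrying about?) only needs the sign and
magnitude of z.

## Known limitations

* The random-scheme replicate spread: at the desk scale used here, the
  replicate-to-replicate deviance spread of RDM reliably exceeds the WTGB
  fold spread for every species and the UTGB fold spread for the narrowest
  specialist, but for wider-ranging species RDM-vs-UTGB spreads are
  statistically indistinguishable — with only 4 replicates and a 400-cell
  landscape the background draws are too similar for more.
* The engine implements Bernoulli loss only, without monotonic constraints
  or categorical predictors; `tree_complexity` is read as interaction
  depth.
* Serialized models (`brt_to_json()`) predict but cannot recompute partial
  dependence, which needs the training data.
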