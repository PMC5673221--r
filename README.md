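# tgbsdm — target-group background pseudo-absence strategies for boosted regression tree SDMs

Species distribution models for amphibians and other under-surveyed taxa
usually start from presence-only records, so a presence–absence learner such
as boosted regression trees (BRT) must be fed artificial absences. This
package is for modellers and protected-area ecologists who need to decide
*how* to generate those pseudo-absences. It implements the three strategies
most relevant to single-survey data, the full BRT fitting and evaluation
protocol around them, and a virtual-species simulator so the entire
comparison runs end-to-end with known truth.

## The methods at the core

For a target group of surveyed species with `D` pooled presence records, a
focal species with `p_k` presences gets:

* **UTGB** (unweighted target-group background) — the other species'
  presence points, excluding any that share a raster cell with a focal
  presence, so `a_k = D − p_k` pseudo-absences; the background shares the
  survey's sampling bias.
* **WTGB** (weighted) — the same points, each weighted
  `W_ik = p_k / a_k`, so that `Σ W_ik = p_k`: total pseudo-absence weight
  equals total presence weight.
* **RDM** — `p_k` random cells outside the focal presences, with several
  replicates averaged.

Models are weighted stochastic gradient-boosted tree ensembles with
Bernoulli loss (shrinkage `lr`, interaction depth `tc`, bag fraction
selected from {0.5, 0.75}), with the ensemble size chosen by stepwise
10-fold cross-validation. Evaluation uses fold-level rank-based AUC and
weighted deviance `−2 Σ w·[y log p + (1−y) log(1−p)] / n`, TSS
(`sensitivity + specificity − 1`) swept over thresholds 0–1 in 0.01 steps
with the max-TSS and 10th-percentile threshold rules, and a
Shapiro–Wilk / Levene / t-test / Wilcoxon–Mann–Whitney cascade for scheme
comparisons. Interpretation provides gain-based relative influence, exact
weighted-traversal partial dependence, and pairwise interaction sizes
(1000 × the non-additive residual of the 2-D partial-dependence surface).
Projections are discretized into the five suitability classes 0–0.2 …
0.8–1.0 with per-class areas. Moran's I (randomization null) screens
occurrence grids for spatial autocorrelation.

## Worked example

```r
library(tgbsdm)

stack <- make_env_stack(20, 20, n_layers = 8, correlation = 0.6, seed = 1)
group <- make_target_group(stack, default_species_set(), seed = 102)
group
#> <target_group> 4 species, D = 320 records
#>   generalist_toad              p_k = 73
#>   slope_salamander             p_k = 24
#>   lowland_newt                 p_k = 55
#>   filler_frog_group            p_k = 168

pa <- generate_wtgb(group, "slope_salamander")
pa
#> <pseudo_absence_set> WTGB for 'slope_salamander': a_k = 296, sum(w) = 24
```

The 24-presence species gets `a_k = 320 − 24 = 296` pseudo-absences whose
weights sum back to 24 — the defining identity of the weighted scheme. Now
fit, evaluate and map:

```r
td  <- build_training_data(stack, group$species_sets$slope_salamander, pa)
fit <- gbm_step_fit(td$X, td$y, td$w,
                    brt_params(learning_rate = 0.01, tree_complexity = 5,
                               bag_fraction = 0.75, n_folds = 10,
                               step_size = 25, max_trees = 500, seed = 1))
fit
#> <brt_model> 75 trees (of 75 fitted), 8 predictors, lr = 0.01, tc = 5, bag = 0.75
#>   CV (10 folds): mean held-out deviance 0.1821, mean AUC 0.8027 at 75 trees

head(relative_influence(fit), 3)
#>   predictor contribution
#> 7     SLOPE    72.409391
#> 8    ASPECT    14.207816
#> 3      BIO3     3.584533

tss_profile(predict(fit), td$y)
#> <tss_profile> max TSS 0.8818 at threshold 0.51; TSS 0.7838 at 10th-percentile threshold 0.58407

discretize_and_areas(project(fit, stack), cell_area_ha = 86)
#> <suitability_raster> 20 x 20 cells, values 0.230-0.715
#>   class areas (ha / %):
#>     0.0-0.2         0.0    0.00%
#>     0.2-0.4     24768.0   72.00%
#>     0.4-0.6      4472.0   13.00%
#>     0.6-0.8      5160.0   15.00%
#>     0.8-1.0         0.0    0.00%
```

The virtual slope specialist is recovered faithfully: `SLOPE` and `ASPECT`,
its true drivers, top the contribution ranking (72% and 14%), held-out
discrimination is good (AUC 0.80), the weighted background pulls the
deviance far below the 2·log 2 ≈ 1.386 uninformative level, and the map
concentrates suitability in the middle classes rather than collapsing into
0–0.2 as unweighted backgrounds tend to.

The full study — simulate, screen with Moran's I, fit all three schemes for
all three focal species, compare them statistically, interpret and map — is
one call, `run_study(study_config(seed = 1))`, and the numbered scripts
under `analysis/` run it as a narrative (simulation, autocorrelation
screening, fitting, scheme comparison, and a five-seed replication of the
headline calibration pattern), writing tables and rasters under `results/`.

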