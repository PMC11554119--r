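# pescale

Simulation and analysis pipeline for a recurring question in visual
predictive processing: when a learned expectation is violated, **what kind
of surprise does the increased sensory response encode?** In a cued
statistical-learning fMRI design — letter cues predicting object images
with 7:1 odds — the prediction-error response on unexpected trials can be
regressed on how dissimilar the seen image is from the expected one under
different feature models: early ("low-level") and late ("high-level")
layers of a visual feature hierarchy, animacy category, or word-level
semantics. If early visual cortex predicts its own features, its surprise
response should scale with low-level dissimilarity; if high-level
predictions are broadcast down the hierarchy, even V1's prediction errors
should scale with high-level dissimilarity.

`pescale` implements that analysis end to end and, because real data of
this kind are large and access-controlled, ships a synthetic-data generator
with planted ground truth so every estimator is testable by parameter
recovery. It is intended for methodologists who want a compact, fully
seeded reference implementation of this family of analyses.

## The model

For unexpected trial $t$ with expected image $e(t)$ and seen image $s(t)$,
surprise under feature model $m$ is the correlation distance
$d_m(t) = 1 - \mathrm{cor}\big(f_m(e(t)), f_m(s(t))\big)$, z-scored within
subject. Two complementary estimators quantify scaling:

* **Parametric modulation GLM** — condition regressors (expected,
  unexpected, no-go; 0.5-s events, double-gamma HRF) plus one z-scored
  modulator per feature model on the unexpected trials, temporal
  derivatives and nuisance; OLS per voxel, fixed effects over runs,
  one-sample t / Wilcoxon over subjects.
* **Single-trial regression** — least-squares-separate (LSS) betas per
  trial, regressed on $z(d_m)$ per subject
  ($\beta_t = b_0 + b_1 z_t + \varepsilon_t$), group test on slopes $b_1$;
  per-voxel best-layer maps from single-layer $R^2$.

Around these sit searchlight RSA (cosine-distance neural RDMs, Kendall
tau-a against layer RDMs) for the feedforward gradient, linear-SVM decoding
(ROI voxel selection, true-class-probability vs surprise), and behavioural
statistics (Greenhouse–Geisser RM-ANOVA, Holm post-hocs, Cousineau–Morey
within-subject CIs, JZS Bayes factors).

## Worked example

Simulate four subjects whose unexpected-trial responses scale with
high-level (layer-8) surprise at slope 2 in a planted voxel population,
then recover the slope through the LSS → regression path:

```r
library(pescale)

st  <- stimulus_set()
tpm <- build_tpm(st)
print(tpm)
#> <tpm> trials per run (cue x image)
#>    image
#> cue dog tiger swan elephant car hammer guitar house
#>   b   7     1    1        1   1      1      1     1
#>   d   1     7    1        1   1      1      1     1
#>   ...

subject_fit <- function(s) {
  rd    <- layer_rdms(st, seed = s)            # instance-averaged layer RDMs
  fh    <- synth_feature_hierarchy(st, seed = s)
  truth <- default_truth(c(10, 10, 6), fh[[8]], slope = 2, seed = s)
  run   <- generate_run(tpm, st, seed = 100 + s)
  sv    <- list(layer2 = trial_surprise(rd$layer2, run, "layer2"),
                layer8 = trial_surprise(rd$layer8, run, "layer8"))
  bold  <- synth_bold(run, sv["layer8"], truth, noise_sd = 1, seed = 200 + s)
  betas <- lss(highpass(bold_matrix(bold)), run, tr = 1)
  roi   <- match(which(truth$populations == "high_scaling"), which(bold$mask))
  dplyr::mutate(
    dplyr::bind_rows(scaling_regression(betas, sv$layer2, voxels = roi),
                     scaling_regression(betas, sv$layer8, voxels = roi)),
    subject = s)
}

slopes <- purrr::map_dfr(1:4, subject_fit)
scaling_group(slopes)
#> # A tibble: 2 × 9
#>   model_id     n statistic        p effect_size mean_slope mean_r ci_low ci_high
#>   <chr>    <int>     <dbl>    <dbl>       <dbl>      <dbl>  <dbl>  <dbl>   <dbl>
#> 1 layer2       4      3.75 0.0331          1.87      0.389  0.201 0.0587   0.719
#> 2 layer8       4     24.5  0.000148       12.3       1.86   0.959 1.62     2.10
```

The layer-8 group slope (1.86, CI [1.62, 2.10]) recovers the planted value
of 2 (LSS on overlapping event designs attenuates slightly); the layer-2
slope is small and reflects only layer 2's residual correlation with
layer 8 — in the study-scale simulations, per-subject stimulus sets are
additionally optimized to decorrelate the two layers' RDMs, which drives
the layer-2 slope to zero.

`run_pipeline(pipeline_config(...))` chains the full path — design →
features → BOLD → GLM → LSS → localizer decoding → ROI scaling → group and
behavioural statistics — for any number of synthetic subjects and writes a
manifest with content hashes for reproducibility.

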