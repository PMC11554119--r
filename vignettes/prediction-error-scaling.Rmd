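---
title: "Modeling and recovering high-level surprise scaling of visual prediction errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and recovering high-level surprise scaling of visual prediction errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pescale)
```

## The scientific question

After statistical learning, visual cortex responds more strongly to
unexpected than to expected stimuli. `pescale` implements the analysis
pipeline that asks *what kind* of surprise drives that up-regulation: does
the prediction-error response in a given area scale with how dissimilar the
seen stimulus is from the expected one in that area's *own* feature space
(local tuning), or with dissimilarity in a *high-level* feature space
broadcast down the hierarchy? The pipeline operationalizes "dissimilarity
at level *l*" as the correlation distance between stimulus representations
in layer *l* of a deep-network-like feature hierarchy, and asks whether the
single-trial BOLD response to unexpected images grows linearly with that
distance.

The package is simulation-first: every input the analysis needs is
generated with planted ground truth, so each estimator can be checked by
parameter recovery, and the headline qualitative phenomenon — a
low-to-high feedforward gradient in localizer responses alongside a
uniformly high-level prediction-error preference — can be reproduced end
to end.

## Experimental design model

The paradigm pairs 8 letter cues one-to-one with 8 images (4 animate, 4
inanimate). Per run the paired image follows its cue 7 times and every
other image once (`build_tpm()`): cue reliability is exactly 7/14 = 0.5 and
every image appears 14 times, so stimulus frequency cannot confound
expectation. A 128-trial run adds 16 no-go trials (vowel cue, uniformly
drawn image). Behavioural blocks triple the expected-pair count (21) and
double the no-go count (256 trials). Localizer runs present each image in
four 12-s miniblocks (15 cycles of 500 ms on / 300 ms off) and each
phase-scrambled version in two, with a brightness target at one uniformly
drawn cycle outside the first 3 and last 2.

Trial order is randomized under the constraint that the same cue–image pair
never repeats on consecutive trials. Plain rejection sampling is used
first; for behavioural blocks, where an admissible order is too rare for
rejection alone (21 copies of each expected pair in 256 slots), violating
positions are repaired by swapping with admissible partners inside the same
seeded loop, so generation stays deterministic given the seed.

Intertrial intervals are exponential, offset to the minimum and truncated
at the maximum (run: mean 5 s, range 3–12 s; block: mean 2.5 s, range
1.5–7.5 s). The rate is solved numerically so the *truncated* mean hits the
target, and draws use the inverse CDF of the truncated law — equivalent in
distribution to resampling out-of-range draws, with no boundary atoms.

## Feature hierarchy and surprise

`synth_feature_hierarchy()` stands in for layer activations of a trained
visual network. Two independent latent stimulus factor matrices ("low" and
"high") are mixed with per-layer weight $w_l$ rising from 0 to 1; features
are `sqrt(1 - w_l) * low %*% P + sqrt(w_l) * high %*% Q` plus feature
noise. The square-root amplitudes make the layer's representational *gram*
a linear mixture of the two latent geometries, so adjacent layers are more
similar than distant ones and the schedule is interpretable in RDM space.
Instances share the latent factors and differ only in projections and
noise; layer RDMs (`correlation_rdm()`, 1 − Pearson over feature rows) are
averaged over 10 instances (`layer_rdms()`) to suppress instance
idiosyncrasies. An "untrained network" control is a hierarchy drawn with an
independent seed.

Trial-wise surprise (`trial_surprise()`) is the model dissimilarity between
the image the cue predicted and the image actually seen, z-scored across a
subject's unexpected trials. Z-scoring uses the sample (n − 1) standard
deviation; the choice only rescales slopes uniformly and does not affect
inference. Control models are the binary animacy RDM (task-relevant
response category) and a correlation-distance RDM over supplied word
embeddings (semantic surprise); embeddings are an input, never trained
here.

Stimulus sets are optimized per subject (`select_stimulus_set()`): among
random admissible 4 + 4 subsets of a pool, the score
`var(low ltv) + var(high ltv) − |r(low ltv, high ltv)|` (ltv = RDM lower
triangle) is maximized with unit weights — the simplest scalarization of
"maximize within-layer variance, minimize across-layer correlation". The
search is sampled (default 1,000 candidates), not exhaustive; the selection
can run directly on precomputed instance-averaged pool RDMs. Pool outliers
are flagged (`flag_outliers()`) by average-linkage agglomerative clustering
on correlation distance, cut at the number of categories; a stimulus is
excluded when it is the sole member of its category outside that category's
modal cluster. The linkage, cut height and sole-member rule are
configurable choices; only an example of the intended rule is fixed by the
design.

## BOLD model and first-level estimation

Synthetic BOLD (`synth_bold()`) is a linear time-invariant model: each
image is a 0.5-s boxcar convolved with a double-gamma HRF (response peak
6 s, undershoot peak 16 s, amplitude ratio 6, peak-normalized), with
per-trial amplitude `baseline + sum_m slope_m * z_m(trial)`. Slopes live in
a planted voxel population recorded in a `ground_truth` object, so recovery
is checkable exactly: at zero noise the GLM returns planted slopes to
numerical precision. Drift is a random-amplitude combination of the
discrete-cosine components with periods above 128 s, i.e. exactly the null
space of the high-pass filter — the filter-removes-drift property is
therefore testable. Noise is white Gaussian by default with an optional
AR(1) toggle. Nuisance regressors (`synth_nuisance()`) model six motion
parameters as stationary AR(1) fluctuations (head motion is bounded, not a
random walk — a random-walk model would make the confounds mutually
collinear in a way real confound sets are not), framewise displacement as
the motion-derivative magnitude, and CSF/WM means as slow AR(1) plus noise.

Design matrices (`build_design()`) hold HRF-convolved condition regressors
(expected, unexpected, no-go), one z-scored parametric modulator per
feature model built on the unexpected-trial boxcar, optional first-order
temporal derivatives, and nuisance columns, convolved on a 16× oversampled
grid. Modulators are *not* serially orthogonalized against the condition
regressors: shared variance is deliberately discarded rather than
attributed. Estimation is voxel-wise OLS; run-level contrasts combine
across runs by inverse-variance fixed effects; group inference is a
one-sample t (Cohen's dz) or Wilcoxon signed-rank (matched-pairs
rank-biserial) across subjects, two-sided throughout. Collinearity is
monitored by per-regressor VIFs (1/(1 − R²) after mean removal). Cluster
inference replaces parametric random-field correction with sign-flip
permutation of subject maps (26-connectivity, max-cluster-extent null) —
assumption-free and verifiable by simulation. Where multiplicity is
corrected, Benjamini–Hochberg FDR is used for ROI × modulator families and
Holm–Bonferroni for behavioural post-hocs.

Single-trial estimates use least-squares-separate (`lss()`): per trial, a
design with the trial's own regressor, one regressor per image identity
for the remaining go trials, a no-go regressor and nuisance. Temporal
derivatives are omitted in LSS iterations (configurable). On designs
spaced beyond the 32-s HRF support, LSS equals a one-regressor-per-trial
least-squares fit to machine precision, which the tests use as an oracle.

## RSA, scaling and decoding

Searchlights are 6-mm spheres at 2-mm voxels (123 members deep in a mask).
Neural RDMs z-score localizer stimulus betas per voxel and take cosine
distances; model comparison uses Kendall tau-a over RDM lower triangles
(the RSA-field convention when candidate models predict ties; tau-b is
available by flag), Fisher-z transformed for group inference. The
feedforward best-layer map labels each sphere with the layer of maximal
group-mean correlation, thresholded at group z ≥ 3.1, ties broken toward
the earlier layer.

The headline analysis (`scaling_regression()`) regresses unexpected-trial
LSS betas (ROI mean or per voxel) on z-scored surprise, per subject, and
tests slopes against zero across subjects. The prediction-error best-layer
map uses one single-layer regression per layer and compares explained
variance (R²) per voxel — deliberately not a joint eight-predictor model,
because neighbouring layers' surprise vectors are strongly correlated and
joint estimation would split their shared variance arbitrarily. The map is
thresholded at a liberal group z ≥ 1.96. For whole-brain scaling maps the
source data carry 5-mm smoothing plus an additional 3-mm pass; note that
sequential Gaussian widths compose in quadrature (√(5² + 3²) ≈ 5.8 mm),
not additively to 8 mm — the sequential operation is what is implemented.

ROI construction dilates anatomical masks with a 3-mm Gaussian kernel,
assigns voxels shared between masks to the smaller mask, and selects the
200 most stimulus-informative voxels by localizer decoding accuracy
(`top_k_decoding`; `bottom_k_decoding` provides stimulus-uninformative
control ROIs and `stimulus_driven` the z > 3.1 alternative; k sweeps
100–500 are supported). Voxel selection always derives from localizer data
only, never from main-task data, so selection cannot bias the scaling
tests.

Decoding uses linear SVMs (cost = 1, the library default, logged) with
stratified 4-fold cross-validation for the searchlight accuracy map, and
pairwise-coupled probability calibration for the true-class-probability
analysis: a decoder trained on prediction-free localizer patterns predicts
class probabilities on unexpected main-task trials, and the probability
assigned to the class actually shown is regressed on high-level surprise.
A uniform decoder yields exactly 1/8 = 0.125. Expectation-condition
decoding averages single-trial estimates per object × condition × run
before testing.

Bayes factors for null results use the default-prior JZS one-sample test
(Cauchy scale 0.707) by numerical integration in log space — computed
natively rather than through an external GUI.

## Behavioural statistics

Reaction times outside (100, 1,500) ms are excluded — the bounds are
written as strict inequalities, so boundary values are retained — and only
correct responses enter the RT analysis. Unexpected trials split by
animacy agreement with the expected image into same- vs different-response
conditions. The three-condition repeated-measures ANOVA applies
Greenhouse–Geisser correction whenever ε < 1 (ε from the double-centered
condition covariance; Huynh–Feldt is not used, keeping one uniform rule);
partial eta squared is SS_effect/(SS_effect + SS_error). Post-hoc paired t
tests are Holm-corrected. Within-subject error bars follow the
Cousineau–Morey procedure: remove subject means, add the grand mean,
rescale condition variances by C/(C − 1). Subject exclusion applies a
directional 2-SD rule per quality metric (higher-is-worse for FD, FD%,
DVARS and RT; lower-is-worse for tSNR and accuracy). Synthetic behaviour
plants the facilitation ordering with condition means 501 / 509 / 524 ms,
a common 90-ms RT spread, and small condition-dependent error rates —
values chosen to match the published group means and a typical
speeded-response variability.

## What the generator does and does not emulate

The simulator reproduces the design arithmetic exactly, linear
HRF-convolved responses with planted scaling, layered representational
geometry with instance averaging, selective-pattern localizer responses
(intact > scrambled), and response-time facilitation. It does not model
nonlinear haemodynamics, motion artifacts, physiological noise structure,
spatial autocorrelation of noise, or realistic anatomical geometry, and its
feature spaces are Gaussian latent mixtures rather than trained network
activations. Passing recovery tests therefore demonstrates estimator
correctness under the stated linear model — not robustness to everything
real data contain.

## Problem sizes and numerical choices

Simulated volumes default to 20 × 20 × 10 voxels at nominal 2-mm spacing
and TR 1 s — large enough for 6-mm searchlights with genuine region
interiors, small enough that a full synthetic subject runs in seconds. The
bundled test suite uses 100 replicate designs for the collinearity check,
200 replicates of a 33-subject study for power and type-I bounds (run at
the trial-beta level, with the BOLD→LSS→beta link verified separately by
exact noise-free oracles and a reduced-volume end-to-end recovery), and 8
synthetic subjects at full volume for the gradient phenomenon. Degenerate
inputs fail loudly: zero-variance feature rows, constant dissimilarity
models, rank-deficient designs, and single-condition CI requests are
errors, not silent results. Fisher z of |tau| = 1 is clamped at
atanh(1 − 1e−12) with a warning.

## Known limitations

Run-level autocorrelation is handled by OLS with an optional AR(1) toggle
rather than full prewhitening; group-level inference over subjects, which
is the surface this package tests, is robust to that choice at these
scales. The candidate count of the stimulus-set search and the clustering
cut of the outlier screen are unstated in the underlying design and are
exposed as arguments. The SVM's probability calibration affects the scale
of probability-vs-surprise slopes; the calibration method is therefore
fixed (pairwise coupling) and recorded.
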