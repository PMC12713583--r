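---
title: "Methods: from spike trains to functional clusters, trajectories and decoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spike trains to functional clusters, trajectories and decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spikechoice` implements a complete analysis chain for single-neuron spike
trains recorded during a value-guided saccadic choice task, together with a
synthetic generator that plants known structure so that every stage can be
validated by parameter recovery.  This vignette explains the models and the
choices behind them; the package's tests compute every empirical claim made
here.

## Task and data model

The task the package assumes is a sequential choice paradigm: a background
scene (1000 ms) is followed by central fixation (700 ms), then a single
"good" (rewarded) or "bad" (unrewarded) object appears in the contralateral
or ipsilateral hemifield.  The subject accepts the object by foveating it or
rejects it by a return saccade, by staying at fixation, or by looking
elsewhere.  Scenes 1–2 carry stable object values; scenes 3–4 reverse the
contingencies, so value must be read from the scene context.  Reaction time
(RT) is the interval from target onset to saccade onset.

Data enter the package as two tidy tables: spike times per (neuron, trial)
and a trial table with design factors, choice, RT and event times.  Each
neuron owns its session of trials — neurons were not recorded
simultaneously — which makes the neuron the unit of non-independence for
every statistical procedure downstream.  The trial table therefore carries a
`neuron_id` column.

## Spike density and baseline normalization

Spike trains aligned to scene, target, or saccade onset are binned at 1 ms
(half-open bins `[t, t+1)`) and convolved with a unit-area Gaussian kernel,
SD `sigma_ms = 20` ms, truncated at ±4 SD.  Edges are zero-padded without
mass renormalization, so estimates within ~80 ms of a window edge are
attenuated; analysis windows are chosen with an 80-ms margin so that no
statistic is read from the attenuated region.

Activity is z-transformed against a 500-ms pre-event baseline: the aligned
event's own baseline (pre-scene for scene-aligned activity, pre-target for
target-aligned).  The baseline statistics are pooled across all of a
neuron's trials (all baseline bins of all trials).  Whether standardization
should be per trial or pooled per neuron is genuinely open; pooling is the
default because single-trial baseline SDs of low-rate neurons are extremely
noisy (a 500-ms window at 15 Hz holds ~7 spikes), and a `per_trial` mode is
available behind a flag.  Neurons with zero baseline SD (silent or constant
units) are excluded with a warning rather than propagating infinities.

## Functional clustering

The clustering feature of a neuron is two numbers: its mean z-scored
activity 100–300 ms after contralateral good-object and contralateral
bad-object onsets (ipsilateral trials are deliberately not part of the
feature vector).  K-means uses Euclidean distance on these raw 2-D features
without re-standardization, since both coordinates are already on the
common z scale.

The number of clusters is selected by repeated silhouette evaluation: for
each K in 2–6, k-means is repeated from random initializations (each repeat
the best-of-10 k-means++ style starts by within-cluster sum of squares) and
the mean silhouette width of each repeat's solution is averaged; the K with
the highest average wins.  The repeat count is 5000 at full scale and is
configurable; recovery tests use 20–500 repeats, which is ample for a 2-D
feature space where repeats differ little.

A three-cluster solution is relabelled canonically from its centroids:
label 2 is the centroid with the most negative bad-object feature (the
bidirectional value-coding profile), label 1 the remaining centroid whose
good-object feature exceeds its bad-object feature, label 3 the other.
Ties break by descending good-object feature, deterministically.

## PCA validation of the groupings

As a data-driven check, the contralateral trial-averaged responses to good
and bad objects over 0–300 ms are stacked as separate rows (2N × 300), each
time column centered and scaled, and decomposed by PCA.  Each neuron's
scores on PC1–3 for the two conditions form a 6-D feature vector that is
clustered with K = 2 and K = 3 and cross-tabulated against the window-based
assignments.  PCA signs are fixed by flipping each loading so its
largest-magnitude element is positive, making score features reproducible.
The package reports cross-tabulations and does not hard-code any expected
agreement.

## Condition and reaction-time mixed models

Condition effects on epoch-mean activity are modelled as
`activity ~ scene * value * direction + (1 | monkey) + (1 | monkey:neuron)`
by REML.  With two subjects the subject-intercept variance is weakly
identified; fits proceed with a boundary-tolerant optimizer and singular
fits are flagged, never hidden.  Whole-model significance uses a parametric
bootstrap against the random-effects-only null: responses are simulated
from the fitted null, both models are refitted, and
`p = (1 + #{LR_sim ≥ LR_obs}) / (n_ok + 1)`; refit failures are counted and
excluded.  The bootstrap is written in-package on top of `lme4::simulate`
and `refit`.  Post-hoc pairwise contrasts among the four value × direction
conditions run within each scene with Bonferroni adjustment over that
scene's six contrasts (the declared family).

Trial-level response parameters are extracted from single-trial z series on
accept trials with contralateral good objects: onset latency is the first
bin after target onset with z strictly above 2 (searching up to the saccade,
so the response precedes the action); the peak is the maximum z within
150 ms from onset; the slope is (peak − z(onset)) / (t_peak − t_onset),
zero when the peak sits at the onset bin.  Trials never crossing the
threshold are flagged non-responsive and excluded with a logged count.
Each parameter's relation to RT is fitted as
`RT ~ parameter + (1 | monkey) + (1 | monkey:neuron)` with Satterthwaite
p-values; with three clusters and three parameters, nine models form the
family and the significance threshold is 0.05/9 (0.0056 displayed at four
decimals, exact internally).

## Sliding-window choice regression

Per neuron, mean activity in a 50-ms window sliding in 1-ms steps over
contralateral trials is regressed on the upcoming choice coded +1 (accept)
and −1 (reject, all three strategies).  With this coding the action
coefficient is exact least squares, and for balanced classes equals half
the difference between class means.  Windows are indexed by center and
reported only where the full window fits.  For display, series are smoothed
with a centered 21-ms moving average whose edge windows use the available
points (length-preserving), and neurons are sorted by preference sign and
then by the first time the smoothed magnitude exceeds twice the SD of the
neuron's pre-target coefficients; this sort rule is the package's own
documented choice, not claimed identical to any published figure.

## Population trajectories and divergence time

Per cluster, trial-averaged spike densities for accept and reject choices
(contralateral trials, each row baseline-corrected by subtracting its
pre-target mean) are concatenated over time and decomposed by a single PCA
with time points as observations and neurons as variables — centered but
unscaled, because spike densities are already on a common physical scale
(spikes/s).  Both conditions are projected onto the first three components
and the Euclidean distance between the trajectories is computed at each
millisecond.  The divergence time is the first post-target sample whose
distance exceeds the baseline mean plus three baseline SDs, with no
persistence requirement (a single-point rule).

The baseline statistics use the 600 ms preceding target onset.  Under
20-ms smoothing, distance samples decorrelate over roughly 40 ms, so a
300-ms window holds only about seven effectively independent samples — too
few for a stable 3-SD threshold (recovery simulations showed unstable SD
estimates producing spurious pre-onset crossings).  Doubling the window to
600 ms, still inside the fixation epoch, stabilizes the rule; this is the
package default.

## Population decoding

Decoding uses elastic-net regression (mixing parameter α = 0.5, fixed a
priori) on spike counts in 1-ms bins from −600 to +600 ms around target
onset, 1200 features per sample.  One sample is one (neuron, trial): since
neurons come from separate sessions, a simultaneous-population feature
vector does not exist, and the per-neuron-sample design is the one under
which grouping folds by neuron is meaningful.  A pseudo-population mode
(condition-matched trial concatenation across neurons) exists behind a flag
for sensitivity analysis; neither mode is claimed to reproduce any
particular published performance value.

Performance is estimated by nested cross-validation grouped by neuron: an
outer 10-fold split assigns whole neurons to folds (greedy bin packing
balances fold sizes); within each outer training set an inner grouped
cross-validation selects the penalty λ maximizing pooled out-of-fold AUC
(choice) or minimizing MSE (RT) along a λ path computed on that training
set (50 values spanning four decades below the coefficient-zeroing λ at
full scale).  Feature standardization happens inside each fit on training
data only.  The final model at the selected λ predicts the held-out fold,
and the overall AUC or cross-validated R² is computed from the pooled
out-of-fold predictions.  Class imbalance is handled by unweighted logistic
loss; AUC is imbalance-robust.

Ablation (each cluster removed) and single-cluster analyses rerun the whole
nested procedure on the subset.  The permutation test shuffles choice
labels within neuron — preserving per-neuron class balance, since the label
shuffling unit is otherwise unspecified — and repeats the entire nested
grouped procedure per permutation (2000 at full scale; far fewer suffice
for calibration checks).

Why grouping matters: neurons have idiosyncratic, temporally structured
firing signatures, and trials of one neuron are therefore not exchangeable
with trials of another.  With trial-level folds, a model can memorize a
neuron's signature together with its incidental class imbalance and appear
to decode labels that are independent of activity.  The test suite
demonstrates this contrast with a construction in which each neuron has a
distinctive temporal bump and a label imbalance assigned independently of
its activity: grouped cross-validation stays at chance while trial-level
cross-validation reports inflated AUC.

## The synthetic generator

The generator emulates the statistical structure the analyses assume:
187-like populations of task-responsive neurons in three response profiles
(good-preferring facilitative; bidirectional good-up/bad-down;
bad-preferring), two subjects, the scene → fixation → target → saccade
trial timeline, contralateral preference, accept/reject choices with
return/stay/other rejection strategies, faster accept than reject RTs, and
a planted linear dependence of RT on the trial's neuronal response-onset
latency.

Firing is an inhomogeneous Poisson process generated by thinning: baseline
rate per neuron drawn log-normal (median 15 Hz, log-SD 0.4, typical of
tonically active basal-ganglia units), plus a condition gain ramping
linearly from the trial's onset latency to a plateau 150 ms later, rectified
at zero.  The linear ramp is a deliberate choice: no parametric response
shape is implied by the analyses, and a ramp makes the onset/peak/slope
extraction well-defined for closed-form checks.  Default plateau gains are
+22/+8 Hz (cluster 1 good/bad), +20/−10 Hz (cluster 2), +5/+20 Hz
(cluster 3) on contralateral trials, halved ipsilaterally — angularly
distinct in the good/bad feature plane, so the population carries the
robust three-cluster structure the analyses assume; onset latency means
are 110/95/125 ms with 15 ms trial-to-trial SD.  Accept-trial RT is
150 + 0.4 × latency + N(0, 25²) ms; reject RTs are shifted 60 ms slower
with SD 40 ms, expressing only the qualitative fact that rejects are
slower.  Good objects are accepted with probability 0.95; bad objects are
rejected via return/stay/other with probabilities (0.70, 0.20, 0.10) in
stable and (0.55, 0.33, 0.12) in flexible scenes, so stay proportions
differ between scene regimes.  Trial counts per (scene × value × direction)
condition default to 20 — the number is not dictated by the analyses and is
configurable; it was chosen to give session sizes (320 trials) typical of
primate recording sessions.

One master seed drives everything; per-neuron streams are derived from it
deterministically, so datasets are bit-reproducible and independent of
neuron processing order.

What the generator does *not* emulate: biophysical spiking dynamics
(refractoriness, bursting, adaptation), eye-position traces and saccade
detection, hemifield geometry beyond a categorical label, slow
session-level drift, and correlated noise across neurons (each neuron's
session is independent).  Passing recovery tests therefore shows that the
pipeline's inferences are correct when its statistical assumptions hold —
not that those assumptions hold for any particular real recording.

## Numerical and scale choices

Degenerate inputs are handled explicitly: zero-baseline-SD neurons are
excluded with warnings; k-means restarts absorb empty-cluster failures and
`K = N` returns singleton clusters directly; rank-deficient populations use
fewer than three components with a flag; constant predictors and
single-class neurons raise errors or are skipped with logged warnings;
Fisher/Kruskal tests run on degenerate tables without crashing.

Recovery tests run at desk scale: clustering recovery uses the full default
population (150 neurons, 20 trials/condition) over 100 seeds with 20
silhouette repeats per K; divergence recovery uses 12 neurons with
deterministic 50-ms onsets, 24 trials/condition and a 1200-ms correction
window over 100 seeds (minimal pre-onset exposure keeps the single-point
3-SD rule's false crossings out of the recovery band); the RT
model runs 400 simulations of 20 neurons × 20 trials; bootstrap calibration
runs 200 × 199 resamples on 8-neuron datasets; decoding checks use 30
neurons at 5 trials/condition with 5 × 4 nested folds and a 20-value λ
path.  The full-scale defaults of record (5000 silhouette repeats, 10 × 10
folds, 50-λ path, 10 000 bootstrap iterations, 2000 permutations) remain
the documented defaults of the corresponding functions.

## Limitations

Cluster-specific quantities reported for any real dataset (cluster sizes,
divergence times, decoding performance) depend on recordings the package
cannot regenerate; the package validates the *procedures* by recovery on
synthetic data and makes no claim to reproduce specific published values.
The monkey-level random intercept is near-unidentifiable with two subjects
and is retained for structural fidelity with singularity flagging.  The
divergence rule is a single-point threshold crossing by design and will
fire on isolated noise excursions when its baseline window is made short;
users analyzing noisy populations should prefer the default 600-ms
baseline.
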