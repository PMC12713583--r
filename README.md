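# spikechoice

Analysis of single-neuron spike trains recorded while a subject chooses to
accept or reject valued objects with saccades.  The package is aimed at
systems neuroscientists who record basal-ganglia (or other subcortical)
neurons one session at a time during value-guided choice tasks and want a
tested, reproducible path from raw spike times to functional cell classes,
trial-by-trial encoding models, population state-space trajectories and
choice decoders.

## What it computes

Given spike-time and trial tables (or its own synthetic data), the pipeline
runs:

1. **Spike density and normalization.**  Event-aligned 1-ms binning, Gaussian
   smoothing (σ = 20 ms) into a spike density function (SDF), and a baseline
   z-transform: z(t) = (SDF(t) − μ_base) / σ_base, with μ_base, σ_base pooled
   over a 500-ms pre-event window.
2. **Functional clustering.**  K-means on each neuron's mean z in 100–300 ms
   after contralateral good- and bad-object onsets; the number of clusters K
   maximizes the mean silhouette over repeated k-means runs (K ∈ 2..6); a
   three-cluster solution is relabelled canonically (1: good-preferring
   facilitative, 2: bidirectional value-coding, 3: bad-preferring).
   Baseline rates are compared across clusters by Kruskal–Wallis.
3. **PCA validation.**  PCA on the stacked 2N × 300 matrix of good/bad
   condition responses (columns standardized); k-means on the 6-D PC1–3
   score features at K = 2 and 3, cross-tabulated against the window-based
   clusters.
4. **Mixed-effects encoding models.**
   `activity ~ scene * value * direction + (1|monkey) + (1|monkey:neuron)`
   with parametric-bootstrap model tests and Bonferroni post-hoc contrasts;
   trial-level onset latency / peak / slope extraction (first z > 2 after
   target onset; peak within 150 ms; slope onset→peak) and
   `RT ~ parameter + (1|monkey) + (1|monkey:neuron)` with Satterthwaite
   p-values at the 0.05/9 threshold.
5. **Sliding-window choice regression.**
   `MeanActivity = β0 + β_Action·Action` (accept = +1, reject = −1) in a
   50-ms window stepped at 1 ms, smoothed and sorted for display.
6. **Trajectories.**  Per cluster, a shared PCA over accept/reject
   trial-averaged baseline-corrected SDFs; divergence time = first
   post-target millisecond where the 3-D inter-trajectory distance exceeds
   baseline mean + 3 SD.
7. **Decoding.**  Elastic net (α = 0.5) on 1-ms spike counts from −600 to
   +600 ms, one sample per (neuron, trial), under nested 10-fold
   cross-validation *grouped by neuron* (λ chosen by inner grouped CV);
   pooled out-of-fold AUC / R², plus ablation, single-cluster and
   within-neuron label-permutation analyses.

A synthetic generator plants three response profiles, choice behavior, and
a linear RT-on-latency dependence with known parameters, so every stage is
validated by parameter recovery in the test suite.

## Worked example

```r
library(spikechoice)

ds <- simulate_dataset(simulation_config(seed = 42))   # 150 neurons, 3 profiles
contra  <- ds$trials[ds$trials$direction == "contra", ]
aligned <- aligned_activity(ds, trials = contra, event = "target",
                            window = c(-580, 400))
features <- build_features(aligned, ds$trials)          # N x (good, bad)

sel <- select_k(features, 2:6, n_repeats = 100, seed = 42)
sel
#> <cluster_selection> chosen K = 3 over 100 repeats per K
#>  k mean_silhouette sd_silhouette
#>  2       0.5777886   0.000000000
#>  3       0.6879549   0.000000000
#>  4       0.6541882   0.002791396
#>  5       0.6037356   0.002422617
#>  6       0.5688520   0.015245129

a <- assign_clusters(features, sel$chosen_k, seed = 42)
labels <- canonicalize_labels(a$cluster, a$centers)
table(labels)
#>  1  2  3
#> 50 50 50
mclust::adjustedRandIndex(labels, ds$neurons$true_cluster)  # 1

compare_baseline_rates(baseline_rate(ds)[names(labels)], labels)$p.value
#> 0.136   # baseline rates do not differ across functional clusters

cluster_divergence(ds, labels)
#>   cluster n_neurons divergence_ms
#> 1       1        50           119
#> 2       2        50            90
#> 3       3        50            84

ft <- build_feature_table(ds, assignments = labels)
nested_cv_elastic_net(ft, task = "choice", k_outer = 5, k_inner = 4,
                      nlambda = 20, seed = 42)
#> <decoding_result> choice decoding: AUC = 0.649
```

Reading the output: the silhouette table selects three functional clusters
and the canonical labels recover the planted profiles exactly (adjusted Rand
index 1) while baseline firing rates carry no cluster information (Kruskal–
Wallis p = 0.14).  Accept/reject trajectories separate 84–119 ms after
target onset — well before the ~190-ms mean accept reaction time — and a
neuron-grouped elastic-net decoder reads the upcoming choice from single
(neuron, trial) spike counts at AUC 0.65 on held-out neurons.

The whole pipeline can also be driven from a YAML config:

```r
report <- run_pipeline(pipeline_config(seed = 1, outdir = "out"))
```

or from the shell via `inst/scripts/run_pipeline.R`.

## Vignette

`vignettes/methods.Rmd` documents the models, every tunable parameter with
its default and rationale, what the synthetic generator does and does not
emulate, and the package's numerical choices.
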