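# cinesync

Reverse-correlation analysis of group-synchronized responses to naturalistic
movie stimuli, with a ground-truth synthetic-study generator.

## The problem

In naturalistic fMRI a group watches the same movie; stimulus-locked
processing appears as *synchronization* — moments where the BOLD signal
deflects the same way across viewers. For clinical questions (the motivating
case: heroin-use-disorder inpatients vs. matched controls watching a
drug-themed movie before and after treatment) the question is *which
content* drives the synchronization, and whether that content bias differs
between groups and changes with treatment.

`cinesync` implements the full statistical pipeline for people analyzing
ROI-level movie-fMRI time series:

- **Preprocessing** from the point volumetric tools leave off: initial-TR
  drop, joint confound/high-pass/detrend projection with z-scoring, global
  (arousal) component extraction and selective-component residualization.
- **Shared response model (k = 1)** per ROI, group and session: alternating
  least squares for `X_i ≈ w_i s`, deterministic initialization, per-subject
  projections `z(w_i' X_i)`.
- **Synchronized-TR detection**: a TR `t` is synchronized when the lower
  bootstrap confidence bound (default 5000 subject-wise resamples) of the
  group median exceeds the 95th percentile of a max-statistic null built
  from phase-randomized surrogates (FFT phase scrambling preserving each
  subject's amplitude spectrum) — family-wise control over TRs.
- **Reverse correlation / content bias**: each synchronized TR maps through
  the 5-10 s hemodynamic lag window to one-second labeled movie bins; the
  bias is the labeled fraction of the unique mapped bins
  (`bias ∈ [0, 1]`). Group differences and group-by-session deltas are
  tested by randomizing TR placement (5000 permutations, two-sided, add-one
  correction) with Benjamini-Hochberg FDR over ROIs.
- **ISC-behavior coupling**: leave-one-out inter-subject correlation per
  subject and ROI, Fisher-z aggregation over an ROI set (e.g. OFC), Pearson
  correlations of ISC (and its session delta) with craving measures under
  BH-FDR, plus sample-profile utilities (pooled two-sample t from summary
  statistics, paired Wilcoxon signed-rank).
- **A synthetic study generator** (`sim_config()` / `simulate_study()`)
  producing two-group, two-session voxel data with known planted structure
  — sparse HRF-convolved salient events inside labeled vs. unlabeled bins,
  per-subject coupling, shared arousal, motion/CSF confound leakage, drift,
  noise, and a craving table linked to the planted coupling — so every
  stage is testable with ground truth and no downloads.

## Worked example

Simulate a study at recovery scale (15 subjects/group, 10 ROIs of which
ROIs 1-3 are drug-locked with the clinical group's drug amplitude falling
1.5 → 0.5 across sessions), run the pipeline, and test biases:

```r
library(cinesync)
library(dplyr)

cfg <- sim_config(n_subjects_per_group = c(15, 15), n_rois = 10,
                  voxels_per_roi = 16, n_trs = 610,
                  drug_locked_rois = 1:3, ofc_rois = 1:3, seed = 2024)
study <- simulate_study(cfg)
study <- preprocess_study(study)
detected <- detect_sync_study(align_study(study),
                              n_boot = 500, n_phase = 500, seed = 1)
bias <- bias_tests(detected, study$label_track, n_perm = 2000, seed = 2)
select(bias, roi, bias_a_base, bias_a_follow, stat_delta, q_delta)
#> # A tibble: 10 × 5
#>      roi bias_a_base bias_a_follow stat_delta q_delta
#>    <int>       <dbl>         <dbl>      <dbl>   <dbl>
#>  1     1       0.816        0.0938    0.734   0.00250
#>  2     2       0.679        0.241     0.366   0.0700
#>  3     3       0.910        0.207     0.660   0.00250
#>  4     4       0.214        0.333    -0.106   0.814
#>  5     5       0.324        0.465     0.0489  0.869
#>  ...
```

At baseline the clinical group's synchronized TRs in the drug-locked ROIs
map overwhelmingly to drug-labeled seconds (bias 0.68-0.91 against a 45%
base rate); at follow-up the bias collapses, and the group-by-session
permutation test flags ROIs 1 and 3 at `q < 0.05` while the seven
content-unbiased ROIs stay null.

The ISC-craving analysis on the same run:

```r
isc <- isc_scores(detected, study$truth$ofc_rois)
isc_behavior_correlations(filter(isc, group == "g1"),
                          filter(study$behavior, group == "g1"),
                          "scene_induced_craving_max")
#> # A tibble: 2 × 7
#>   measure                   contrast     n     r       p q_value discovery
#> 1 scene_induced_craving_max baseline    15 0.322 0.242    0.242  FALSE
#> 2 scene_induced_craving_max delta       15 0.659 0.00759  0.0152 TRUE
```

The session change in aggregated "OFC" ISC tracks the session change in
scene-induced craving (planted latent correlation 0.54), while the baseline
correlation alone does not survive correction — the qualitative pattern the
method is designed to resolve.

`run_pipeline()` wraps the whole chain (simulate → preprocess → align →
detect → bias → ISC/behavior) behind a YAML/list config with
reference-analysis defaults, writing CSV/TSV tables and a JSON manifest;
`validate_inputs()` checks on-disk inputs against their schemas. Result
objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_bias()`
visualizations.

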