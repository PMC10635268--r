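---
title: "Reverse-correlation analysis of group-synchronized movie responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-correlation analysis of group-synchronized movie responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinesync)
```

## The analysis problem

When a group of people watches the same movie, stimulus-locked processing
shows up as *synchronization*: at certain moments the BOLD signal deflects
the same way in most viewers. In clinical naturalistic fMRI the interesting
question is not just *how much* a region synchronizes but *to which content*.
`cinesync` implements a reverse-correlation pipeline for that question:

1. reduce each region of interest (ROI) to one time series per subject with
   a single-component shared response model (SRM);
2. find the time points (TRs) where the *group median* response is larger
   than chance synchronization could explain;
3. map those TRs back — through the hemodynamic lag — to labeled one-second
   movie bins, and summarize the mapped bins as a *content bias* (e.g. the
   fraction of bins carrying drug-related content);
4. compare the bias between groups, and its change across two scanning
   sessions, by permutation tests with Benjamini-Hochberg correction over
   ROIs;
5. relate per-subject synchronization (leave-one-out inter-subject
   correlation, ISC) to behavioral measures such as craving.

The motivating application is drug-cue reactivity: inpatients with a heroin
use disorder and matched controls watching a drug-themed movie before and
after treatment, with the prediction that synchronization in
reward/salience regions is biased toward drug scenes at baseline and that
this bias declines with treatment along with craving.

## Detection model

Within one (group, session, ROI) cell, let $x_i(t)$ be subject $i$'s
z-scored shared-component series. A TR $t$ is *synchronized* when the lower
bound of the bootstrap confidence interval for the group median exceeds a
family-wise threshold:

* **Bootstrap CI.** Subjects are resampled with replacement (default 5000
  draws); the per-TR median of each resample gives a percentile interval
  (2.5th/97.5th at the default 95% level).
* **Max-statistic null.** Each null draw phase-randomizes every subject's
  series independently — FFT, uniform random phases on the free
  frequencies with conjugate symmetry (DC and Nyquist untouched), inverse
  FFT — so surrogates keep each subject's amplitude spectrum and
  autocorrelation but lose stimulus alignment. The per-TR median is
  computed and its maximum over TRs recorded; the 95th percentile of these
  maxima is the detection threshold. Controlling the *maximum* controls
  the family-wise error rate over TRs.

Detection is one-sided (positive deflections), following the logic that
synchronized stimulus responses deflect the shared component upward; a
mirrored negative test is available behind `two_sided = TRUE` but off by
default. Ties at the threshold are resolved as strict inequality
(`ci_low > threshold`).

An important, deliberate property of this construction: because surrogates
preserve the spectrum of the *observed* series — signal included — the null
"chance synchronization" level rises with the strength of the shared
signal. Detection therefore selects the top excursions of the median trace
rather than everything above a fixed cut, and the number of synchronized
TRs stays modest (a few percent of TRs) even at high SNR. The permutation
machinery downstream is designed around such sparse TR sets.

## From TRs to content bias

Analyzed TR indices live in the post-drop frame (the first 10 TRs of the
scan are discarded). For a synchronized TR $t$, the movie moment that
caused it is earlier by the hemodynamic delay; following the fixed-lag
convention, the scan time $m = t + 10$ is mapped to the five one-second
bins $[m - 10, m - 5)$. The union of bins over all synchronized TRs —
duplicates removed, out-of-track bins clipped — is scored against the
binary label track, giving the bias

$$\text{bias} = \frac{\#\{\text{unique mapped bins labeled } 1\}}
                     {\#\{\text{unique mapped bins}\}} \in [0, 1].$$

An empty TR set has no defined bias; such ROIs are excluded from the FDR
family rather than being assigned $p = 1$ (no evidence either way).

Two permutation tests share one null construction — each group's TR set is
replaced by the same number of TRs placed uniformly at random without
replacement over the analyzed range, independently per group, and the
statistic recomputed (default 5000 draws, configurable through `n_perm`):

* **Baseline group difference:** statistic $\text{bias}_A - \text{bias}_B$.
* **Group-by-session delta:** statistic
  $(\text{bias}_{A,\text{base}} - \text{bias}_{A,\text{follow}}) -
   (\text{bias}_{B,\text{base}} - \text{bias}_{B,\text{follow}})$,
  positive when group A's content bias declines more between sessions.

Two-sided p-values use the add-one correction
$p = (1 + \#\{|\text{null}| \ge |\text{obs}|\})/(n_\text{perm} + 1)$, and
BH-FDR runs across ROIs separately per test family. The uniform placement
null preserves the size of the TR set but not its autocorrelation; this
matches the reference procedure, and in practice the session/group designs
cancel most event-level clustering because the same movie drives all cells.

## Shared response model ($k = 1$)

Per (group, session, ROI), the model is $X_i \approx w_i s^\top$ with
unit-norm voxel weights $w_i$ per subject and one shared series $s$. The
fit alternates exact minimizers — $w_i = X_i s / \lVert X_i s\rVert$, then
$s = \tfrac1N \sum_i w_i^\top X_i$ — so the reconstruction objective is
non-increasing; iteration stops at a relative change below $10^{-8}$ or
100 iterations. Initialization is deterministic (leading right singular
vector of the subject-stacked data, computed through the smaller Gram
matrix), and the sign of $s$ is fixed against the mean voxel signal, so no
random state enters the fit. Downstream statistics use the *per-subject
projections* $z(w_i^\top X_i)$: the bootstrap, the leave-one-out ISC and
the behavioral correlations all need subject-level series, which the group
shared series alone cannot provide. Fitting is per session as well as per
group, so session comparisons never share weights.

## Preprocessing

Starting from (simulated) voxel series, per subject and session:

1. drop the first 10 TRs (onset transients), recording the offset so
   TR-to-movie-time mapping stays correct;
2. regress out, in a single least-squares projection: intercept, linear
   trend, a discrete-cosine drift basis containing every frequency below
   $1/140$ Hz, and the confound columns (six motion parameters expanded to
   24 — values, squares, derivatives, squared derivatives — plus CSF);
   z-score each voxel. The joint projection guarantees the residual is
   exactly orthogonal to all nuisance columns; sequential filtering could
   reintroduce drift;
3. average all cleaned voxels into the subject's *global component*
   (z-scored), a proxy for arousal/engagement;
4. keep each voxel's *selective component*: the z-scored residual after
   regressing the voxel on the global component.

The global component is computed after cleaning (the order is recorded in
the run manifest). A z-score of a numerically constant series returns
zeros with a warning rather than NaN, and rows that the projection
annihilates (inputs inside the nuisance span) are zeroed explicitly so
roundoff cannot be amplified.

## The synthetic study generator

`simulate_study()` emulates the study design end-to-end with known ground
truth: two groups (defaults 30 and 25 subjects), two sessions, a 1033-TR
scan at 1 s TR (1023 analyzed seconds), and a binary label track with
exactly 45.4% labeled bins in geometric blocks (default mean scene length
30 s — long narrative scenes).

The stimulus-locked structure is built from *sparse salient events*: about
one eligible bin in five carries a unit impulse; impulses inside labeled
bins and impulses inside unlabeled bins form two event streams per ROI,
each convolved with a canonical double-gamma HRF. For a drug-locked ROI
the shared drive is

$$s_{g,\text{sess}}(t) = A^{drug}_{g,\text{sess}}\, d(t) +
  A^{nondrug}_{g,\text{sess}}\, u(t),$$

where $d$ and $u$ are normalized on a *common* scale (the SD of the
all-events response), so the amplitudes are per-event response heights in
units of the voxel noise SD and equal amplitudes mean equal peak heights.
Every other ROI follows its own unit-variance event series scaled by the
non-drug amplitude — synchronized but content-unbiased, a live null for
the bias tests. Unit-intensity impulses keep the two event types cleanly
separated in peak height, so the amplitude ratio governs which content
dominates the detected synchronization peaks; this is what makes the
planted content bias identifiable by a max-statistic detector whose
threshold scales with total signal power (a boxcar-level parameterization
of the same amplitudes produces fluctuations far too small to detect).

Default amplitudes plant the clinical phenotype: the clinical group's drug
amplitude falls from 1.5 to 0.5 across sessions (non-drug 0.9 throughout),
while the comparison group holds flat at 1.0/1.0. Each subject-session
scales the whole shared drive by a coupling coefficient drawn uniformly
from $[0.5, 1.5]$ — the minimal structure giving nonzero group-median
synchronization plus subject-level ISC variation. On top of the drive,
every voxel receives: a shared per-group-session arousal series (amplitude
0.5) entering all voxels with unit loading; leakage of standardized
motion/CSF confound walks (loading SD 0.3); a random linear drift
(SD 0.3); and white noise (SD 1).

Scene-induced craving is linked to the *planted coupling coefficient*, not
to realized ISC — `round(4 + 2 * coupling + N(0, 0.9))` on a discrete
0-10 scale (the rating scale bounds are an assumption; only the in-scanner
pre/post scale is known to be 0-9) — so recovering the ISC-craving
correlation is a genuine inference problem. These defaults imply a latent
delta-correlation of
$2\sigma_{\Delta c}/\sqrt{4\sigma^2_{\Delta c} + 2(0.9)^2} \approx 0.54$,
the effect size the application domain reports; the truth record carries
it as `planted_rho`. Other behavioral columns (pre-movie craving,
movie-induced craving, HCQ total, demographics) are generated independently
of coupling, serving as specificity controls.

What the generator does *not* emulate: volumetric/spatial structure and
motion in image space, physiological noise spectra, rater disagreement in
labels, habituation across sessions, and any dependence between craving
and non-coupling factors. Passing recovery tests on this generator shows
the pipeline's statistics behave as designed under the planted model — not
that real data meet those assumptions.

## Validation experiments

Two experiment functions bundle the study-scale checks; both are exercised
by the test suite and the acceptance script.

* `calibration_experiment()` — family-wise error under the global null:
  one group of 15 subjects, 20 ROIs of 4 voxels, 300 analyzed TRs, all
  stimulus amplitudes zero (arousal, confound leakage, drift and noise
  retained), 1000 phase randomizations and 500 bootstraps per ROI, 200
  replicate datasets. The fraction of ROI analyses with *any* synchronized
  TR must stay at or below $0.05 + 2\,\text{SE}$. The detection rule is
  conservative by construction (a CI bound compared against a max-null),
  so observed rates sit well below the nominal level.
* `recovery_experiment()` — planted-effect recovery at the design's effect
  sizes: 15 subjects per group, 600 analyzed TRs, 10 ROIs of 16 voxels
  with 3 drug-locked (also the "OFC" ISC set), 400 bootstrap/phase draws,
  2000 permutations. Scored against truth: sensitivity and specificity of
  the session-delta test at BH $q < 0.05$, and coverage of the planted
  ISC-delta/craving-delta correlation by the per-replicate Fisher-z 95%
  CI, over 50 replicates.

Problem sizes (ROI counts, voxel counts, resampling counts where the
reference values are not part of the claim) were fixed once while designing
the generator, as conditions under which the planted amplitudes are
detectable by this class of max-statistic test; they are deliberately
smaller than the full 450-ROI study so the experiments run on a laptop.

## Numerical choices and edge cases

* All resampling (bootstrap, phase surrogates, TR placement) draws from
  R's RNG — including inside the compiled kernels — so a single seed
  reproduces every result; bootstrap and phase null use separate seed
  substreams, so changing one count does not perturb the other stage.
* Random phases are generated by Marsaglia's polar method (exactly uniform,
  no trigonometric calls); surrogate transforms run through FFTW with one
  reused batched plan per cell.
* Percentile and quantile conventions follow R's type-7 default.
* Degenerate cases: a single-subject bootstrap, an all-zero SRM subject,
  $|r| = 1$ in the Fisher transform, empty TR sets, and constant series
  all fail fast with explicit messages or defined conventions (documented
  on each function).
* `fdr_bh()` requires p-values in $(0, 1]$; the behavioral correlation
  wrapper clamps numerically-zero p-values (perfect correlations in
  synthetic data) to the smallest positive double.

## Limitations

* The uniform permutation null ignores TR-set autocorrelation; with very
  sparse, strongly clustered synchronization the test can be mildly
  anticonservative for *baseline* contrasts. The session/group designs
  cancel most of this; a block-preserving null is a possible extension.
* Leave-one-out ISC saturates near 1 at high SNR, compressing subject
  differences; the ISC-behavior correlation is therefore attenuated
  relative to the planted latent correlation (coverage is maintained by
  the CI width at realistic group sizes).
* The single-component SRM assumes one dominant shared direction per ROI;
  regions with several concurrent shared processes would need $k > 1$,
  which is out of scope here.
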