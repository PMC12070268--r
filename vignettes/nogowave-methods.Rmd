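---
title: "Methods: simulating and analysing Go/Nogo oscillatory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Go/Nogo oscillatory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nogowave)
```

## The analysis problem

Go/Nogo tasks with feature overlap probe how perception–action bindings
("event files") interfere with response inhibition: when a Nogo stimulus
shares features with Go stimuli, withholding the response requires
reconfiguring the binding, which raises false-alarm rates and modulates
oscillatory EEG activity — midfrontal theta (4–7 Hz) increases, posterior
alpha (8–12 Hz) and beta (15–30 Hz) decrease. `nogowave` implements the full
analysis chain for such a study with two groups (patients with Gilles de la
Tourette syndrome, GTS, and neurotypical controls, NT) and two
feature-overlap conditions, together with a synthetic-data module so that
every stage is testable without access to raw recordings.

The chain is: behavioural statistics of the 2×2 mixed design; sensor-level
Morlet wavelet power with cluster-based permutation statistics; DICS
beamforming of band-limited source power with voxel-level cluster statistics
and DBSCAN peak localization; and a leave-one-out (jackknife) robustness
analysis whose per-iteration cluster statistics are compared between groups
with rank tests.

## Synthetic data: what it emulates and what it does not

`make_task_schedule()` reproduces the task structure exactly: 196 Go and 84
Nogo trials per overlap condition (70:30), seven equally sized blocks with
within-block shuffling, 450 ms stimuli, a 1700 ms response deadline, and
uniform 700–1100 ms inter-trial intervals.

`simulate_behavior()` draws per-subject hit rates, reaction times and
false-alarm rates from cell means and SDs. The default cells are the study
conditions: false alarms GTS 0.35 ± 0.13 / 0.02 ± 0.03 and NT 0.24 ± 0.08 /
0.01 ± 0.01 (overlapping / non-overlapping), hit rates 0.97 ± 0.04 vs.
0.98 ± 0.03, reaction times 498 ± 49 vs. 490 ± 46 ms. Rates are sampled from
Beta distributions matched to each cell by moments, because a normal draw
would violate the `[0, 1]` support at the near-floor false-alarm cells; a
clipped normal is used only where moment matching is infeasible
(`sd^2 >= m(1-m)`). A Gaussian copula with correlation 0.5 links a subject's
outcomes across conditions, giving realistic within-subject dependence
without changing the marginals.

`simulate_epochs()` generates trials × channels × samples arrays of 1/f
background noise (spectral exponent 1, 10 µV RMS per channel) plus
Gaussian-windowed sinusoidal bursts on seeded channels. Burst phase is
uniform per trial, so the planted power is non-phase-locked — it survives
trial-averaged total-power analysis, matching the wavelet pipeline, and
would vanish in an evoked average. Defaults mirror the study scale: 30
subjects per group, 84 trials per condition (the Nogo count), 61 channels,
256 Hz, −2..2 s epochs. The default effects are a midfrontal theta increase
under overlap (stronger in GTS) and broad alpha/beta decreases. A log-normal
per-subject amplitude multiplier (SD 0.2) supplies between-subject effect
variability.

What the generator does *not* emulate: eye blinks, muscle and cardiac
artifacts (the rejection stage is exercised with planted amplitude/flatline
violations instead), volume-conducted correlated background between
channels, realistic anatomy (the source model is a sphere), and clinical
scores beyond independent noise. Passing tests therefore demonstrate the
correctness and calibration of the *statistics* under the assumed generative
structure, not robustness to every artifact class of real recordings.

The toy source model (`make_source_model()`) places a regular grid (default
5 mm) inside a spherical head (default 60 mm scalp radius, sources within
52 mm: a few hundred voxels at 10 mm spacing, a few thousand at 5 mm), with
analytic homogeneous-medium dipole leadfields, average-referenced, plus a
small seeded electrode-gain perturbation. The atlas is geometric — octant ×
depth-shell parcels — with two reserved labels (`non-labelled` for the deep
centre, `cerebellum` for a posterior-inferior wedge) so the masking logic
can be exercised; real anatomical labelling is out of scope.

## Preprocessing

The chain is resample → filter → average reference → epoch → reject →
interpolate → baseline, each independently testable.

* **Resampling** (default to 256 Hz) is Fourier-domain: the spectrum is
  cropped at the new Nyquist bin and inverse transformed. We chose this over
  polyphase FIR resampling after measuring ~2% passband gain ripple in the
  latter; the Fourier method is flat to numerical precision for band-limited
  content and keeps `ceiling(n * p/q)` samples.
* **Filtering**: Butterworth band-pass 0.5–40 Hz with effective order 8 —
  designed at order 4 and applied forward–backward (zero phase) — plus a
  48–52 Hz band-stop notch (line-noise width is vendor-specific; ±2 Hz is a
  common choice). Signals are demeaned and mirror-padded before `filtfilt`,
  otherwise the 0.5 Hz edge leaves a transient of several µV mid-epoch on
  offset-heavy channels.
* **Artifact rejection**: an epoch is dropped when any channel exceeds
  ±200 µV, or is flat — peak-to-peak below 0.5 µV within a sliding window
  longer than 100 ms (window length `floor(0.1 * fs) + 2` samples, the
  smallest strictly exceeding 100 ms). "Activity" is read as peak-to-peak,
  the common interpretation. Per-channel violations reject the whole epoch;
  the log records trial, rule and offending channel. Manual inspection and
  ICA are deliberately not implemented; the log notes this.
* **Interpolation**: spherical-spline (stiffness 4, 20 Legendre terms) on
  the unit sphere, with a 1e-8 ridge on the spline system for numerical
  stability.
* **Baseline**: subtract the −200..0 ms mean per trial and channel
  (idempotent).

## Time–frequency analysis

`morlet_tfr()` uses complex Morlet wavelets of 7 cycles at every frequency
(3–30 Hz by 1 Hz by default) — seven cycles is the conventional default
where a study leaves the width implicit, and it is exposed as an argument.
Wavelets are L2-normalized (unit energy), so white noise yields a flat power
profile across frequencies and the power of an amplitude-`a` sinusoid scales
as `a^2`; data are zero-padded to the ceiling of the trial length in
seconds, fixing the spectral grid; wavelets are truncated at ±3σ and an
error is raised when the ±2σ core of the lowest-frequency wavelet does not
fit the padded window. Power is averaged over trials (total power), then
`band_average()` takes the arithmetic mean over band bins (theta 4–7, alpha
8–12, beta 15–30 Hz) and the analysis window. The sensor-statistics window
defaults to 0–1 s post-stimulus, matching the source-analysis window; raw
power (no log, no baseline normalization) enters the statistics, since
nothing else is specified for the original analysis.

## Cluster-based permutation inference

`permutation_test()` implements the standard Monte-Carlo cluster test over
an adjacency structure: elementwise t statistics (paired or two-sample), a
cluster-forming threshold defaulting to the two-sided critical t at α for
the design's df, connected components of suprathreshold same-sign nodes,
`T_sum` as the cluster statistic, and a null distribution of the maximal
(minimal) cluster statistic over label randomizations — sign flips within
subject for the dependent design, size-preserving group relabelings for the
independent design. Positive and negative clusters are each referenced to
their own tail and flagged at α/2 (the conservative two-tailed standard);
p-values are `(1 + #null ≥ obs) / (R + 1)`, so the smallest attainable p is
`1/(R+1)`.

Numerical choices: zero-variance paired differences produce a capped t of
±1e6 rather than ±Inf, making degenerate synthetic inputs deterministic; the
permutation schedule is drawn once per test from a single seed and shared
across nodes within each randomization.

The sensor-level min-neighbor rule (`min_neighbors = 2`: a node enters a
cluster only when at least two of its neighbours are suprathreshold with the
same sign) follows the usual semantics of that setting and suppresses
singleton clusters. It prunes observed and permuted maps alike, which makes
inference strictly more conservative — on 12-subject null studies it lowers
the family-wise rejection rate well below the nominal 0.05. The type-I-error
calibration suite therefore checks the base test (rule disabled) against the
exact binomial band around α, and separately asserts that the rule never
rejects more; the rule stays enabled for sensor analyses and disabled for
voxel grids (26-connectivity), as is conventional.

Sensor neighbourhoods use a distance threshold chosen automatically as the
smallest value at which the median electrode has ≥ 6 neighbours
(`sensor_adjacency()` records it as an attribute).

## DICS beamforming and peak localization

`csd_multitaper()` estimates band cross-spectral densities in the 0–1 s
window with single-Hanning tapering (1 Hz bins at the 1 s window), averaged
over trials and band bins, with Hermitian symmetry enforced exactly.
`dics_common_filter()` builds, per voxel, `W = (L' C^-1 L)^-1 L' C^-1` from
the real part of the *combined* conditions' CSD, regularized by
`λ · mean(diag(C)) · I` with λ = 5%. The "rank" parameter retains leadfield
orientations; the default 3 keeps all (standard for EEG) — we read the
original "rank reduction of 3%" as the rank-3 setting with a stray percent
sign, and both λ and rank are arguments. Orientations are reduced to a
scalar as the dominant eigenvalue of the projected source CSD
(dominant-orientation beamformer). Condition power maps come from the common
filter; `relative_contrast()` forms `(P_over − P_non)/(P_over + P_non)`,
bounded in [−1, 1], with 0/0 voxels flagged missing. Voxel-level statistics
run as dependent-sample t cluster permutation on the condition-wise power
maps, with the relative contrast used for localization and display — the
original text supports both readings, and both paths exist.

Peak localization follows the stated order — atlas masking first, then
thresholding: reserved labels are removed, the top 1% (by signed value in
the direction of the significant cluster; configurable) is kept with
`ceiling(q/100 · N)` voxels and ties broken by voxel index for determinism,
and DBSCAN clusters the surviving voxels in millimetre space with
`eps = 1.5 ×` grid spacing and `min_pts = 5` (the voxel itself counts).
DBSCAN is written in the package (no R implementation is among the
dependencies) with one canonicalization: border voxels reachable from two
clusters attach to their *nearest* core voxel (ties by index), making the
partition independent of voxel order; tests verify it against a brute-force
reachability oracle.

## Leave-one-out cluster robustness and group comparison

`loo_iterate()` repeats the voxel-level permutation test once per subject,
leaving that subject out, with the per-iteration seed fixed as
`seed + iteration`. Each record stores the `T_sum` and size of the largest
significant cluster of the expected sign — the original analysis reports one
cluster per band and group; summing over all significant clusters is
available via `collapse = "sum"` — plus `relative_T_sum = T_sum / n`.
`compare_groups()` runs a Mann–Whitney test on a chosen statistic with two
absence handlings: `missing` drops iterations without clusters, `zero`
penalizes them with zeros (so its usable n always equals the group size).

Effect sizes use `r = Z / sqrt(n)` with n the *per-group* size: the reported
values are consistent only with √30, not √60 (e.g. −4.78/√30 = −0.873), so
that convention is the default, with the denominator exposed as an argument.
Note the LOO iterations are overlapping jackknife samples, not independent
observations; the group comparison treats them as observations exactly as
the original procedure does, and no correction for their dependence is
attempted.

## Behavioural statistics

`mixed_anova_2x2()` is the classical split-plot (mixed) ANOVA via
`stats::aov` with a subject error stratum — the reported `F(1, 58)` df
structure identifies this, not a likelihood-based mixed model; in the
balanced design all sums-of-squares types coincide, and tests verify the F
values against a first-principles SS decomposition. Partial eta squared is
`F·df1/(F·df1 + df2)`. Post hocs are gated per group by Shapiro–Wilk at
0.05: Welch t (with Welch–Satterthwaite df and pooled-SD Cohen's d — the
printed d values are consistent with pooling at equal n) when all groups
pass, otherwise Wilcoxon signed-rank / Mann–Whitney with tie-corrected
normal-approximation Z, no continuity correction (matching the magnitude of
the reported Z values), and `r = Z/√n`. The approximation is intended for
n ≥ 5; at smaller n the tests fall back to the same formulas but the
enumeration-based checks tolerate the known coarseness.

`sensitivity_f()` solves the noncentral-F power equation for the
within-between interaction: `df1 = (g−1)(m−1)`, `df2 = (N−g)(m−1)ε`,
noncentrality `f² · N · m · ε / (1−ρ)`; with N = 60, α = 0.05, power 0.95,
ρ = 0.5 it returns f = 0.237. A Monte-Carlo test simulates the design at the
returned f (cell offsets ±f, subject SD √ρ, error SD √(1−ρ), which gives
exactly that noncentrality) and recovers the target power.

`loo_means()` puts behavioural and clinical variables on the jackknife
footing before `loo_spearman()` correlates them; significance is flagged at
the Bonferroni threshold 0.001 (a 48-comparison family at familywise 0.05).
The exact 48-pair list lives in supplementary material that is not part of
the main text; the package reproduces the structure (overlap effects,
per-band LOO statistics, clinical scores) rather than a verbatim list.

## Problem sizes used by the test suite

Unit tests run at a desk scale: 12 subjects per group, 32 channels, 10 mm
grids, and 12–40 trials per condition. The type-I-error suite (200 replicate
studies × 500 randomizations) additionally samples at 64 Hz with −1..1 s
epochs and 12 trials: the null-calibration property is invariant to trial
count, sampling rate and epoch length (the theta band lies far below either
Nyquist frequency), so the smallest faithful configuration is used. The
detection-power suite plants the midfrontal theta effect at burst amplitudes
7 vs. 2.5 µV, which at that scale yields a per-subject band-power effect of
d ≈ 1.5 at the seeded channels, and requires a significant positive cluster
covering a seeded channel in ≥ 90% of 50 studies. Source recovery demands
20/20 dipole localizations within one grid step at a sensor SNR of 5.

## Known limitations

* The spherical head, homogeneous-medium leadfields and geometric atlas are
  stand-ins: absolute source amplitudes and parcel names carry no anatomical
  meaning.
* ICA-based and manual artifact handling are not implemented; only the two
  automatic criteria are.
* The LOO group comparison inherits the original procedure's treatment of
  dependent jackknife iterations as independent observations.
* Wavelet power is reported without baseline normalization; comparisons
  across frequencies inherit the 1/f background slope.
* BrainVision support covers multiplexed binary float32/int16 continuous
  files with basic marker parsing — enough to feed real recordings into the
  chain, not a complete vendor-format implementation.
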