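---
title: "Models and methods behind corticostate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corticostate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`corticostate` analyzes simultaneous wide-field optical mapping (WFOM) of
neuronal calcium activity and cortical hemodynamics in behaving mice. This
vignette is the package's account of its models: what is assumed, which
parameters matter, how the synthetic session generator works, and where the
numerically delicate choices lie.

## The optical model

Three channels are acquired in interleaved frames at 20 Hz each: lime-excited
fluorescence of a red-shifted calcium indicator, and green (~530 nm) and red
(~625 nm) diffuse reflectance. Two physical facts drive the spectroscopy
module:

1. **Reflectance attenuation is log-linear in hemoglobin concentration.**
   After division by a resting baseline image, the normalized reflectance at
   wavelength $\lambda$ is
   $I_R^{norm}(t,\lambda) = e^{-\Delta\mu_a(t,\lambda) X_R(\lambda)}$ with
   $\Delta\mu_a = \varepsilon_{HbO}(\lambda)\,\Delta[HbO] +
   \varepsilon_{HbR}(\lambda)\,\Delta[HbR]$. With two wavelengths this is a
   2×2 linear system per pixel and frame; `convert_hemoglobin()` solves it
   directly (the extinction/pathlength matrix is validated as nonsingular at
   construction). $\Delta[HbT]$ is defined as the sum of the two species.

2. **Raw fluorescence is attenuated on the way in and on the way out.** The
   excitation light experiences (approximately) the green-reflectance
   absorption and the emitted light the red-reflectance absorption, each over
   a different pathlength. Dividing the normalized fluorescence by
   $I_R^{norm}(\lambda_{red})^{P_r} I_R^{norm}(\lambda_{green})^{P_g}$
   removes both attenuations, where $P_g = X_{ex}/X_R(\lambda_{green})$ and
   $P_r = X_{em}/X_R(\lambda_{red})$ are pathlength ratios. The correction
   is exact when the rendered forward model holds; on real tissue it is an
   approximation that degrades near the midline where motion is strongest.

The extinction coefficients and reflectance pathlengths shipped by
`default_optics()` are compilation-style values (Prahl-type tabulated
hemoglobin spectra at 530/625 nm, converted to 1/(µM·mm); pathlengths on the
Monte-Carlo scale for mouse cortex). They are configuration with override
hooks (`optical_model()`, `read_optics_yaml()`) — the algorithms, not these
constants, are the substance, and none of them is asserted as a measured
property of a specific preparation.

`estimate_pathlength_ratios()` treats $P_g, P_r$ as free parameters and
grid-searches them (defaults spanning [0, 0.6] × [0.5, 2.5], bracketing the
plausible 0.2–0.3 and 1.1–1.8 ranges) to minimize the mean absolute
correlation between corrected fluorescence and $\Delta[HbT]$ across pixels.
This decorrelation objective is a quantitative surrogate for the qualitative
criterion of vessel-like artifacts disappearing from corrected images: when
the correction is right, no hemodynamic structure should remain.

## Temporal filtering

Pipeline defaults: neural signals are low-passed at 6.5 Hz (heart-rate band
removal), hemoglobin signals additionally at 0.25 Hz (respiratory vascular
artifacts in the 1–4 Hz range), both with a Chebyshev type-I characteristic
of order 20 and 0.2 dB passband ripple, applied with zero phase. "Pass-band
ripple" pins the family to Chebyshev-I; the ripple unit is taken as dB (the
convention).

A deliberate numerical choice: the filter is applied **in the frequency
domain** as the analytic squared Chebyshev-I magnitude
$|H(f)|^2 = 1/(1+\epsilon^2 T_n^2(f/f_c))$, not as a time-domain
forward–backward (filtfilt) recursion. An order-20 Chebyshev-I with a cutoff
at 0.025 of Nyquist is numerically unstable as a double-precision transfer
function — its rounded denominator polynomial has roots outside the unit
circle and filtfilt returns NaN. The squared analytic magnitude with zero
phase is exactly what forward–backward application computes in the ideal
case, is stable at any order, and is evaluated with the cos/cosh closed form
of $T_n$. Signals are extended by odd reflection on both ends (the same idea
as filtfilt's initial-condition padding) to suppress edge transients. The
response is normalized to unit gain at the in-band reference (DC for
lowpass), so constants pass through unchanged and the passband ripples in
$[1, 1+\epsilon^2]$; bandpass is realized as a highpass–lowpass cascade.

Global cardiac pulsation is removed separately (`remove_global_pulsation()`)
by dividing each frame by one plus the high-pass-filtered fractional
fluctuation of the global mean (cutoffs: >1 Hz hemodynamic, >2 Hz neural).
PCA denoising (`pca_denoise()`) is a truncated SVD of the mean-centered
pixel×time matrix; the full-scale component counts (200 reflectance, 300
fluorescence) are elbow choices that scale down with data size — tests use
counts of order 20–30 on 60×60 synthetic stacks.

## Parcellation

`cluster_hemisphere()` is k-means under the correlation distance
$1 - r(x, c)$: rows are standardized, assignment maximizes Pearson
correlation with centroids, centroids are means of member rows, and the best
of `replicates` random restarts by total within-cluster distance is kept.
Empty clusters are repaired by reseeding with the worst-fit pixel. No
installed clustering routine offers this metric, so the Lloyd loop is
implemented here and tested against planted block structure (exact recovery,
permutation invariance).

Clustering is run on rest-segment frames: resting dynamics carry the finest
spatial detail, whereas locomotion coalesces strongly co-active sensorimotor
territories. The left-hemisphere map is reflected across the midline, the
mirrored ROIs initialize a single k-means run on the right-hemisphere data,
and bilateral pairs are the solution of the linear assignment problem on the
left×right centroid-correlation matrix (Hungarian method, implemented here;
exact ties are broken by the spatial overlap of mirrored masks, folded in as
an infinitesimal secondary cost). ROIs are ordered pairs-first: left 1..k,
right k+1..2k with `pairs[i,] = (i, k+i)`.

Candidate cluster counts are compared by `evaluate_cluster_count()`: every
pixel trace is regressed (NNLS) on the centroid time courses and the
residual and explained signal energy are reported next to the PCA (optimal
rank-N) curve. Both explained-energy figures use the uncentered total, which
makes "PCA ≥ NNLS at matched N" an exact theorem rather than an
approximation. `consensus_mode_map()` canonically relabels repeated maps
onto the first by assignment on overlap counts and takes the per-pixel
mode, ties resolved toward the map with the best quality score.

## Windowed correlation and the state decomposition

`windowed_correlation()` computes full pairwise Pearson matrices over 10-s
windows (200 samples at 20 Hz). The window step is not dictated by the
measurement; the default is 1 frame so the downstream coefficient time
courses are effectively continuous, and each map is indexed by its central
frame (a window convention chosen here and used consistently). For
hemodynamic signals a first-degree polynomial is removed per ROI within each
window (projection onto an orthonormal [intercept, slope] basis) — slow
drifts otherwise dominate 10-s correlations. An ROI with zero variance in a
window would make Pearson undefined; such entries are set to 0, flagged in a
mask, and warned about once.

The five behavioral correlation states are defined from wheel-encoder bouts
(`detect_bouts()`: supra-threshold runs, threshold defaulting to 5% of the
session's 99th-percentile speed, gaps under 1 s absorbed):

* **onset** — window spanning 5 s rest + 5 s locomotion; bouts ≥ 10 s with
  ≥ 60 s pre-rest;
* **locomotion** — the central 10 s of bouts ≥ 20 s;
* **offset** — 5 s locomotion + 5 s rest; bouts ≥ 20 s with ≥ 10 s
  post-rest;
* **initial rest** — the 10 s immediately after cessation; bouts ≥ 5 s with
  ≥ 60 s post-rest;
* **sustained rest** — the 10 s starting 40 s after cessation, same bouts
  (40 s being the time pupil size takes to return to baseline after
  running stops).

All intervals are half-open in frames, transition windows anchored at
[event−5 s, event+5 s). A bout may contribute to several states; offset and
initial-rest windows overlap by construction (they share the 5 s after
cessation).

`fit_states_nnls()` solves
$d = \sum_n x_n c_n,\; c \ge 0$ per window on the vectorized **strict upper
triangles** — the diagonal is identically 1 and would act as a spurious
intercept shared by all basis maps. The solver is an active-set
(Lawson–Hanson) NNLS working from the normal equations, so repeated solves
against one basis reuse the cross-products; tests verify it against an
independent projected-gradient solver. The residual is
$\|(d - cx)^2\|_1 / \|d^2\|_1$, defined as 1 for an all-zero map.
Cross-validation partitions **bouts** (not windows) into folds, so a window
is never fit against a basis its own bout helped define; windows overlapping
no basis window use the full basis, and if a fold would leave a state with
zero windows the full-data map for that state is substituted with a warning.
The fit is returned as a classed object with `coef`, `predict`, `fitted`,
`residuals`, `summary` and `plot` methods.

For the arousal analyses, rest epochs are sub-threshold runs of at least
60 s. Reciprocity is the per-epoch Pearson correlation between the
initial-rest and sustained-rest coefficients; pupil association correlates
each rest coefficient with pupil diameter per epoch, summarizes the two
distributions by Epanechnikov kernel densities and compares them with a
two-sample Kolmogorov–Smirnov test.

## Statistics

`ranksum_map_compare()` runs a two-sided Wilcoxon rank-sum test per unique
upper-triangle entry, with the Bonferroni family equal to the number of
entries tested (4186 for 92 ROIs) — the family is per-matrix, a choice made
here. Exact p-values (Wilcoxon distribution) are used when both groups have
n ≤ 10 without ties; otherwise the normal approximation with tie correction.
The z sign convention is fixed: z > 0 where the second group exceeds the
first. The display z-map zeroes insignificant entries; the raw map is kept.
The Epanechnikov KDE bandwidth defaults to Silverman's reference rule
rescaled by the kernel's canonical bandwidth ratio (×2.214 relative to the
Gaussian rule); the kernel is stated by the analysis convention, the
bandwidth is not, so the reference rule is used. Fisher-z comparisons are
`atanh` + one-way ANOVA + pairwise Welch t-tests.

## The synthetic session generator

`simulate_session()` produces behavior, ground-truth cortical dynamics, and
raw optical channels that are *exactly* consistent with the forward model
the pipeline inverts. What it emulates:

* **Behavior** — locomotion bouts (default 0.5/min, 10–40 s, smoothed edges
  and speed jitter); an arousal level that saturates during running, decays
  exponentially after offset with time constant `pupil_decay_tau_s`
  (default 15 s, returning pupil to baseline ≈ 40 s after offset), and
  wanders slowly between high and low levels during prolonged rest (gated
  in 55–70 s after offset so the stereotyped initial→sustained transition
  stays clean); pupil diameter tracking arousal; whisking elevated around
  bouts.
* **Cortex** — rectangular parcel tiles per hemisphere with a 2-pixel
  midline gap (bilateral mirroring is exact by construction; real anatomy
  is not needed to test the algorithms). Each bilateral pair shares a
  band-limited latent (Ornstein–Uhlenbeck, τ = 0.2 s, FFT-band-passed to
  0.1–6 Hz) mixed to the target bilateral correlation. The frontal third of
  tile rows is "anterior": high-gain resting fluctuations
  (`rest_gain_anterior`, default 2.5 — a free parameter; the anterior/
  posterior amplitude ratio is not a quantity the emulated system pins
  down) suppressed to `locomotion_suppression` (0.3) during bouts,
  amplitude and long-range coupling modulated by arousal so initial and
  sustained rest express distinct correlation states, plus an anterior
  network component specific to low-arousal rest and per-side
  desynchronization during locomotion. Sensory tiles carry
  locomotion-locked activation plus a shared gait-band fluctuation;
  stereotyped mixed-sign co-activation patterns mark the 4 s before onset
  and before offset. These structural choices were made to give each of the
  five states a distinct, non-collinear correlation signature — without
  them the basis maps degenerate pairwise (offset≈initial rest, or
  locomotion≈initial rest) and no decomposition method could tell them
  apart.
* **Hemodynamics** — gamma-kernel HRF (shape 2.5, scale 0.35 s — "gamma
  shaped" is the constraint, these values are the package's choice)
  convolved with the parcel drive, delayed by `hrf_lag_s` (1.5 s), scaled
  to µM; HbO/HbR split anti-correlated with HbT ≡ HbO + HbR identically.
  Cardiac (9 Hz) and respiratory (2.5 Hz) oscillations are injected as
  small spatially uniform hemoglobin components — pulsation physically *is*
  hemodynamic, and this keeps the optical forward→inverse round trip exact.
* **Optics** — the Beer-Lambert forward model with a smooth illumination
  gradient; the first 5 s are a clamped baseline (zero hemodynamics,
  F/F_base = 1, ramping in over 2 s) so baseline normalization is exact.
  Channel measurement noise defaults to zero: photon-noise modeling is out
  of scope, and the exact-inversion contract is part of the design.

What it does **not** emulate: vascular anatomy, photon statistics, eye
blinks, motion artifacts, cross-animal registration, or the real geometry of
cortical areas. Passing tests therefore demonstrate that the *measurement
chain* — conversion, correction, parcellation, windowed correlation, state
decomposition, statistics — recovers planted structure faithfully; they do
not certify performance on artifact-laden real recordings.

## Problem sizes and numerical conventions

Test and acceptance runs use scaled problem sizes chosen for desk hardware:
60×60 images for structural checks (full 46-per-hemisphere parcellation on a
2-minute session; exact-inversion checks on 3600 pixels × 2400 frames),
20×22 images with 8 parcels per hemisphere for the 10-minute state-recovery
sessions, and epoch pooling across four sessions for the arousal analyses
(matching the multi-animal pooling such analyses require — a single 10-min
session contains only ~5 long rest epochs).

Conventions worth knowing when extending the package: bouts and windows are
1-based half-open frame intervals; windowed maps are indexed by central
frame; basis windows snap to the nearest covered series window (exact at the
default step of 1); NNLS and map distances exclude the diagonal; the
Euclidean map distance is the Frobenius norm over the upper triangle;
k-means ties in assignment go to the first centroid; all generators and
estimators are deterministic under their seed arguments.

## Known limitations

The fluorescence correction assumes reflectance pathlengths proxy the
excitation/emission pathlengths up to the constant ratios $P_g, P_r$; this
breaks down where absorption changes are extreme or motion is large. The
rank-sum map comparison treats windows as exchangeable samples, ignoring
their temporal autocorrelation — with a 1-frame step adjacent maps share
199/200 of their data, so group sizes should count epochs or bouts, not
windows. The state basis is a 5-state linear model by design; shorter-lived
transients (1–2 s) and non-locomotor behaviors (grooming, startle) are
outside its vocabulary.
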