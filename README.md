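# corticostate

Behavioral correlation states from wide-field optical mapping (WFOM) of the
mouse dorsal cortex.

Awake, head-fixed mice on a running wheel alternate between locomotion and
quiet rest, and the interregional correlation structure of cortex-wide
neuronal activity reorganizes with those behavioral states — including a
switch between two distinct *resting* states tracking arousal (indexed by
pupil diameter). `corticostate` implements the full analysis chain needed to
quantify this from raw dual-modality imaging: lime-excited red-shifted
calcium-indicator fluorescence (neuronal) plus green and red reflectance
(hemodynamic), each sampled at 20 frames/s, with synchronized wheel, pupil
and whisker behavioral measurements. A ground-truthed synthetic session
generator emulates all of this so every stage is testable without acquired
data.

## What it computes

**Spectroscopy.** Reflectance is converted to oxy-/deoxy-hemoglobin
concentration changes by the modified Beer-Lambert law: per pixel and frame,
`-ln I_R^norm(λ) = (ε_HbO(λ) Δ[HbO] + ε_HbR(λ) Δ[HbR]) X_R(λ)` is solved
across the green and red wavelengths, with `Δ[HbT] = Δ[HbO] + Δ[HbR]`. Raw
fluorescence is corrected for time-varying hemoglobin absorption on both the
excitation and emission paths:

    F(t)/F(base) = I_em^norm(t) / ( I_R^norm(t, λ_red)^Pr · I_R^norm(t, λ_green)^Pg )

where `Pg`, `Pr` are the excitation/emission-to-reflectance pathlength
ratios (estimable from data via `estimate_pathlength_ratios()`; plausible
ranges 0.2–0.3 and 1.1–1.8).

**Parcellation.** Correlation-distance k-means (46 clusters per hemisphere at
full scale, best of many restarts) on rest-period pixel dynamics; the left
map is mirrored onto the right hemisphere to initialize clustering there,
and bilateral ROI pairs are established by solving the assignment problem on
centroid correlations — yielding 92 paired ROIs. Candidate cluster counts are
compared by per-pixel NNLS reconstruction `M(x,y,t) = Σ_n W(x,y)_n H(t)_n`
against the PCA optimum, and repeated maps are combined by a per-pixel mode
after canonical relabeling.

**Dynamics and states.** Pairwise Pearson maps over a moving 10-s window
(200 samples) give a `92 × 92 × time` correlation-map series. Five behavioral
correlation states — locomotion onset, sustained locomotion, locomotion
offset, initial rest, sustained rest — are defined from wheel-encoder bouts,
averaged into a basis `x(r,r)_{1:5}`, and every real-time map `d(r,r,t)` is
decomposed by non-negative least squares,

    d(r,r,t) = Σ_{n=1..5} x(r,r)_n c(t)_n ,

with goodness of fit `‖(d − cx)²‖₁ / ‖d²‖₁` and 5-fold cross-validation over
bouts. Downstream analyses quantify the reciprocity of the two rest states,
their signed association with pupil diameter (Epanechnikov KDE +
Kolmogorov-Smirnov), windowed SD around locomotion, Welch spectra, and
band-resolved correlation maps, with Wilcoxon rank-sum map comparisons under
Bonferroni correction.

## Worked example

Simulate a 10-minute session, extract ROI time courses, and decompose the
moving-window correlation maps into the five behavioral states:

```r
library(corticostate)

cfg <- sim_config(duration_s = 600, image_shape = c(20, 22), seed = 1)
ses <- simulate_session(cfg)

# ROI time courses from the parcellation, low-passed at 6.5 Hz
parc <- parcellation_map(ses$truth$parcel_labels, ses$truth$bilateral_pairs)
roi  <- extract_roi_timecourses(ses$truth$true_F, parc, cfg$frame_rate)
roi  <- roi_matrix(zero_phase_filter(roi$values, filter_spec("lowpass", 6.5),
                                     cfg$frame_rate),
                   cfg$frame_rate, "neural_dff")

# moving-window correlation maps and the five-state NNLS decomposition
cs    <- windowed_correlation(roi, window_s = 10)
bouts <- detect_bouts(ses$behavior$wheel_velocity, cfg$frame_rate)
wins  <- extract_state_windows(bouts, cfg$frame_rate, ncol(roi$values))
fit   <- fit_states_nnls(cs, windows = wins, cv_folds = 5, seed = 1)
summary(fit)
```

```
State fit over 11801 windows (4-fold CV)
          state   mean    sd argmax_share
          onset 0.0958 0.221       0.0736
     locomotion 0.2398 0.255       0.1695
         offset 0.0938 0.236       0.0708
   initial_rest 0.3026 0.330       0.3214
 sustained_rest 0.2769 0.273       0.3648
Residual quantiles:
    5%    25%    50%    75%    95% 
0.0716 0.1160 0.1580 0.2220 0.3030 
```

Each column of `coef(fit)` gives the nonnegative contribution of the five
state maps to one 10-s window; `argmax_share` shows how often each state
dominates (this session spends most of its time at rest, split between the
two resting states), and the residual is the fraction of map energy the
five-state model leaves unexplained. The two resting states trade off
against each other within every long rest epoch:

```r
epochs <- detect_rest_epochs(ses$behavior$wheel_velocity, cfg$frame_rate)
round(rest_reciprocity(fit, epochs), 2)
#> [1] -0.76 -0.53 -0.74 -0.76 -0.81
```

a strongly negative per-epoch correlation between the initial-rest and
sustained-rest coefficients (mean −0.72 here), the signature of slow
arousal switching during prolonged quiescence.

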