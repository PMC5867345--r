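---
title: "Rhythm-resolved EEG features for cross-subject emotion recognition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm-resolved EEG features: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis in one paragraph

`emorhythm` implements a feature-engineering pipeline for recognizing binary
emotional valence (negative vs positive) from multi-channel EEG across
subjects. Each trial is decomposed into the four classical rhythms — theta
(4–7 Hz), alpha (8–15 Hz), beta (16–31 Hz) and gamma (>32 Hz; the delta band
is excluded as sleep-related) — normalized per subject and channel, cut into
4-s sliding windows with 2-s overlap, and described by 18 features per
channel and rhythm: nine time–frequency descriptors and nine nonlinear
dynamical-system descriptors. The trial's feature is the mean over its
windows, giving `18 × n_channels × 4` columns (2304 for a 32-channel
montage, 4464 for 62 channels). Five selection strategies (χ², mutual
information, ANOVA F, SVM-RFE, L1-penalized linear SVM) rank the columns on
training data, and a linear SVM is evaluated subject-wise by
leave-one-subject-out (LOSO) cross-validation, with searchlight reports per
channel, scalp region, rhythm and feature type. A complementary
connectivity analysis correlates window-level feature values between
channels per subject and emotion group, binarizes the matrices over a
threshold grid and compares clustering coefficients between groups.

# Preprocessing

**Rhythm filters.** Linear-phase FIR bandpass filters, Hanning-windowed,
order `2·fs` taps (≈1.5 Hz transition band). The filter is applied by FFT
convolution with exact group-delay compensation: a symmetric FIR delayed by
`order/2` samples has identically zero phase, so window-level features stay
aligned in time across bands while the applied magnitude response equals
the designed one (forward–backward filtering would square it). The first
and last `order/2` samples carry edge transients and are trimmed before
windowing. The open-ended gamma band is closed at `min(45, 0.45·fs)` Hz:
45 Hz stays clear of the 50 Hz mains notch, and the Nyquist cap keeps the
design valid for 128 Hz recordings.

**Normalization.** Each channel is z-scored with its mean and standard
deviation pooled across all of a subject's trials — after rhythm
extraction, independently per rhythm stream. This removes per-subject gain
and offset idiosyncrasies (the main obstacle to cross-subject
generalization) while preserving relative channel variability. Subjects
are processed strictly independently, and the transform is idempotent.

**Windows.** Stride = window length − overlap; a 60-s trial yields
(60−4)/2+1 = 29 windows. Ratings exactly at the valence pivot (5 on the
1–9 scale) satisfy neither of the two strict inequalities that define the
classes and are excluded rather than assigned.

# The 18 features

Features 1–9 (time–frequency): peak-to-peak mean, mean square, variance,
Hjorth activity/mobility/complexity, maximum-PSD frequency, maximum PSD,
and power sum. Conventions: population variance (÷n) throughout, so the
Hjorth ratios are denominator-free; first differences are per-sample (not
scaled by fs), so mobility/complexity are in per-sample units — only
relative comparisons matter downstream. The spectral estimator is the
unwindowed one-sided periodogram per 4-s segment (the window mean already
smooths); densities are per FFT bin and scaled so that their sum equals
the window's mean square exactly (Parseval), making `power_sum` the
band-limited power.

Features 10–18 (nonlinear): approximate entropy, C0 complexity,
correlation dimension, Kolmogorov (K2) entropy, largest Lyapunov exponent,
permutation entropy, singular-spectrum (SVD) entropy, Shannon entropy and
spectral entropy. No embedding or tolerance parameters are canonical in
the affective-EEG literature, so defaults follow the conventional
time-series choices and are all exposed via `feature_params()`:

| parameter | default | note |
|---|---|---|
| ApEn `m`, `r` | 2, 0.2·sd | tolerance as a fraction of the window sd ⇒ scale-invariant |
| PE order, delay | 3, 1 | normalized by log 3! ⇒ value in [0,1] |
| SVD entropy `m` | 20 | trajectory dimension; entropy normalized by log m |
| corr. dimension | m scanned 2–8 | delay = ACF 1/e decay; Theiler window = dominant period |
| K2 entropy `m` | 2 | same radius grid; rate in nats/sample |
| Lyapunov `m` | 5 | Rosenstein; slope in nats/sample |
| Shannon bins | 16 | equal width over [min, max]; natural log |
| C0 threshold | 3× mean spectral power | see below |

**Numerical choices worth knowing.**

* *Correlation dimension / K2.* Correlation sums use Chebyshev distances
  over a 32-point log-spaced radius grid spanning range/1000 to the data
  range, with a Theiler window equal to the dominant signal period so
  temporally adjacent (same-phase) pairs never masquerade as recurrences.
  The slope is fitted where `C(ε)` lies in [0.001, 0.05]; the embedding
  dimension is the first whose slope gain over its predecessor drops below
  0.15 ("slope saturation"). For i.i.d. noise the slope keeps growing and
  the largest m is reported with `saturated = FALSE`. On the package's
  fixtures this recovers dimension ≈1 for a sine orbit and ≈1.9–2.0 for
  Lorenz-x (literature value 2.05).
* *Lyapunov exponent.* Rosenstein divergence curves with Euclidean
  neighbour search and a resolution floor of `1e-10·sd`: distances below
  the floor are clamped, so an exactly periodic signal (whose
  nearest-neighbour distances are pure rounding noise) produces a flat
  curve and a ≈0 slope instead of a fit to numerical garbage. The slope is
  fitted over the initial span of the curve up to 0.5 nat below its
  plateau. The r=4 logistic map yields ln 2 within a few percent.
* *C0 complexity.* The "regular" part keeps Fourier coefficients whose
  squared magnitude exceeds 3× the mean; C0 is the residual power
  fraction. The factor 3 (within the conventional parameter range of this
  statistic) is deliberate: at threshold 1× the expected C0 of white noise
  is analytically 1−2/e ≈ 0.26, which would not separate noise from
  structured signals; at 3× a pure tone scores <0.05 and white noise >0.5.
* *Estimator failures.* Dimension/Lyapunov-type estimators are
  low-confidence on 4-s windows (512–800 samples) and may return flagged
  undefined values; estimator *correctness* is validated on long fixtures,
  and undefined window values are imputed with the training-set column
  median (count recorded in `na_mask`). Windowed short-data estimates are
  still usable as relative class discriminators, which is all the
  classifier needs.
* A known property caveat: the amplitude-histogram Shannon entropy does
  **not** order sine below Gaussian noise — the arcsine amplitude law of a
  tone is closer to uniform over its support than a Gaussian is over its
  range. The other entropies do satisfy the constant ≤ sine ≤ noise
  ordering.

# Feature selection

Filter criteria discretize continuous features into 5 quantile bins fitted
on training data (the binning is a documented convention; nothing in the
method fixes it): χ² is the Pearson statistic of the bin × class table, MI
the plug-in estimate in bits, F the one-way ANOVA ratio of between- to
within-class variance. SVM-RFE eliminates the `k` smallest-|w| features
per step over `S = (p−q)/k` steps, ties broken by column index. The L1
selector minimizes `‖w‖₁ + C·Σ max(0, 1−y(w·x+b))²` by FISTA; squared
hinge keeps the smooth part differentiable, and the C convention (C
weights the loss) matches the behaviour of the standard linear-SVM
implementations: the selected set is empty as C→0⁺ and grows with C. The
sweep grids mirror the study design: selection size stepped by 10 for
filters/RFE, C on 0.01–1 in steps of 0.01 for L1.

# LOSO evaluation

One fold per subject; min-max feature scaling, imputation, selection and
the linear SVM (cost 1, no class weighting) are fitted on the remaining
subjects only. Scaling fitted per training fold is the leakage-safe
reading of "features were normalized"; the alternative (global scaling)
would let held-out subjects influence the fit. ROC/AUC are computed from
the decision values of all held-out trials pooled across folds — a single
curve per method, matching how one ROC per selection strategy is usually
reported; per-fold averaging is the documented alternative. Folds whose
held-out subject lacks one class are flagged and excluded from the mean
accuracy. Where a subject has multiple sessions, all of them leave
together (folds are defined by subject identity).

Searchlight slices re-run the same harness on manually chosen column
subsets: per channel; per scalp region; per rhythm (four bands plus their
concatenation); per (feature, rhythm) pair (72 slices with all 18
features); per category (linear vs nonlinear). Region partition: hemisphere
from the terminal digit of the 10-20 label (odd = left, even = right, z =
midline), anterior vs posterior from the letter prefix with the central
row (`C*`, `T7/T8`) in between; quadrant selectors drop midline and
central-row electrodes, hemisphere selectors drop the midline, and
anterior/posterior selectors drop the central row — the "cross" channels
are eliminated from sub-region sets. The exact partition used in the
original study is not tabulated anywhere, so this montage convention is a
documented choice, not a reproduction.

# Connectivity analysis

For one (feature, rhythm) and each subject and emotion group, every
channel contributes its sequence of window-level feature values pooled
over the group's trials; the channels × channels Pearson matrix of those
sequences is the connectivity estimate. Windows, not trials, are the
observation unit: trial-level values would give only a handful of points
per group against thousands of matrix entries. Matrices are averaged per
group without Fisher transformation (both the unit and the averaging are
documented conventions — the source procedure states neither). Signed
correlations are compared against the threshold (strictly greater), so
negative correlations never create edges; the diagonal is forced to zero.
Clustering coefficients are `2·triangles/(k(k−1))` per node (0 for degree
< 2, computed via igraph's local transitivity and cross-checked against
exhaustive triangle counting), and the threshold scan reports, for each
threshold in 0.01–0.99 (step 0.01), a paired t-test of the per-subject
global clustering coefficients between groups, plus the maximal contiguous
ranges with p < 0.05 in the `lo~hi` format of the original tables.

# The synthetic generator

Real affective-EEG corpora are access-controlled, so the package ships a
generator that emulates the *structure* the analysis relies on, with
defaults fixed at the study conditions: 200 Hz sampling, 60-s trials, a
62-channel 10-10 montage (a 32-channel/128 Hz preset mirrors the
music-video protocol), and balanced negative/positive trials per subject.
Per rhythm, each channel mixes one global, one region-local and one
idiosyncratic amplitude-modulated narrowband source; the loadings set the
expected inter-channel correlation to `base_corr` (0.3) for positive
trials plus `class_corr_gap` (0.15) for negative ones — encoding the
empirical finding that negative-emotion recordings are more strongly
inter-correlated — with `local_corr` (0.05) extra within a scalp quadrant.
The class effect on the signal content is confined to the beta band:
positive-class trials multiply the beta carrier frequency (centre 20 Hz)
and amplitude by `class_beta_shift` (default 1.25, which yields a
beta-band mobility separation comfortably above 1.5 pooled sd). Subjects
carry log-normal gains (`subject_scale_sd = 0.2`) and per-channel DC
offsets, exactly the idiosyncrasies the per-subject normalization must
remove; broadband Gaussian noise (`noise_sd = 0.3`) completes the signal.
Fixed seeds give bit-identical datasets.

What the generator does *not* emulate: volume-conducted forward-model
topographies, artifacts (EOG/EMG), non-stationary arousal dynamics, 1/f
background structure, or label noise in the ratings. Passing the planted
recovery tests therefore shows the pipeline recovers the statistical
structure it targets — not that any particular accuracy level would be
reached on real recordings, whose headline numbers depend on the
access-controlled datasets themselves.

# Problem sizes in the test-suite and validation runs

The suite exercises the full pipeline at reduced scale, chosen as the
smallest sizes at which every planted effect is still comfortably
detectable: 4–8 channels, 8–12 s trials at 128 Hz, 3–6 subjects for LOSO
properties (15 subjects for the connectivity power checks, matching the
subject count of the film-clip study), linear features for the
LOSO-recovery loops, and long single-channel fixtures (n = 2000–100 000)
for estimator validation. Dimensionality checks run the full 18 × 32 × 4
and 18 × 62 × 4 assemblies on short trials. All stochastic checks fix
their seeds.

# Known limitations

* Nonlinear estimates on 4-s windows are biased and variance-heavy; they
  are treated as features, not as physical dimension/entropy measurements.
* The exact numeric feature values of the original study are not
  reproducible even in principle: its nonlinear parameters are unstated,
  and its datasets are access-controlled. The package reproduces the
  *procedure* and its self-contained quantities.
* EDF ingestion is not provided; trials are read from CSV + TSV metadata
  (`read_trials()`/`write_trials()`).
* The L1 objective uses squared hinge; with the plain hinge the selected
  sets can differ slightly near the sparsity threshold.
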