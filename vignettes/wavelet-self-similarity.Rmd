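---
title: "Wavelet self-similarity features for physiological time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet self-similarity features for physiological time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pupilwave` treats a physiological recording — its motivating case is
pupil diameter sampled at 1 kHz during a cognitive task — as a realization
of a self-similar process. Self-similarity means the signal's statistical
character is invariant under rescaling; its strength is summarized by the
Hurst exponent `H ∈ (0, 1)`. Standard Brownian motion has `H = 0.5`;
`H > 0.5` indicates persistent, long-memory dynamics, and lower `H` means
more erratic, less regular behaviour.

The working assumption is that of wavelet-domain scaling analysis: after an
orthonormal discrete wavelet transform, the detail coefficients `d_{j,k}`
of an `H`-self-similar signal have level energies that decay geometrically,

    E[energy(d_j)] ∝ 2^{-j(2H + 1)},

with `j` indexing levels so that level `j` holds `2^j` coefficients (fine
levels are long). The wavelet spectrum `S(j) = log2(energy(d_j))` is then
linear in `j` and an ordinary least-squares fit gives the slope, hence
`H = -(slope + 1)/2`. Every `slope_fit` object in the package satisfies
this identity by construction.

The package's distinctive component is the *energy estimator*. The
classical choice is the level's sample variance. Its replacement here is
the squared sample distance variance

    nu²_n(x) = (1/n²) Σ_{i,j} A_{ij}²,   a_{ij} = |x_i − x_j|,

with `A` the double-centered `a` matrix. Two properties make it a drop-in
replacement: translation invariance and `a²`-scale equivariance, which
together mean swapping variance for distance variance shifts the spectrum
by a constant intercept but leaves the slope — and therefore `H` —
unchanged in expectation. Unlike the variance, it responds sublinearly to
a minority of wildly perturbed coefficients, which is exactly the failure
mode blink spikes and recording glitches induce.

We use the *squared* Székely–Rizzo statistic with the biased `1/n²`
normalization (matching the printed double-centering with `1/n` row and
column means). The unsquared root would halve the spectral slope and break
the `H` relation; the squared form preserves it.

### The fast algorithm

The naive evaluation of `nu²_n` is `O(n²)`. The package's fast path
expands the sum of squared double-centered entries into three moments of
the pairwise-distance matrix — `Σ a²_{ij}`, the row sums `r_i`, and the
grand total — all of which are computable from one sort and prefix sums in
`O(n log n)`. The result is algebraically identical to the naive
statistic; the test suite drives both implementations over hundreds of
random vectors (Gaussian, heavy-tailed, tied) and requires agreement to
`1e-9` relative. The naive implementation is retained as the permanent
reference oracle.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `wavelet` | `"db6"` | Daubechies-6 (12 taps, 6 vanishing moments): smooth enough to annihilate low-order trends, short enough for 1024-sample windows. Haar, db2–db10, sym4–sym8 available. |
| `n_levels` | maximal (`J−1`) | Detail levels extracted; "decomposition level L" means `J0 = J − L`. |
| `window_size` | 1024 samples | Pipeline window (~1 s at 1 kHz). 1024 balances slope stability (10 octaves) against feature locality; a 165,000-sample session yields 161 windows. |
| pipeline `n_levels` | 5 | Detail levels per 1024-sample window. Five levels (j = 5…9) leave ≥ 32 coefficients per level used after the automatic level policy. |
| `estimator` | distance variance (fast) | See above; `"variance"` gives the classical spectrum. |
| `n_features` | 6 | Fisher-selected window positions fed to the classifiers. |
| `train_fraction` | 0.67 | Stratified per-group split, rounding to nearest; 22 + 28 subjects split 15 + 19 for training. |
| `knn_k` | 5 | KNN neighbourhood (capped at the training size); SVM uses an RBF kernel with library defaults. Neither is prescribed by the method; both are recorded in results. |
| `max_missing_fraction` | 0.8 | Sessions with *more* than 80% missing samples are rejected. |

## Numerical choices

**Periodic boundaries.** The pyramid uses periodized filters, so the
transform is exactly orthogonal (Parseval to machine precision), every
level has exactly `2^j` coefficients, and the explicit matrix form of the
transform is well defined — the test suite checks the pyramid against a
brute-force orthogonal-matrix product for n ≤ 64.

**Bridge detrending (default on).** A periodized transform sees the signal
as circular. For random-walk-like paths the wrap-around jump between last
and first sample acts as an artificial discontinuity whose energy leaks
into every level; with the plain variance estimator it can dominate the
fine-level energies outright. `estimate_hurst()` therefore subtracts the
line joining the endpoints before decomposing. The wavelets in use have
enough vanishing moments that this affects only boundary coefficients, not
the scaling behaviour.

**Automatic level policy.** The OLS fit by default excludes (i) the finest
detail octave, whose energy deviates from the theoretical scaling line for
*discretely sampled* fBm-type signals (a sampling/aliasing effect), and
(ii) levels with fewer than 8 coefficients, whose log energies carry a
large small-sample bias (the expected log of a χ² variable). If fewer
than three levels would survive, all levels are used. An explicit
`level_range` always overrides the policy; the contamination experiment
deliberately regresses over *all* levels because that is the protocol it
replicates.

**Degenerate inputs.** Levels with zero energy or fewer than two
coefficients are skipped with a warning rather than mapped to `-Inf`; if
fewer than three usable levels remain the spectrum errors, and in the
windowed pipeline such windows become `NA` features. Constant signals are
therefore rejected, not silently fitted. Signals of non-dyadic length are
truncated to the largest power of two (windows of 1024 are already
dyadic). Fisher ties and Youden ties both break toward the lower
index/threshold, with floating-point near-ties (rationally equal gammas
computed along different paths) treated as ties.

**Threshold selection.** The Youden-index threshold for logistic
regression is chosen on the *training* predictions and then applied to the
test partition. Selecting it on test predictions would leak information;
this is a deliberate divergence risk when comparing against analyses that
do not state where they thresholded.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
consumes: per subject, 8 sessions of 165,000 samples at 1 kHz (the
defaults mirror a task-based pupillometry design of 8 sessions × 20
trials, treating each session as one concatenated signal); group-level
differences expressed purely through the Hurst exponent of exact fBm
paths; an affine rescaling to a plausible pupil range (≈ 4 mm ± 0.3 mm,
irrelevant to slopes by scale invariance); and missingness placed as
contiguous blink-like bursts (default 200 ms) rather than i.i.d. dropouts,
totalling 30% of samples by default. Default group exponents are
`H_case = 0.85` and `H_control = 0.95`: controls near the regular end of
the range observed for pupillary dynamics, cases less regular, with a
separation small enough that classification is not trivially saturated.

What the generator does *not* contain: any physiological pupil model
(light reflex, task-evoked dilation, trial structure within a session),
measurement quantization, or slow drifts. Passing tests on this generator
therefore demonstrate that the estimator chain recovers scaling structure
and group differences *of the modelled kind*; they cannot certify
performance on real recordings, where group differences may be smaller,
nonstationary, and confounded.

The fBm simulator itself is exact (circulant embedding of the fGn
covariance, Cholesky fallback for tiny n), and is validated in the test
suite against the analytic covariance kernel and the closed-form fGn
lag-1 autocorrelation `2^{2H−1} − 1`.

## The contamination experiment

`contamination_experiment()` probes estimator robustness: each replicate
decomposes a fresh Brownian path (n = 1024, db6, 9 levels), perturbs
`min(100, 2^j)` randomly chosen coefficients per level with additive
Gaussian noise, and re-estimates `H` with both energy estimators. The
noise scale is a genuinely open choice — the protocol it replicates does
not state one — so it is exposed: per-level empirical SD (default),
pooled global SD, or an absolute value. Coarse levels with fewer than 100
coefficients are contaminated entirely.

Under the default calibration the distance-variance estimator shows
decisively smaller median bias than the variance estimator. Its
interquartile range, however, is statistically indistinguishable from the
variance estimator's in this regime: the distance variance has a somewhat
larger sampling variability on clean Gaussian coefficients, and its
smaller response to the contamination offsets that almost exactly. The
spread advantage emerges in more asymmetric, outlier-dominated regimes
(e.g. global-SD noise, where fine-level coefficients are hit with
perturbations far above their own scale).

## Problem sizes used by the validation suite

The shipped tests and validation runs use: 200 replicates for the
Brownian recovery and contamination studies (n = 1024); 200 replicates per
`H ∈ {0.3, 0.5, 0.7, 0.9}` at `n = 2^14` for parameter recovery (both
estimators within ±0.05 mean bias); and end-to-end cohorts of 30 + 30
subjects with 8 sessions of `2^13` samples — sizes chosen so the whole
suite exercises every stage at meaningful Monte-Carlo resolution while
remaining comfortably runnable on a laptop.

## Known limitations

* Windows are cut from the *compacted* signal (cleaning precedes
  segmentation), so samples within a window are not uniformly spaced in
  time wherever data were missing. This is inherent to the
  compaction-first design; heavy missingness will blur the time
  localization of window features.
* Sessions of unequal cleaned length are aligned by truncating every
  subject to the cohort-wide minimum window count; trailing data in longer
  sessions is unused.
* Feature selection is computed on the full feature matrix before the
  train/test split (as in the workflow the package operationalizes), which
  can optimistically bias small-cohort estimates; treat single-split
  metrics on few subjects as noisy.
* With perfectly separable training data, logistic regression saturates
  and the train-chosen Youden threshold sits at machine-precision
  distances from 0 or 1, making tiny-cohort LR results brittle. SVM/KNN
  are unaffected.
* No non-decimated transform, biorthogonal filters, wavelet leaders, or
  alternative Hurst estimators (DFA, periodogram); the decimated
  orthogonal spectrum is the point of the package.
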