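---
title: "Methods: EEG connectivity, microstates, and the RSBagging ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG connectivity, microstates, and the RSBagging ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsbagging)
```

This vignette documents the models implemented by the package, the
defaults it chooses where the analysis is genuinely open, the numerical
conventions, and what its synthetic validation does and does not
establish about real clinical EEG.

## Preprocessing

A recording is a channels-by-samples matrix in microvolts with a sampling
rate and montage labels; the default montage is the 20-electrode 10-20
layout with a hand-curated symmetric scalp adjacency. Preprocessing runs
in a fixed order:

1. **Bad-channel interpolation.** Channels named by the caller (or flagged
   by `detect_bad_channels()`) are replaced by the mean of their good
   montage neighbours. The detector scores each channel by the deviation
   of its log-variance from the median log-variance of its neighbours,
   standardized by 1.4826 × MAD across channels; the default threshold is
   a robust z of 5. The statistic is a package choice — variance outliers
   against local context are the standard symptom of a faulty electrode —
   and the MAD guard means identical channels can never be flagged.
2. **Average reference.** Every sample is centred across channels, so the
   instantaneous channel mean is 0 (asserted to 1e-9 of the data scale in
   the tests). All later stages (GFP, microstate maps, spatial
   correlations) assume this reference.
3. **Band-pass.** Windowed-sinc FIR (Hamming window), default passband
   0.5–45 Hz, transition width 0.5 Hz, applied forward-backward for zero
   phase. The forward-backward pass is evaluated in the frequency domain
   (multiplication by |B(ω)|² with reflection padding), which is
   mathematically the filtfilt result away from the edges and keeps the
   cost O(n log n) even at the ~3300 taps the 0.5 Hz transition implies at
   500 Hz.

Artifact handling is an epoch-level amplitude rule: after splitting into
epochs, any epoch whose peak absolute value exceeds 150 µV (configurable)
is dropped. Continuous-rejection algorithms from GUI toolboxes are
deliberately not imitated; an explicit threshold is reproducible and
preserves the shape contract of everything downstream.

**Epoching.** Analyses use 2 s epochs by default. The choice fixes the
spectral resolution at 0.5 Hz, so the 1 Hz analysis grid is exactly
resolvable, and gives one phase/amplitude observation per epoch; it is
exposed in the configuration because nothing in the method depends on it
structurally.

## Connectivity measures

All nonparametric measures share one substrate: per-epoch Hann-tapered
FFT cross-spectra on a 1 Hz grid spanning 1–45 Hz. The per-observation
phase difference of a channel pair is realized as `arg S₁₂`; no
filter–Hilbert decomposition is used. Formulas, per pair and frequency,
with ⟨·⟩ the average over observations:

| measure | definition | range |
|---|---|---|
| COH | \|⟨S₁₂⟩\|² / (⟨S₁₁⟩⟨S₂₂⟩) | [0, 1] |
| PLV | \|⟨S₁₂/\|S₁₂\|⟩\| | [0, 1] |
| PLI | \|⟨sign Im S₁₂⟩\| | [0, 1] |
| wPLI | \|⟨Im S₁₂⟩\| / ⟨\|Im S₁₂\|⟩ | [0, 1] |
| wPLI_de | (Σ_{j≠k} Im S₁₂⁽ʲ⁾ Im S₁₂⁽ᵏ⁾) / (Σ_{j≠k} \|Im S₁₂⁽ʲ⁾\|\|Im S₁₂⁽ᵏ⁾\|) | [−1, 1] |
| PPC | (\|Σ e^{iθⱼ}\|² − N) / (N(N−1)) | [−1, 1] |
| wPPC | (\|Σ S₁₂\|² − Σ\|S₁₂\|²) / ((Σ\|S₁₂\|)² − Σ\|S₁₂\|²) | [−1, 1] |

COH is implemented as magnitude-squared coherence, exactly as the
quotient above. The 0/0 convention is: wPLI, wPLI_de and PLI are 0
whenever their denominator vanishes (a purely real cross-spectrum, i.e.
zero-lag coupling — this is the deliberate zero-lag suppression of the
lag-index family), and COH is 0 when a channel has no power at a
frequency.

CSD is the magnitude of the observation-averaged cross-spectrum. POWCORR
is the orthogonalized log-power envelope correlation: per observation the
component of Y orthogonal to X has power Im(S_yx)²/S_xx, its log is
correlated with log S_xx across observations, and the two directions are
averaged. The power envelope comes from the shared epoch-FFT substrate
rather than a wavelet transform — one spectral decomposition feeds every
measure, and the orthogonalization (not the time-frequency atom) is what
gives the measure its robustness to shared zero-lag signal.

### Directed measures

DTF, PDC and GC derive from MVAR models
`x_t = Σ_k A_k x_{t−k} + e_t`, fitted by pooled least squares across
epochs (no lag crosses an epoch boundary). With `order = "auto"` the
order minimizes AIC over 1–20; fitted models must have companion spectral
radius < 1. From `A(ω) = I − Σ A_k e^{−2πiωk/fs}`, `H = A⁻¹`,
`S = H Σ H*`:

- `GC_{x→y}(ω) = ln( S_yy / (S_yy − (Σ_xx − Σ_yx²/Σ_yy)|H_yx|²) )`,
- `DTF_ij = |H_ij|² / Σ_m |H_im|²` (rows sum to 1),
- `PDC_ij = |A_ij|² / Σ_m |A_mj|²` (columns sum to 1).

Orientation: the GC array is indexed (source, target); DTF and PDC keep
the indexing of their normalizations, in which entry (i, j) carries the
influence of channel j on channel i. In the feature pipeline GC is
computed from bivariate (two-channel) models per pair, matching its
pairwise formula; DTF and PDC come from one full multivariate model,
which is the setting in which their normalizations are meaningful.

### Vectorization

Features are the arithmetic band average (1–45 Hz by default) unfolded
over the upper triangle (i < j in montage order): 190 values for 20
channels. Directed matrices are asymmetric, so a reduction is required to
reach the same width; the upper triangle is the package's documented
choice, and `directed_full = TRUE` emits all n(n−1) ordered pairs
instead.

## Microstates

GFP at sample t is the spatial RMS of the average-referenced map.
Clustering operates on the maps at local GFP maxima — the standard
practice, since topographies are most stable and best-determined at GFP
peaks. The modified k-means is polarity-invariant throughout: a map is
assigned to the prototype maximizing the squared spatial projection, and
each prototype update is the first principal eigenvector of its assigned
maps' scatter matrix, so v and −v are equivalent. Iteration stops when
the relative GEV change falls below `tol` (default 1e-6); the best of
`restarts` (default 20) seeded initializations is kept, and an emptied
cluster is re-seeded from the worst-explained map. Backfitting labels
every sample by maximal absolute spatial correlation; zero-GFP samples
inherit the neighbouring label; optional smoothing merges runs shorter
than `min_duration_ms` into their predecessors (default 0 = off, since
no smoothing is assumed by the parameter definitions).

Per-state parameters: mean GFP (µV), mean run duration (ms), occurrence
(runs/s), coverage (fraction of samples; sums to 1 by construction), and
GEV `= Σ_{t∈k} (GFP_t · corr(v_t, map_k))² / Σ_t GFP_t²`. The feature
vector concatenates the five parameters over states ordered by
descending coverage — prototype indices are arbitrary across subjects,
so an intrinsic ordering is needed for features to be comparable; in
group analyses the intended protocol is to fit prototypes on training
subjects only and backfit everyone, avoiding test-set leakage.

## RSBagging

Given a two-class cohort with the positive class the minority:

1. **Stratified split** — each class contributes round(n·f) subjects to
   the test set (default f = 0.3; the split fraction is a package
   default, exposed in configuration), preserving the cohort imbalance in
   the test set.
2. **Balanced subsets** — each of N subsets is the full minority set plus
   an equal-size random majority sample, drawn *without replacement
   within* a subset (each majority part is a genuine subset of the
   majority class) and independently *across* subsets, which is where the
   ensemble's diversity comes from. A with-replacement-within option
   exists behind a flag.
3. **Base models** — one Gaussian-kernel SVM per subset (C = 1 by
   default; γ defaults to 1/(p·var) on z-scored features, the common
   scale heuristic). Features are z-scored with training-set statistics
   only. Probabilities come from a Platt-style sigmoid fitted in-package
   on each model's decision values with Platt's smoothed targets; this
   replaces libsvm's internal cross-validated calibration, whose
   unseeded shuffling would break run-to-run reproducibility.
4. **Abstaining soft vote** — the mean positive probability p is
   thresholded at α ∈ [0.5, 1]: positive if p ≥ α, negative if
   1−p ≥ α, otherwise no prediction. At α = 0.5 the tie p = 0.5 goes
   to the positive (minority) class, so binary cohorts always get full
   coverage there.
5. **Metrics** — accuracy, sensitivity, specificity and F1 are computed
   from the confusion counts of *predicted* subjects only; Predict Rate
   divides the number of predicted subjects by the full test size. All
   five are reported as percentages.

N defaults to 11 — odd, so that even an uncalibrated hard vote could not
tie — and both N and α are first-class configuration, with the α grid
0.5–0.6 in steps of 0.02 as the default sweep.

## Synthetic generators and what they establish

Each generator produces exactly the structure one stage assumes, under a
mandatory seed:

- **Oscillators**: per-segment random tone phases; a coupled pair shares
  phase up to a fixed lag plus von Mises jitter with concentration
  κ = 10·(s/(1−s))², mapping strength s = 1 to exact lock and s = 0 to
  independence. Segments default to the 2 s epoch length so each epoch is
  one independent phase observation.
- **MVAR**: exact simulation of a stable model with 500 samples of
  burn-in; sample autocovariances are checked against the Lyapunov
  fixed-point values in the tests.
- **Microstates**: piecewise-constant templates with shifted-geometric
  run lengths (default mean 80 ms, within the 40–150 ms range typical of
  resting microstates), random per-segment polarity, mild amplitude
  jitter, and white sensor noise.
- **Cohorts**: class-conditional Gaussian feature tables; the `table1`
  preset reproduces a 241-subject clinical composition (144 awake vs 97
  DoC subjects, with sex, motor-side and lesion-side counts), with mean shifts
  along orthogonal directions per clinical attribute so every task is
  learnable from one table. The default separation of 2 feature-space
  standard deviations makes the tasks learnable but imperfectly so —
  deliberately, since a separable cohort would make the imbalance
  problem invisible.

These generators validate *mechanics and calibration*: estimator
formulas against closed-form population values (e.g. PLV → I₁(κ)/I₀(κ)
under von Mises phases, PPC's unbiasedness under the uniform null),
directed measures against a dense-grid inversion oracle, parameter
recovery under planted structure, and the ensemble's behaviour under
controlled imbalance. They do not emulate volume conduction beyond
zero-lag mixing, 1/f spectra, non-stationarity, or real artifact
morphology — so passing tests demonstrate correctness of the methods,
not clinical performance on real EEG.

## Numerical choices and degenerate inputs

- Frequency grids snap to the epoch's resolvable bins; a grid finer than
  1/T is rejected rather than interpolated.
- Ratio measures use the 0/0 → 0 convention documented above; POWCORR
  returns 0 with a warning when a power envelope has zero variance.
- `evaluate()` keeps abstained subjects out of the confusion counts but
  in the Predict Rate denominator; when a metric's own denominator is
  empty (e.g. no predicted positives) it is NA, and an all-abstained
  test set is flagged rather than scored.
- Cluster assignment ties break to the first prototype; eigenvector
  polarity is irrelevant by construction.
- Unstable MVAR fits raise an error suggesting a lower order; singular
  spectral matrices report the offending frequency.
- EDF export quantizes to 16 bits over a symmetric range covering the
  data; round-trip error is bounded by one digitization step.

## Problem sizes

The test-suite and verification runs use desk-scale problems chosen so
each statistical check has comfortable resolution: 2 000 observations for
phase-measure calibration (Monte-Carlo error ≈ 0.01 on PLV), 800 epochs
for zero-lag suppression (null wPLI ≈ N^{−1/2} ≈ 0.035), 60 s of
synthetic EEG for microstate recovery, 100 random models for the
normalization identities, and 20 replicates of 1 000-subject 10:1
cohorts for the imbalance contrast.

## Limitations

Sensor-space connectivity only; no source modelling, no time-varying
connectivity, no statistical thresholding of connectivity graphs; the
microstate module does not compute canonical A/B/C/D template matching or
transition syntax; the ensemble is strictly binary. The clinical
usefulness of any particular measure is a property of real cohorts and
cannot be established by this package's synthetic validation.
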