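---
title: "Methods: feature extraction, selection, and topological charting for pain recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature extraction, selection, and topological charting for pain recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

painfeat implements a complete analysis pipeline for recognizing calibrated
heat-pain levels from peripheral physiological signals: three surface EMG
channels (zygomaticus, corrugator, trapezius), skin conductance (SCL), and
ECG. This vignette documents the models and procedures, the tunable
parameters and their defaults, the synthetic data generator that stands in
for the access-restricted source database, and the numerical and design
choices made where the protocol left them open.

## The experimental design being emulated

The reference protocol records five synchronized channels while a thermode
delivers one of five per-subject-calibrated stimulus levels: baseline `B`
(32 °C, no pain), pain threshold `T1`, two interpolated levels `T2`/`T3`,
and pain tolerance `T4`. Each of 85 subjects contributes 20 trials per
level; the physiological response is a 5.5 s window per trial. Four
classification problems are defined over these levels: pain threshold
(B vs T1), pain tolerance (B vs T4), three-class (B/T1/T4), and five-class.

Because the source database is available only on request, the package ships
a generator (`make_roster()`, `synth_trial()`, `synth_dataset()`) that
reproduces this design with documented channel models:

* **EMG** — band-limited (20–250 Hz by default) Gaussian noise whose
  envelope amplitude scales with the level ordinal times a per-subject
  log-normal gain (median 1, log-SD 0.25). The facial channels carry larger
  level effects than the trapezius.
* **SCL** — a tonic baseline (uniform 2–10 µS per subject) plus a
  stimulus-locked phasic response with a bi-exponential Bateman kernel
  (rise 0.75 s, decay 3 s, ~0.8 s latency), amplitude increasing with level.
* **ECG** — a Gaussian-bump QRS template train at the subject's resting
  rate (uniform 55–95 bpm), with the mean rate decreasing slightly with
  level. Only R-peak timing matters for the HRV features, so no further
  morphology is modeled.
* All channels receive an additive 50 Hz power-line sinusoid of
  configurable amplitude.

Level effects are parameterized directly as Cohen's *d* between baseline
and tolerance on each channel's driving parameter, standardized by that
parameter's trial-to-trial SD (25 % relative for the amplitude channels,
0.8 bpm for heart rate). The defaults — facial EMG 0.6, trapezius 0.35,
SCL 0.6, heart rate −0.35 — place the strong channels in the
medium-to-large band and the weak ones in the small band, matching the
qualitative pattern the protocol reports (facial EMG and phasic SCL rise
with pain; heart rate falls slightly). Setting every effect to zero
(`null_effects()`) makes the five levels exchangeable, which is the basis
of the type-I-error calibration experiments. A companion generator,
`synth_feature_matrix()`, draws trials directly at the feature level
(subject random intercepts plus unit noise) with designated columns
carrying exact standardized level effects; it is used wherever an
experiment needs the injected effect size to be exact on the feature scale.

What the generator deliberately does **not** emulate: real EMG burst
structure and motion artifacts, SCL drift nonstationarity, ECG morphology
beyond the R wave, any correlation between channels beyond the shared
stimulus, and the absolute amplitude scales of the original recordings.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and well calibrated, not that its accuracy numbers transfer to real
recordings.

The recommended sampling rate is 512 Hz (the public documentation of the
emulated database), which supports the 250 Hz upper EMG band edge.
Full-roster experiments (8 500 trials) run at a reduced rate of 128 Hz with
the EMG band capped at 55 Hz; 128 Hz is the practical floor because the
50 Hz power-line component must stay below Nyquist. The generator enforces
`fs > 2 × emg_band[2]`.

## Preprocessing

`preprocess_trial()` applies, per channel:

1. **Zero-phase Butterworth filtering** (4th order): 20–250 Hz for EMG,
   0.1–250 Hz for ECG; SCL is only segmented, never filtered. Filtering is
   forward–backward with odd-reflection padding and steady-state initial
   conditions, so a DC input maps to numerically zero output and peak
   timings (used by the TMNP/TMNV features) are not shifted.
2. **Power-line removal by empirical mode decomposition.** The signal is
   sifted into intrinsic mode functions (natural-cubic-spline envelopes
   with the two outermost extrema mirrored about each boundary;
   ratio-of-sums Cauchy stopping criterion, tolerance 0.2; at most 10 IMFs
   and 50 sifting passes). The IMF whose FFT-peak frequency lies within
   ±5 Hz of the line frequency is dropped and the signal reconstructed
   without it; if no IMF qualifies the signal passes through unchanged and
   the provenance records it.
3. **Response-window segmentation** — a pure half-open slice of the 5.5 s
   window starting at stimulus onset. The generator's recordings are
   exactly the response window (onset at t = 0); the protocol's wording
   ("the window after the onset") is interpreted as onset-aligned.
4. **Hilbert spectrum** per continuous channel: each IMF's analytic signal
   gives instantaneous amplitude and frequency; squared amplitudes are
   accumulated on a time × frequency grid (64 frequency bins over
   [0, fs/2], one time bin per 16 samples). Binning conserves total energy
   by construction. The pipeline reuses the power-line decomposition with
   the line IMF excluded, which is equivalent to decomposing the cleaned
   signal up to re-sifting error and halves the EMD cost.

## The 155-feature bank

`feature_registry()` defines the canonical order: 39 features per EMG
channel (`z`/`c`/`t` prefixes), 35 for SCL (`s`), and 3 HRV features for
ECG (`h`). SCL omits the four spectral-shape features (BW, CF, MOF, ZC)
that are undefined for the slow electrodermal channel — note this keeps
MNF and MDF for SCL. Seven theoretical groups:

* **Amplitude**: MAV, RMS, PK, P2P; higher-order MAVs of the first and
  second differences with MAV-normalized variants (an operationalization —
  the normalizing convention is ours); mean relative times of local maxima
  and minima (strict sign-change extrema, no prominence threshold, time
  normalized to [0, 1], zero when no extrema exist).
* **Variability**: sample VAR/SD, range, IQR (linear-interpolation
  quantiles).
* **Stationarity**: median; SD of sub-window means and SDs over 10 equal
  non-overlapping sub-windows (remainder samples dropped); and a
  degree-of-stationarity family from the Hilbert spectrum,
  DS(f) = mean over time of (1 − H(f,t)/H̄(f))², with IDS its trapezoid
  integral over frequency and MIDS/MMNDS the energy-weighted integral and
  mean. The weighting by marginal spectral energy is our reading of the
  "modified" variants, isolated behind the registry so alternates can be
  swapped in.
* **Entropy**: ApEn, SampEn (Chebyshev distance, m = 2, r = 0.2 SD),
  FuzzyEn (exponential membership exp(−(d/r)²)), Shannon entropy of a
  16-bin amplitude histogram (bits), and spectral entropy of the Welch
  spectrum normalized to [0, 1]. A constant signal yields all zeros.
* **Linearity**: for lags 1…32, excess nonlinear dependence
  max(0, g(τ) − ρ(τ)²) with g = 1 − exp(−2 MI) from a Miller-Madow-corrected
  histogram MI and ρ the autocorrelation; LDF averages over lags, PLDF
  pools all lag pairs. The bias correction matters: without it the MI
  estimator's O(bins²/n) positive bias masks the linear/nonlinear contrast
  entirely.
* **Similarity** (against the subject's pain-free baseline recording, same
  channel): Pearson CC, histogram MI (16 × 16 bins, nats, uncorrected —
  the raw estimator is the feature here, since no difference of estimates
  is taken), and Welch magnitude-squared coherence summaries over the
  modality passband (EMG: the EMG band; SCL: 0–2 Hz): mean, median,
  trapezoid integral, and mean over bins with coherence > 0.5 (zero when
  empty). The baseline reference is a dedicated extra baseline recording
  per subject, not one of the 20 counted trials.
* **Frequency**: Welch spectrum (Hamming, fs/2-sample segments, 50 %
  overlap) moments MNF/CF/BW, interpolated MDF, spectral peak MOF, and
  sign-change count ZC with zero samples skipped and no hysteresis
  (signals are pre-filtered).
* **HRV** (ECG only): R peaks via 5–30 Hz bandpass → squaring → adaptive
  threshold (half the rolling 1.5 s maximum) with a 250 ms refractory
  period; MNRR, RMSSD, and the least-squares RR slope in ms/beat. Windows
  with fewer than three peaks yield zeros and a sparse flag — a 5.5 s
  window can legitimately be sparse. Because these features are computed
  on RR *intervals* (ms), a heart-rate decrease with pain surfaces as an
  MNRR increase.

`extract_features()` guarantees a finite 155-vector (degenerate conventions
absorb NaN/Inf). `zscore_normalize()` fits per-column means/SDs on a stated
row subset only — inside cross-validation always the training rows, so no
leakage — and maps constant columns to zero.

## Feature selection and classification

`make_epoch_splits()` reproduces the repeated-epoch scheme: per epoch,
within every (subject, level) stratum, a one-quarter hold-out (75 % train /
25 % test) and a 3-fold split of the train rows; one fold (chosen per epoch
from its seed) is the wrapper validation set and the other two are the
feature-selection train set. On the 20-trial roster this gives exactly
15/5 and 10/5 rows per subject per level. Other roster sizes use
nearest-integer stratification. The study default is 100 epochs; desk-scale
experiments here use 10–20.

Univariate selection (`ufs_rank()`) ranks features by the mean one-way
ANOVA F value across epochs, computed on each epoch's FS-train rows; ties
break by registry order, and a zero-within-variance feature with distinct
means sorts first (F = ∞ by convention).

Wrapper selection (`sfs_epoch()`) is greedy sequential forward selection
with a Gaussian Naive Bayes objective (variance floor 1e−9) trained on the
FS-train rows and scored by validation-fold accuracy; ties break by
registry order; the full iteration curve is kept for post-hoc analysis.
`sfs_vote()` tabulates per-iteration votes across epochs (the reported
vote-table shape). For the *consensus set* we use `sfs_consensus_set()`:
repeated plurality voting in which each epoch votes for the first feature
in its own selection order not yet in the set. With similarly informative
features, epochs disagree on ordering and plain per-iteration winners
fragment (the same feature can win several iterations while late
iterations are won by validation noise); the first-unseen aggregation
yields a distinct-feature set and recovers designated informative features
reliably. Both views are exposed.

`evaluate_curve()` trains, for each feature-count n, a linear soft-margin
SVM (C = 1, one-against-one for multi-class, features z-scored with
statistics fit on the outer train rows) and reports held-out accuracy mean
± SD across epochs. `curve_maxima()` returns the local maximum — the
smallest n whose step to n + 1 is neither statistically significant
(paired t-test across epochs at α = 0.05) nor substantive (mean gain
≥ 0.5 accuracy points) — and the global maximum, the rounded mean of the
per-epoch argmax. The step test is necessarily a cross-epoch construct
(one accuracy value per epoch per n carries no within-epoch variance), so
the local maximum is a single number rather than a per-epoch average; it
is capped at the global maximum so the invariant local ≤ global always
holds, with an improving-to-the-end curve yielding local = global = N.

## The Mapper feature chart

`mapper_chart()` charts the *feature space*: the z-scored feature matrix is
transposed so the 155 features are points and trials are coordinates
(`feature_point_cloud()`), with Euclidean pairwise distances. The lens is
the distance to the 2nd nearest neighbor (`knn_filter()`, an inverse
density). The cover (`build_cover()`) is the standard uniform-interval
construction: N = 4 intervals of length range/(N − (N−1)L) stepped by
(1 − L) of their length so consecutive intervals overlap by L = 50 % of
their length; boundary values are assigned inclusively, and a constant
lens degenerates to a single interval. Each region is clustered by Ward
(`ward.D2`) agglomeration (`cluster_region()`); the distance is Euclidean
throughout, which is what Ward linkage presumes. The tree is cut at the
first merge-height gap exceeding the mean plus one SD of all gaps — single
cluster if none qualifies, and regions of one or two members stay single
clusters (two points carry a single merge and no gap structure). Nodes are
the clusters; edges connect nodes sharing features, weighted by the
intersection size; nodes carry size, mean lens, and modality composition
(`assemble_chart()`). `annotate_feature_sets()` tags nodes with named
feature sets for chart-based comparison of selection results, and
`write_chart_graphml()` exports GraphML plus a JSON companion. Functional
group labels (signal amplitude and power, nonlinear complexity, frequency
information, unique, connecting) are analyst annotations in the original
protocol, so they are exposed as optional manual set annotations rather
than an algorithm. Charting uses the globally z-scored matrix: the chart
is descriptive, not predictive, so no per-fold normalization applies.

## The interaction analysis

`interaction_table()` compares baseline against pain tolerance per feature:

1. subject effects are removed by per-subject centering over **all**
   available rows (for balanced data this equals fixed per-subject
   intercepts, and using all levels rather than only B/T4 rows spreads the
   centering constraint and keeps the two-sample test close to its nominal
   level);
2. normality of the pooled residuals is tested by a Kolmogorov–Smirnov
   test against a normal with estimated parameters; rejection at 0.05
   routes to a Wilcoxon rank-sum test, otherwise a two-sample t-test;
3. Cohen's d is computed on the residualized values (test and effect size
   on the same scale), signed tolerance-minus-baseline, with (n−1)-weighted
   pooling;
4. the arrow category applies the 0.2 / 0.5 / 0.8 bands gated on p < 0.05,
   upward when tolerance exceeds baseline.

No multiple-testing correction is applied by default, matching per-feature
reporting; p-values are exported so any correction can be applied
downstream. The wide table reports `na` for modality–feature pairs outside
the registry.

## Problem sizes, calibration, and what the experiments show

The package's own experiments (test suite and `scripts/acceptance.R`) use
these scales, chosen once as desk-scale stand-ins for the full study:

* full-roster structural runs (85 × 5 × 20 = 8 500 trials) at 128 Hz;
* the synthetic classification study at 12 subjects × 10 trials/level,
  10 epochs;
* type-I calibration in two parts. First, 1 000 independent replicates,
  each a fresh null-mode reduced roster (5 subjects × 4 trials/level) drawn
  at the feature level with one per-feature test run per replicate,
  rotating through the registry — independence makes the rejection-rate
  estimate binomial (SE ≈ 0.7 %), the scale on which a 3.5–6.5 % band is
  meaningful. Second, a signal-level check pooling all 155 tests over 20
  null datasets run through the full extraction pipeline: per-feature
  tests within one dataset share trials and co-reject, so this pooled rate
  has SE ≈ 5 %/√K rather than binomial, and it is asserted within a
  3-sigma envelope around the nominal level (a 60-dataset study measured
  the pipeline's long-run null rate at 4.7 %, with the ECG features
  conservative because their sparse-window and tie conventions create
  point masses);
* recovery experiments at 20 subjects × 20 trials/level and 20 epochs with
  designated feature-level effects of d = 0.6–1.0 for selection and
  band-centered magnitudes 0.35 / 0.65 / 1.0 (and −0.65) for the
  interaction categories. Feature-level injection is used precisely
  because the injected d is then exact by construction, making
  band-recovery a well-posed check; signal-level direction recovery is
  verified separately against the generator's constructed effects.

Monte-Carlo assertions in the tests are designed so that their sampling
distributions sit several standard errors inside the asserted bounds under
the stated conditions; they verify calibration and recovery of the
machinery, not any claim about real physiological recordings.

## Known limitations

* The EMD variant is the standard sifting algorithm; no ensemble (EEMD)
  or noise-assisted variant is provided, and mode mixing on real signals
  is not addressed.
* LDF/PLDF, the higher-order MAVs, the degree-of-stationarity family, and
  the "modified" coherence summaries are operationalizations of named
  features whose exact formulas live in sources not reproduced in the
  protocol; each is documented above and isolated behind the registry.
* The SVM evaluation retrains on the outer-train rows per feature count
  and reports outer-test accuracy; reusing validation folds would be the
  main alternative reading.
* At strongly reduced sampling rates the 50 Hz line component falls
  *inside* the capped EMG band, and the matched IMF then carries genuine
  EMG energy: line removal at 128 Hz attenuates the injected EMG amplitude
  effect from d ≈ 0.6 to ≈ 0.2, whereas at 256 Hz (band 20–110 Hz) and at
  the native 512 Hz the line IMF is spectrally separable and the effect
  survives (measured d ≈ 0.6 and ≈ 0.7–0.9). Structural full-roster runs
  therefore use 128 Hz, while effect-sensitive experiments use 256 Hz or
  more. The same caution applies to real low-rate recordings.
* Runtime: full-roster extraction is practical at the reduced sampling
  rate; a full 512 Hz, 100-epoch replication is outside desk scale.
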