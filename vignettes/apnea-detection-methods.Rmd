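---
title: "Methods: multi-signal apnea detection with a stacked error-reducing classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-signal apnea detection with a stacked error-reducing classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The detection problem

Obstructive sleep apnea (OSA) is a repeated collapse of the upper airway
during sleep lasting 10 s or more. In polysomnography (PSG) an apnea
leaves coordinated traces across channels: the airflow amplitude drops to
a small fraction of its basal value; thoracic and abdominal effort
persists (attenuated, often paradoxically counter-phased) because the
obstruction is mechanical, not central; blood oxygen saturation (SaO2)
dips several percentage points with a circulation delay of roughly
10-20 s; and the heart rate cycles through bradycardia during the event
and tachycardia on arousal. `apneamer` turns these signatures into a
per-segment binary classification (apnea vs normal) through four stages:
channel-specific preprocessing, a 66-feature multi-domain battery,
two-stage feature selection, and a stacked "multi-error-reduction" (MER)
classifier.

Two segmentation protocols share one feature code path. Event-duration
segmentation scores the physiologist-annotated intervals themselves;
fixed 60 s windows reflect deployment, where no event boundary is known
in advance. A window inherits the apnea label when its overlap with
annotated apnea time is at least 10 s — the clinical minimum event
duration; the threshold is configurable (`overlap_min_s`). Trailing
partial windows are dropped rather than padded, because most features
assume a full-length window.

## Preprocessing

* **SaO2 (1 Hz).** Point-to-point changes of more than 8 percentage
  points are non-physiological; such samples are replaced by the median
  of the first 10 s of the series. The scan compares each sample with its
  *corrected* predecessor, which makes the operation idempotent.
* **Airflow (10 Hz to 1 Hz).** A 10 s running-median baseline is
  subtracted, a 3rd-order Butterworth low-pass at 3 Hz removes noise, and
  the series is decimated to 1 Hz. Note that a 10 s median spans only 2.5
  cycles of typical 0.25 Hz breathing, so the baseline stage itself
  absorbs a modest share of the respiratory tone; this is inherent to the
  stated window length.
* **Effort (10 Hz).** 60 s running-median baseline, Butterworth band-pass
  0.05-4 Hz, order 3 per direction.
* **ECG (125 Hz).** Butterworth band-pass 0.05-40 Hz (order 3), which also
  performs baseline correction.

All filters are applied with exactly zero phase so that event boundaries
are not shifted: the signal is mirror-extended to twice its length and
multiplied in the frequency domain by the *squared* closed-form digital
Butterworth magnitude — the gain of a forward-backward pass. This
construction is exactly symmetric under time reversal and has no edge
transients, properties that a time-domain forward-backward filter only
approximates.

R peaks are found by a modified Pan-Tompkins detector: 5-15 Hz band-pass,
five-point derivative, squaring, 150 ms moving-window integration, and
adaptive signal/noise thresholds with a 200 ms refractory period. The
modifications are (a) the already band-passed ECG is re-filtered 5-15 Hz
inside the detector, (b) a 2 s learning phase initialises the thresholds,
and (c) a search-back pass at half threshold recovers beats missed for
longer than 1.66 times the running RR average. Detected positions are
refined to the local ECG maximum.

RR intervals outside 0.3-2.0 s, or deviating more than 20% from the
median of the five surrounding intervals, are replaced by that local
median (clamped to the range). This concrete rule is the package's
rendering of heart-rate-correction practice; both thresholds are
configurable in `preprocess_config()`. The ECG-derived respiration (EDR)
signal uses the R-wave-area principle: per beat, the mean amplitude of
the 120 ms QRS window after removing the window's endpoint baseline,
linearly interpolated to 1 Hz.

## The 66 features

Twelve SaO2 features (median, MM2, kurtosis, variance, minimum, mean,
mean-crossings, Lempel-Ziv complexity, Poincare SD1, Bel98/Abo98, and the
0.016-0.05 Hz Yule-Walker band mean) capture desaturation dips and
recovery dynamics. Ten airflow features add Welch band means (0-0.1 and
0.4-0.5 Hz), db3 depth-3 wavelet means and complexity. Six abdominal and
six thoracic features summarise effort amplitude and its upper spectral
band. Thirty-two ECG features combine RR-interval statistics (one-sided
NN50, SDSD, half-window SD difference, serial correlations at lags 3-4,
dominant frequency in 0.03-0.5 Hz, wavelet spectral density), ECG-sample
moments and spectral shape, sym3 depth-7 detail entropies and variances,
the EDR coefficient of variation, and a kernel-PCA summary of QRS
morphology.

Interpretation choices where a name alone under-determines a formula:

* **MM2** counts adjacent local-extremum excursions larger than
  2 percentage points, scanning the alternating extrema sequence with
  plateaus collapsed.
* **Bel98/Abo98** are seconds strictly below / at-or-above 0.98 times the
  window maximum (sample counts at 1 Hz).
* **Lempel-Ziv complexity** binarizes at the window median (values at or
  above the median map to 1) and counts LZ76 phrases, normalized as
  `c(n) log2(n) / n`. A phrase is closed at the first symbol that makes it
  novel relative to all preceding text (overlap allowed); a trailing
  suffix that stays reproducible adds no phrase, so a constant window has
  count 1. With two-valued windows an unbalanced median can binarize to a
  constant; on real oximetry (quantized to 0.1) this is rare.
* **SDSD_RR** is the standard deviation of successive RR differences (the
  standard HRV meaning); **tSD_RR** is the absolute difference between
  the RR standard deviations of the two segment halves.
* **WSD_RR** is the total sym3 detail energy of the RR window divided by
  its length (depth capped at `floor(log2(n))`).
* **var/kur** in the ECG block act on the ECG samples, not the RR series.
* **Spectral spread / decrease** use the standard audio-descriptor
  formulas on the Welch PSD of the ECG window (2 s Hann segments, 50%
  overlap).
* **kPCA**: RBF kernel with the median-heuristic bandwidth, double-centred
  kernel, eigenvalues scaled by the beat count; the two features are the
  largest eigenvalue and the relative power of the second component. The
  median heuristic keeps the operation deterministic and parameter-free.
* **Normalized-band convention.** The effort and ECG "80-100 Hz" bands
  exceed the Nyquist frequency of their channels (5 and 62.5 Hz), which is
  physically impossible; the band edges are therefore read as percentages
  of Nyquist — the uppermost fifth of the spectrum — uniformly across
  channels. The convention is explicit in `band_stat()` and swappable.

Degenerate segments degrade gracefully: fewer than 2 RR intervals zero
the RR features, fewer than 3 beats zero the kPCA pair, constant series
return zero complexity/correlation — always with a warning, never a
non-finite value.

### Numerical choices

The wavelet transform is the orthonormal periodized DWT (db2, db3; sym3
coincides with db3 at order 3). For even lengths at every level the
transform is exactly orthogonal (Parseval to machine precision); odd
lengths are extended by one repeated sample. Welch estimates use Hann
windows with the overlap floored to whole samples (the airflow
configuration "5 samples, 2.5 overlapped" becomes overlap 2) and
zero-padding to 256 points so that narrow bands contain several grid
points at 1 Hz sampling. Yule-Walker spectra use order 5 throughout, with
40-sample segment averaging on effort channels; a constant segment yields
a flat zero spectrum with a warning rather than an error. Kurtosis is the
Pearson (non-excess) moment ratio, 3 for a normal distribution, defined
as 0 for constant windows.

## Two-stage feature selection

**Stage 1 (statistics).** Per patient and feature, a one-way ANOVA
(equal-variance F test) and a Wilcoxon rank-sum test compare apnea vs
normal segments; a pair is positive when both reject at alpha = 0.05. The
rank-sum criterion is read as the binary rejection indicator — the
toolbox convention — since a literal "p = 1" criterion would select only
ties. `lambda[feature]` counts positive pairs across patients; a feature
survives when lambda strictly exceeds half the processed patients. No
multiple-testing correction is applied within Stage 1: the cross-patient
counting is itself the aggregation device. Patients lacking two segments
per class are skipped and reported.

**Stage 2 (SVM wrapper).** Selected features are either grouped into
classes by descending lambda — split at the largest gaps between distinct
lambda values, ties sharing a class — and hill-climbed over cumulative
class unions against an all-features baseline on a 21-configuration SVM
grid (linear; polynomial degree 2-4; RBF sigma 1, 5, 25; each at R in
0.2, 1, 10); or ordered individually by lambda and grown as prefixes
under a single SVM configuration until the all-features baseline accuracy
is reached. In the class variant the winner is the candidate with the
best mean AUC among those within one accuracy point of the best —
accuracy adjudicates, AUC breaks near-ties; both tolerances are
arguments. Splits are always at the patient level, so no patient
contributes to both sides of any train/validation boundary.

Before selection the training split is balanced and cleaned: rows with
any feature more than 3 SD from its mean are dropped, then the majority
class is undersampled to the minority count with a fixed seed.

## The MER stacked classifier

Four gradient-boosted tree learners form level 0. The package configures
them as four xgboost variants — classic shallow-tree gradient boosting,
a depth-wise default, a leaf-wise (lossguide) grower, and a heavily
regularised variant — all capped at 300 trees, depth 6, learning rate
0.1. The specs are pluggable: anything implementing `fit(x, y, seed)` /
`score(model, x)` can stand in, and the tests exercise that contract
directly.

Level 1 is a neural network with input width 4 (one probability per base
learner), one hidden layer of 4 units, and a sigmoid output — backprop on
cross-entropy for at most 500 epochs, early-stopped on a 10%
meta-validation slice (validation error rate selects the kept weights,
cross-entropy breaks ties). Because the four base probabilities are
strongly correlated, the net uses heavy weight decay (0.05), which
shrinks the combiner toward the robust averaging solution, and its
restarts include informed initialisations at the "copy base j" weight
configurations — so the fitted combiner starts no worse than its best
single input and training can only refine from there. Meta-features are
out-of-fold probabilities: for each of k = 5
folds (grouped by patient, both classes required in every fold), base
learners trained on the remaining folds score the held-out fold, so no
row is scored by a model that saw it. Probabilities rather than hard
labels are passed upward because they preserve the bases' confidence;
the meta-network can threshold internally. The deployment threshold is
fixed at 0.5; ROC curves use the raw scores, and AUC is the trapezoidal
area (equal to the Mann-Whitney statistic), with the standard ideal at
sensitivity = specificity = 1.

## The synthetic study conditions

`synthetic_config()` defines the cohort every test and the acceptance
script run: 40 patients, 1 h records, 30 apnea events per hour (patient
multiplier 0.7-1.3), event durations 10-60 s, desaturation depth 3-10
points delayed 15 s with exponential resaturation, airflow collapse to
10% of basal with 2 s transitions, breathing at 0.25 Hz, basal RR 1.0 s
with respiratory sinus arrhythmia, in-event RR lengthening and post-event
shortening, ECG synthesised by placing an amplitude-modulated QRS
template at the cumulative RR times plus baseline wander and white noise,
SaO2 quantized to 0.1 with occasional >8-point spike artifacts so the
artifact-removal path is exercised. Obstructive morphology is the
default: effort persists at half amplitude with the abdominal band
counter-phased; a central mode (effort collapses with airflow) is
available. Ground truth carries exact R times and event intervals, which
is what lets detector sensitivity/precision be scored without human
labels.

What the generator does *not* emulate — and what passing tests therefore
do not show about clinical data: hypopneas and mixed events, arousals and
sleep-stage structure, electrode artifacts beyond Gaussian noise and
oximeter spikes, ectopic beats and atrial fibrillation, position-dependent
signal quality, and the physiological coupling between channels beyond
the programmed signatures. Synthetic separability is far cleaner than
clinical overnight recordings; end-to-end accuracy here validates the plumbing
and the feature battery's sensitivity to the programmed signatures, not
clinical performance.

### Problem sizes

The test suite runs the full pipeline on the default 40-patient cohort
(2400 windows), the selection-recovery property on twenty 40-patient
feature cohorts (10 informative + 56 noise features, 1 SD class
separation, 30 segments per class per patient), preprocessing recovery on
10 records, and the LZ76 oracle over all 4096 binary strings of length up
to 12. The AR-spectrum identity is checked both at the 4096-sample single
fit and, in the acceptance block, on a 131072-sample realization with
8-segment averaging, where the 10% relative-L2 bound holds with a wide
margin for every seed tried; at 4096 samples the sharp AR(1) peak leaves
roughly 10-15% typical error, which is a statement about estimator
variance, not implementation fidelity.

## Known limitations

* The EDF reader/writer covers 16-bit, whole-second-record EDF — enough
  to exchange the five canonical channels, not EDF+ annotations.
* `clean_sao2` replaces artifacts with a single early-record median; a
  record whose baseline drifts far from its first 10 s would be better
  served by a local median, at the cost of the idempotence guarantee.
* The prefix hill-climb stops at the first baseline-matching prefix;
  with strongly redundant informative features this can select very few
  features. That is the stop rule's intent (shortest sufficient subset),
  but it makes the chosen subset sensitive to the lambda ordering among
  near-ties.
* xgboost learners with row subsampling are not invariant to row order;
  determinism is guaranteed for a fixed table, seed and thread count
  (`nthread = 1`).
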