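---
title: "Methods: phoneme-related potentials, convolutional decoding and encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phoneme-related potentials, convolutional decoding and encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prpdecode)
```

## Scientific problem

When listeners process continuous speech, cortical responses time-locked
to individual phonemes carry information about phoneme identity. The
*phoneme-related potential* (PRP) is the average of EEG epochs
time-locked to all instances of one phoneme; the distinctiveness of
these averaged responses across phonemes is a window on how sharply the
cortex differentiates speech sound categories, and a loss of
distinctiveness ("neural dedifferentiation") is a candidate mechanism
for speech-perception difficulties that arise with age despite normal
audiograms. `prpdecode` implements a complete analysis chain for this
question:

1. **PRP extraction** — causal minimum-phase FIR band-pass (1–15 Hz),
   mastoid re-referencing, frequency-based phoneme retention, and
   epoch averaging with an instance cap;
2. **convolutional decoding** — a compact convolutional network
   predicts phoneme labels from PRPs under cross-validation, yielding
   per-participant accuracy and prediction entropy;
3. **relevance analysis** — reference-based attribution of classifier
   decisions to electrodes × time, summarized as relevance dispersion
   and peak latency;
4. **representational similarity** — alignment of neural dissimilarity
   structure with a binary phonetic-feature model
   ([syllabic], [sonorant], [continuant]), forward electrode selection,
   confusion-matrix RDMs with a permutation test, and hierarchical
   clustering of phonemes;
5. **acoustic tracking** — multivariate temporal response functions
   (TRFs) estimated by L1 coordinate boosting, with unique-variance
   partitioning (delta r) and ROI scoring;
6. **statistics** — separability F-curves, cluster-mass permutation
   tests, Welch/Mann-Whitney group tests, rationalized arcsine and
   related behavioral transforms, backward stepwise AIC regression and
   residual group analysis.

Because raw recordings of this kind are rarely redistributable, the
package is built around a synthetic-EEG cohort generator with known
ground truth, so that every stage of the chain is verifiable: decoding
must recover the generative distinctiveness ordering, attribution must
recover the generative spatial spread and latency manipulations,
alignment must recover the feature geometry built into the templates,
and TRF estimation must recover the generative kernels.

## The synthetic cohort generator

Each participant's continuous recording is the sum of three streams:

* **Evoked stream.** The template of phoneme *p* is
  `amp * (C + alpha_i * a_e * (F_p + U_p))`, where `C` is a common
  (phoneme-unspecific) evoked component, `F_p` is the sum of
  feature-indicator components (one damped oscillation with its own
  scalp map per binary feature), `U_p` is a phoneme-unique component
  (smooth random time course × smooth random scalp map, shared across
  the cohort), `alpha_i` is the participant's distinctiveness
  realization, and `a_e` attenuates (by 90%) the electrodes outside the
  top `sigma * E` template-weight electrodes. Templates are inserted at
  annotation onsets (inter-onset intervals uniform on 50–250 ms, so
  responses overlap as in real speech), optionally delayed by the group
  latency shift `tau`.
* **Tracking stream.** Eight band envelopes (smoothed rectified noise)
  and their rectified derivatives are convolved with separable kernels
  (damped-oscillation lag course × scalp gain map).
* **Noise.** A mixture of white and 1/f-shaped Gaussian noise
  (`pink_weight` = 0.6 by default).

Distinctiveness scales the *whole* distinctive part `F_p + U_p` rather
than only the phoneme-unique part: with `alpha = 0` all templates
collapse onto `C` (complete dedifferentiation), and because Spearman
alignment is scale-invariant, group differences in feature alignment
arise through the signal-to-noise ratio of the distinctive part — which
is precisely the dedifferentiation mechanism under study. The feature
components and the phoneme-unique components are centered on the same
time window (about 130 ms), so the distinctive response has a single
dominant lobe and the relevance peak latency is a well-defined
statistic.

Covariates are coupled to the participant-level alpha realizations
through a Gaussian-copula-style construction: each covariate is
`rho * s_i + sqrt(1 - rho^2) * noise` where `s_i` is the
cohort-standardized alpha (standardized with the analytic pooled
moments of the configured groups), which attains the target correlation
`rho` cohort-wide even when groups differ in mean alpha. Nuisance
covariates are independent of alpha.

### Default study conditions

The desk-scale default (`desk_config()`) is a two-group cohort
embodying all the contrasts the analyses are designed to detect:

| parameter | group A ("younger-like") | group B ("older-like") |
|---|---|---|
| distinctiveness alpha | 1.0 | 0.55 |
| spatial spread sigma | 0.6 (localized) | 1.0 (distributed) |
| latency shift tau | 0 ms | 80 ms |

with 10 participants per group, 16 scalp electrodes (+2 mastoids),
12 phonemes (Zipf exponent 1), eight 24 s segments at 128 Hz, noise
6 µV (60% 1/f), and template amplitude 3 µV. `alpha = 0.55` was chosen
so that group B decodes clearly above chance (a few times the uniform
guessing rate, as reported for older listeners), and the noise level so
that the rarest phoneme's PRP (a few dozen instances) retains a usable
signal-to-noise ratio; both were fixed as part of the generator design.
A faithful-scale preset (`full_scale_config()`: 61 electrodes, 31 phonemes,
20 participants per group, fifteen 70 s segments) is provided for
larger runs.

## PRP extraction

Preprocessing applies a windowed-sinc FIR band-pass (1–15 Hz, order
128) converted to minimum phase via the real cepstrum so filtering is
causal with near-zero delay at the pass-band, then subtracts the
mastoid average and drops the mastoid channels. The filter's
coefficients are mean-corrected so DC is rejected exactly.

Phonemes are retained when their instance count *strictly* exceeds 1%
of all instances (configurable, with an exclusion list for dominant
labels). Epochs cover the half-open window [0, 0.5) s after onset —
exactly 64 samples at 128 Hz. Phonemes with more than 319 complete
instances are averaged over a seeded uniform random subset of 319,
removing the frequency-driven SNR advantage of common phonemes; the
selected subset is logged so the average can be reproduced
independently. Epochs that would run past the end of the recording are
dropped and counted. Subsets are re-drawn at every repetition of the
decoding protocol.

## The convolutional decoder

The classifier is a compact convolutional network in the EEGNet-8,2
shape: a temporal convolution (8 filters, kernel length `fs/2`, same
padding), depthwise spatial filtering across electrodes (2 filters per
temporal filter, max-norm ≤ 1), ELU, average pooling (4), dropout 0.5,
a separable convolution (depthwise temporal kernel 16 + pointwise
mixing to 16 channels), ELU, average pooling (8), dropout, and a dense
soft-max. Training minimizes cross-entropy with Adam (initial learning
rate 0.001, decayed by 0.7 every 100 epochs, batch size 16, up to 300
epochs) and the checkpoint with the lowest validation loss predicts the
test fold. Each PRP matrix is standardized by its own mean and standard
deviation before entering the network, removing amplitude confounds
between participants and groups. Arg-max ties resolve to the lowest
label index.

Samples are the (participant × phoneme) PRPs of one group, pooled;
folds are stratified by phoneme so no label is ever absent from
training; per fold a random 15% of the non-test data is the validation
set (re-drawn once, then an error, if a draw empties a label). The
default specification uses 20 folds (5% test); the desk-scale
specification (`desk_classifier_spec()`) uses 4 folds, a 250-epoch cap
and patience-12 early stopping with a 50-epoch minimum — the minimum
guards against stopping on an early noisy plateau of the small
validation set. The repetition protocol (`repeat_protocol()`)
subsamples the larger group to the smaller group's size each
repetition, re-draws the PRP instance subsets, and averages accuracy
and entropy per participant across repetitions.

The training loop is implemented twice: a vectorized R reference
implementation and an operation-for-operation compiled port
(RcppArmadillo) used by default; the test suite verifies that both
produce identical forward passes and identical parameter trajectories
on full-batch runs, and that analytic gradients match finite
differences.

Prediction uncertainty is the Shannon entropy `-sum(p log p)` in nats;
chance accuracy for K phonemes is `100/K` percent (3.23% for the
31-phoneme scale).

## Relevance attribution

Classifier decisions are attributed back to the input with a
rescale-style reference backpropagation against the all-zero input (the
natural rest point of band-passed, baseline-free EEG): linear stages
(convolutions, pooling, the dense layer) propagate through their
weights, and each ELU multiplies by the ratio of output difference to
input difference relative to the reference. For this chain architecture
the completeness axiom — contributions sum to the difference of the
target's pre-soft-max output between input and reference — holds
exactly up to floating point, and is asserted on every call (violation
raises an error, since it can only indicate an implementation bug). A
gradient-times-input rule is provided as a fallback and agrees with the
rescale rule on linear(ized) networks. Each test sample is attributed
by its own test-fold model, so relevance inherits the train/test
separation of decoding.

Per participant, absolute contribution matrices are z-transformed
within matrix (absolute values first, as the dispersion statistic is
about *where* relevance concentrates, not its sign) and averaged across
phonemes and repetitions. Dispersion is the variance (n−1) across
electrodes of time-averaged relevance — smaller means more spatially
distributed relevance; peak latency is the arg-max (earliest tie,
flagged) of the electrode-averaged relevance time course.

## Representational similarity

Feature RDMs are Euclidean distances between 0/1 feature vectors;
neural RDMs are electrode-pattern distances per time step; alignment is
Spearman's rho between strict upper triangles (the diagonal and
duplicate entries carry no information). Constant RDMs are recorded as
rho = 0 with a degeneracy flag. Forward electrode selection starts from
the two most relevant electrodes (relevance-ranked), adds the next
electrode while the overall rho (mean over time and participants)
strictly increases, and stops at the first non-improvement — ties stop
selection. Confusion matrices are row-normalized to conditional
probabilities, symmetrized, and complemented into dissimilarities
(diagonal forced to zero); the group difference in confusion-RDM
alignment is tested by independently shuffling both matrices' rows 5000
times, with the one-sided p reported as the proportion of null
differences smaller than the observed one, exactly as the protocol
prints it — note that under this convention both p near 0 and p near 1
are extreme under the null. Phoneme dendrograms use average-linkage
clustering on PRPs flattened over electrodes × a 0–350 ms window.

## Acoustic tracking

Predictors are 8 log-spaced band envelopes (0.02–5 kHz) and their
half-wave-rectified first differences. In waveform mode a 4th-order
Butterworth band bank stands in for the gammatone filterbank of the
reference implementations and the rectified derivative stands in for
the auditory edge-detection model; synthetic cohorts supply band series
directly, so this approximation only affects the optional waveform
path.

TRFs over lags −100..500 ms are estimated per electrode by L1
coordinate boosting: kernels start at zero; per step, the coordinate
with the largest L1-subgradient correlation (normalized by predictor
scale) receives a fixed-size increment (0.005 × response/predictor
scale ratio), verified by an exact training-error evaluation; each
increment adds a 50 ms Hamming bump along the lag axis (basis
smoothing, implemented by boosting on window-smoothed predictors),
which resolves the identifiability problem sparse increments have with
autocorrelated predictors. Validation uses one rotating training
segment per fold; boosting stops per electrode when the training error
no longer improves or after 10 validation failures, keeping the
best-validation kernel. Folds hold out contiguous segment blocks (3 of
15 at the faithful scale), and test accuracy r is the Pearson
correlation between predicted and observed EEG, averaged over folds.
Unique variance is `delta_r = r_full − r_reduced`; the ROI is the set
of electrodes with delta r significantly greater than zero (one-tailed
one-sample cluster-mass permutation test across all participants), and
each participant's tracking score is the mean delta r over the ROI.

## Statistical layer

* **Separability F-curve**: per time step and electrode, a one-way
  between/within mean-square ratio with phonemes as groups and
  participants as replicates, averaged over electrodes. Undefined
  points (zero within-variance) are flagged, never zeroed.
* **Cluster-mass permutation tests**: mass-univariate t maps
  thresholded at uncorrected p ≤ 0.05, supra-threshold sites joined
  under an adjacency (electrodes within 1.5 × the median
  nearest-neighbor distance, or a chain for time courses), cluster mass
  = summed t, null = maximum absolute cluster mass over sign-flips
  (one-sample, one-tailed) or label exchanges (independent, two-tailed,
  Welch t with per-site Satterthwaite thresholds); t_max reported per
  cluster.
* **Group tests**: Welch's t with Cohen's d and the 95% CI;
  Mann-Whitney U with tie-corrected normal z and no continuity
  correction (the convention adopted where the source protocol does not
  state one).
* **Transforms**: rationalized arcsine units
  `(146/pi)(asin sqrt(x/(n+1)) + asin sqrt((x+1)/(n+1))) − 23`;
  words-in-noise SNR loss `26 − 0.4 n` dB; extended-high-frequency
  thresholds mapped by `log(threshold + 25)` (natural log; base
  unstated in the source).
* **Backward stepwise AIC regression**: predictors z-scored, OLS, AIC
  `n log(RSS/n) + 2(k+1)` (constant terms omitted — only differences
  matter), removing the single predictor whose removal lowers AIC most
  until no removal improves; the removal trace is returned and is
  strictly decreasing by construction. The residuals of the final
  pooled fit are compared between groups with Welch's t (residual
  group analysis).

## Numerical choices and degenerate inputs

* Permutation p values are plain proportions by default (an optional
  add-one smoothing is off, matching the printed convention).
* All-zero TRF predictors yield zero kernels and r = 0 with a flag;
  empty ROIs yield NA scores with a flag; zero-variance attribution
  matrices are excluded from relevance maps with a warning; constant
  RDMs score rho = 0 with a flag; degenerate (constant) group samples
  return flagged trivial test results rather than NaN.
* All randomness descends from user-supplied integer seeds through a
  deterministic child-seed scheme; repeated runs with equal seeds are
  identical.

## Problem sizes used in the shipped checks

The automated checks run the full chain on the desk-scale cohort
(16 electrodes, 12 phonemes, 10+10 participants, eight 24 s segments)
across batches of root seeds, with the 4-fold desk classifier schedule
and two protocol repetitions; TRF recovery uses a two-band, ten-segment
noiseless fixture; cluster-test calibration uses batches of null
topographies at 500 permutations; stepwise-recovery checks use the
covariate layer at n = 40 without EEG synthesis. These sizes are the
package's desk-scale study conditions; the `full_scale_config()` preset
scales every stage up to the faithful geometry.

## What passing on synthetic data does and does not show

The generator reproduces the statistical structure the analyses assume
— feature-organized templates, overlapping evoked responses,
envelope/onset-driven components, 1/f noise, group manipulations of
distinctiveness, spread and latency, covariates with controlled
coupling — but not the full richness of real EEG: no artifacts (the
ASR/ICA cleaning stages of a real pipeline are out of scope), no
participant-specific anatomy or template idiosyncrasies (templates are
shared across a cohort up to scaling), no coarticulation structure in
the annotation stream, and stationary noise. Passing the recovery
checks therefore demonstrates that the implementation detects what it
is supposed to detect when present by construction — not that real
recordings will show these effects.

## Known limitations

* The decoder pools (participant × phoneme) PRPs within group, so
  samples from one participant appear in training and test folds of a
  cross-validation run (in different folds); this matches the printed
  protocol but means decoding accuracy is not a single-participant
  generalization estimate.
* The forward-selection stopping rule is greedy and strict; with noisy
  relevance rankings it can stop early.
* The boosting validation scheme inside each fold (one rotating
  segment) is a documented choice where the reference protocol is
  silent.
* The relevance peak latency (arg-max of the electrode-averaged
  relevance curve) is a high-variance statistic at desk scale: with only
  a couple of dozen attribution matrices per participant the arg-max
  jitters by tens of ms, and group latency contrasts at n = 10 per group
  reach Mann-Whitney significance in most but not all cohort
  realizations. The full-scale protocol (31 phonemes x 20 repetitions)
  averages an order of magnitude more matrices and does not share this
  limitation.
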