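# prpdecode

Tools for quantifying how distinctly the cortex encodes phoneme
categories in continuous-speech EEG — and for detecting the loss of
that distinctiveness ("neural dedifferentiation") between listener
groups.

## What it does

The package implements a complete, testable analysis chain around the
**phoneme-related potential** (PRP): the average of EEG epochs
time-locked to all instances of one phoneme.

* **PRP extraction** — causal minimum-phase FIR band-pass (1–15 Hz),
  mastoid re-referencing, retention of phonemes with > 1% of instances,
  and epoch averaging over the [0, 0.5) s window (61 × 64 arrays at the
  faithful scale) with a 319-instance cap drawn as a seeded random
  subset.
* **Convolutional decoding** — a compact convolutional classifier
  (EEGNet-8,2 shape: 8 temporal filters, 2 spatial filters per temporal
  filter, dropout 0.5) trained with cross-validation to predict phoneme
  labels from PRPs; outputs per-participant accuracy, Shannon
  prediction entropy −Σ p ln p, and confusion matrices, under a
  repetition protocol with group-size balancing.
* **Relevance attribution** — reference-based backpropagation of
  classifier decisions to electrodes × time (completeness-checked),
  summarized as relevance **dispersion** (variance across electrodes of
  time-averaged relevance) and **peak latency**.
* **Representational similarity** — alignment (Spearman rho) of
  time-resolved neural RDMs with a binary phonetic-feature RDM
  ([syllabic], [sonorant], [continuant]), forward electrode selection,
  confusion-matrix RDMs with a row-shuffle permutation test, and
  hierarchical clustering of phonemes.
* **Acoustic tracking** — multivariate temporal response functions over
  lags −100..500 ms estimated by L1 coordinate boosting with
  cross-validation by story segments, unique-variance partitioning
  (Δr), and ROI tracking scores.
* **Statistics** — phoneme-separability F-curves, cluster-mass
  permutation tests (t_max reported per cluster), Welch and
  Mann-Whitney group tests, rationalized arcsine units, words-in-noise
  SNR loss (26 − 0.4 n dB), backward stepwise AIC regression and
  residual group analysis.
* **Synthetic cohorts** — a generator of phoneme-annotated continuous
  EEG with known ground truth (feature-organized evoked templates,
  kernel-driven acoustic tracking, 1/f noise, group manipulations of
  distinctiveness / spatial spread / latency, covariates with
  controlled correlation to distinctiveness), so every stage of the
  chain is verifiable without human recordings.

See the methods vignette (`vignettes/prpdecode-methods.Rmd`) for the
models, conventions and design choices.

## Worked example

```r
library(prpdecode)

cfg <- desk_config(seed = 1)           # 2 groups x 10 participants
coh <- simulate_cohort(cfg)
pre <- lapply(coh$sessions, preprocess)

ann <- do.call(rbind, lapply(coh$sessions, function(s) s$annotations))
retained <- select_phonemes(ann)       # 12 phonemes pass the >1% rule
grp <- vapply(coh$sessions, function(s) s$group, "")

rp <- repeat_protocol(pre[grp == "A"], pre[grp == "B"], retained,
                      desk_classifier_spec(), n_repeats = 2,
                      root_seed = 7, keep_attributions = TRUE)
pt <- rp$participant_table
tapply(pt$accuracy, pt$group, mean)
#>         a         b
#> 0.6791667 0.2958333
group_tests(pt$accuracy[pt$group == "a"],
            pt$accuracy[pt$group == "b"], "mann_whitney")$p
#> [1] 0.0001465688
```

Group A was generated with distinctiveness alpha = 1, group B with
alpha = 0.55: the decoder recovers the ordering — group A's phonemes
are classified far above the 8.33% chance level of 12 classes and
reliably better than group B's, mirroring the younger/older contrast
the analysis chain is designed to detect. The same run yields relevance
maps (`relevance_table(rp$attributions, fs = 128)`), feature alignment
curves (`alignment(neural_rdm_series(prp_set), feature_rdm(inventory))`)
and every downstream statistic.

A full pipeline run with a JSON report:

```r
run_pipeline(desk_config(seed = 1), out_dir = "run1", seed = 1)
```

or from a shell, `Rscript inst/cli/prpdecode.R run-all --seed 1 --out run1`.

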