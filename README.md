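# coughscope

Screening for respiratory disease from the sound of a cough. `coughscope`
is an R implementation of a five-class cough-audio classifier — healthy,
COPD, lung cancer, pneumonia, COVID-19 — built around a channel-attention
residual network (CAM-ResNet18) trained on spectrogram images, with the
full preprocessing, cross-validation, metrics, and noise-robustness
machinery around it. It is aimed at researchers in acoustic digital health
who want a transparent, dependency-light, fully seeded reference pipeline
they can probe end to end.

## The method

Each recording is segmented into 3-second clips (clip longer audio,
zero-pad shorter), pre-emphasized with `y[n] = x[n] − 0.97·x[n−1]`, framed
into 25 ms Hamming windows every 10 ms, and transformed with a 512-point
FFT. Stacking the one-sided magnitude spectra (in dB) gives a 257 × 298
spectrogram image per clip, which is min–max normalized and resized for
the network.

The classifier is an 18-layer residual network whose basic blocks each
carry a channel attention module. For a block output F(x) with C channels,
the attention weights are

    Mc(F) = σ( MLP(AvgPool(F)) + MLP(MaxPool(F)) )

with one shared MLP (C → 256 → 128 → C, ReLU) over the two pooled
descriptors, and the block emits

    Z = Mc · (F(x) + x)

— the channel weights re-scale the feature map after the skip addition.
Training uses softmax cross-entropy, Adam at learning rate 0.001 decayed
×0.1 every 7 epochs, batch size 8, He initialization, and stratified
5-fold cross-validation; reports carry per-class precision, recall, F1 and
specificity with per-fold SD and 95% CI, a pooled confusion matrix, and a
white-noise robustness table at 30/20/10 dB SNR.

The clinical corpus the method was developed on (2610 cough recordings) is
not public, so the package includes a synthetic cough generator — bursts
of resonance-filtered noise with class-specific spectral signatures —
whose default reproduces the corpus shape (5 × 522 clips, 3 s, 16 kHz).
Everything (synthesis, folds, initialization, shuffling, noise) is driven
by explicit seeds.

## Worked example

```r
library(coughscope)

# 1. a small labelled corpus of synthetic coughs (in memory)
corpus <- simulate_corpus(per_class = 100, seed = 42)

# 2. preprocess: normalize, segment to 3 s, pre-emphasize
segs <- list()
for (i in seq_along(corpus$waveforms)) {
  w <- peak_normalize(corpus$waveforms[[i]])
  s <- segment_audio(w, label = corpus$labels[i], source_id = paste0("c", i))
  segs <- c(segs, lapply(s, pre_emphasize))
}

# 3. spectrogram feature images at 64 x 64
feat <- featurize_segments(segs, size = 64)

# 4. 2-fold cross-validated training, 5 epochs per fold (~10 min on one CPU)
cv <- crossval_train(feat$inputs, feat$labels, k = 2,
                     cfg = train_config(epochs = 5, seed = 101),
                     net_cfg = network_config(input_size = 64),
                     fold_seed = 7)
cv$report$pooled
```

```
<metrics: n = 500, accuracy 94.60%, macro F1 94.54%>
        class precision recall    f1 specificity support
1     healthy     99.00     99 99.00       99.75     100
2        copd     95.24    100 97.56       98.75     100
3 lung_cancer    100.00     78 87.64      100.00     100
4   pneumonia     82.35     98 89.50       94.75     100
5     covid19    100.00     98 98.99      100.00     100
```

Each row is one disease class evaluated one-vs-rest on the pooled
out-of-fold predictions (500 clips validated exactly once across the two
folds): after ten minutes of CPU training the model recovers most of the
class-specific spectral signatures — lung cancer, whose resonances sit
between pneumonia's, is the hardest — which is expected, since the default
synthetic classes are separable by construction (see the methods vignette
for what this does and does not demonstrate). A
`default_class_specs("hard")` preset narrows the spectral gaps for
non-saturating comparisons, e.g. of `attention_enabled = TRUE` vs `FALSE`
via `compare_attention()`.

The same pipeline runs from one config — `run_experiment(default_run_config("smoke"))`
— writing histories, metrics, confusion matrix, noise table and an
artifact-hash MANIFEST to a run directory, or from the shell via
`inst/cli/coughscope.R` (`simulate`, `preprocess`, `featurize`, `run`).

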