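# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# A tone segment: unit-amplitude sinusoid at freq_hz.
tone_segment <- function(freq_hz = 1000, rate = 16000, duration_s = 3) {
  n <- round(duration_s * rate)
  segment(sin(2 * pi * freq_hz * (0:(n - 1)) / rate), rate)
}

# Brute-force O(N^2) DFT magnitude oracle: window, zero-pad, direct sum.
dft_mag_oracle <- function(frame, n_fft) {
  L <- length(frame)
  w <- if (L > 1) signal::hamming(L) else rep(1, L)
  xw <- c(frame * w, numeric(n_fft - L))
  ks <- 0:(n_fft / 2)
  vapply(ks, function(k) {
    re <- sum(xw * cos(-2 * pi * k * (0:(n_fft - 1)) / n_fft))
    im <- sum(xw * sin(-2 * pi * k * (0:(n_fft - 1)) / n_fft))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# Small network configuration for fast structural tests.
tiny_net_cfg <- function(...) {
  network_config(stage_channels = c(4, 6, 8, 10), input_size = 16,
                 hidden_sizes = c(8, 6), ...)
}

random_inputs <- function(h, n, seed = 1) {
  set.seed(seed)
  array(runif(h * h * n), c(h, h, n))
}

# A small featurized synthetic dataset (20 clips/class at 32 px), shared by
# training and evaluation tests.
small_feature_set <- function() {
  memo("small_feature_set", function() {
    corpus <- simulate_corpus(per_class = 20, seed = 914)
    segs <- list()
    for (i in seq_along(corpus$waveforms)) {
      w <- peak_normalize(corpus$waveforms[[i]])
      ss <- segment_audio(w, label = corpus$labels[i],
                          source_id = sprintf("fix%03d", i))
      segs <- c(segs, lapply(ss, pre_emphasize))
    }
    c(featurize_segments(segs, size = 32), list(segments = segs))
  })
}

# A quickly trained small model on the small feature set (single split),
# shared by checkpoint/noise tests.
small_trained <- function() {
  memo("small_trained", function() {
    fs <- small_feature_set()
    plan <- make_folds(seq_along(fs$labels), fs$labels, k = 2, seed = 31)
    tr <- which(plan$assignment != 1)
    va <- which(plan$assignment == 1)
    res <- train_model(fs$inputs[, , tr, drop = FALSE], fs$labels[tr],
                       fs$inputs[, , va, drop = FALSE], fs$labels[va],
                       cfg = train_config(epochs = 2, seed = 55),
                       net_cfg = network_config(input_size = 32))
    c(res, list(tr = tr, va = va))
  })
}
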