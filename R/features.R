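# Spectrogram feature images: framing, Hamming window, 512-point FFT,
# dB mapping, and conversion to the fixed-size model input.

#' Slice a segment into overlapping analysis frames
#'
#' Frame i (0-based) contains samples [i*H, i*H + L) for L = frame length and
#' H = hop, both in samples; only complete frames are returned, so the frame
#' count is floor((N - L) / H) + 1.
#'
#' @param s A [segment()] (or any object with `samples` and `sample_rate`).
#' @param frame_len_s Frame length in seconds (default 0.025 = 25 ms).
#' @param hop_s Frame shift in seconds (default 0.010 = 10 ms).
#' @return A `frame_matrix`: list with `frames` (n_frames x L matrix),
#'   `frame_len_s`, `hop_s`, `sample_rate`.
#' @export
frame_signal <- function(s, frame_len_s = 0.025, hop_s = 0.010) {
  x <- s$samples
  L <- round(frame_len_s * s$sample_rate)
  H <- round(hop_s * s$sample_rate)
  if (length(x) < L)
    stopf("segment (%d samples) shorter than one %d-sample frame", length(x), L)
  n_frames <- (length(x) - L) %/% H + 1
  idx <- outer((seq_len(n_frames) - 1) * H, seq_len(L), `+`)
  structure(list(frames = matrix(x[idx], nrow = n_frames, ncol = L),
                 frame_len_s = frame_len_s, hop_s = hop_s,
                 sample_rate = s$sample_rate),
            class = "frame_matrix")
}

#' One-sided magnitude spectrum of a single frame
#'
#' Multiplies the frame by a Hamming window of its own length, zero-pads to
#' `n_fft`, applies the FFT and returns |X(k)| for k = 0..n_fft/2.
#'
#' @param frame Numeric sample vector (length <= n_fft).
#' @param n_fft FFT size (default 512).
#' @return Numeric vector of n_fft/2 + 1 magnitudes.
#' @export
frame_spectrum <- function(frame, n_fft = 512) {
  L <- length(frame)
  if (L > n_fft) stopf("frame length %d exceeds n_fft = %d", L, n_fft)
  w <- if (L > 1) signal::hamming(L) else rep(1, L)
  padded <- c(frame * w, numeric(n_fft - L))
  Mod(stats::fft(padded))[seq_len(n_fft / 2 + 1)]
}

#' Log-magnitude spectrogram image of a segment
#'
#' Frames the segment (25 ms / 10 ms defaults), windows each frame with a
#' Hamming window, zero-pads to `n_fft` and FFTs, then stacks the one-sided
#' magnitude spectra as columns and maps to decibels,
#' 20*log10(|X| + eps). Deterministic: identical input gives a bit-identical
#' array.
#'
#' @inheritParams frame_signal
#' @param n_fft FFT size (default 512).
#' @param eps Floor added before the log so all dB values are finite.
#' @return A `spectrogram_image`: list with `values`
#'   ((n_fft/2 + 1) x n_frames dB matrix, row 1 = 0 Hz), `freq_resolution`
#'   (Hz/bin), `time_resolution` (s/frame), `n_fft`, `eps`.
#' @export
spectrogram_image <- function(s, frame_len_s = 0.025, hop_s = 0.010,
                              n_fft = 512, eps = 1e-10) {
  fm <- frame_signal(s, frame_len_s, hop_s)
  L <- ncol(fm$frames)
  if (L > n_fft) stopf("frame length %d exceeds n_fft = %d", L, n_fft)
  w <- if (L > 1) signal::hamming(L) else rep(1, L)
  # frames as columns, windowed, zero-padded to n_fft, one FFT call
  padded <- rbind(t(fm$frames) * w, matrix(0, n_fft - L, nrow(fm$frames)))
  mag <- Mod(stats::mvfft(padded))[seq_len(n_fft / 2 + 1), , drop = FALSE]
  structure(list(values = 20 * log10(mag + eps),
                 freq_resolution = s$sample_rate / n_fft,
                 time_resolution = hop_s, n_fft = n_fft, eps = eps),
            class = "spectrogram_image")
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram: %d freq bins x %d frames, %.1f Hz/bin, %g s/frame>\n",
              nrow(x$values), ncol(x$values), x$freq_resolution, x$time_resolution))
  invisible(x)
}

#' Convert a spectrogram image to the model input tensor
#'
#' Min–max normalizes the dB values to [0, 1] per image (a constant image
#' maps to all zeros) and bilinearly resizes to `size`.
#'
#' @param img A [spectrogram_image()] or a plain dB matrix.
#' @param size Target (height, width) in pixels; a scalar means square.
#' @return `size[1]` x `size[2]` numeric matrix in [0, 1].
#' @export
spectrogram_to_input <- function(img, size = c(224, 224)) {
  v <- if (inherits(img, "spectrogram_image")) img$values else img
  if (length(size) == 1) size <- c(size, size)
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  if (!all(dim(v) == size)) {
    v <- EBImage::resize(EBImage::Image(v), w = size[1], h = size[2])
    v <- as.matrix(EBImage::imageData(v))
  }
  pmin(pmax(v, 0), 1)
}

#' Export a spectrogram as an 8-bit grayscale PNG
#'
#' Maps dB linearly to gray with darker pixels for higher amplitudes, low
#' frequencies at the bottom of the image.
#'
#' @param img A [spectrogram_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_spectrogram_png <- function(img, path) {
  stopifnot(inherits(img, "spectrogram_image"))
  v <- img$values
  rng <- range(v)
  norm <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  gray <- 1 - norm                      # darker = higher amplitude
  gray <- gray[rev(seq_len(nrow(gray))), , drop = FALSE]  # low freq at bottom
  png::writePNG(gray, path)
  invisible(path)
}

#' Save / load a batch of feature arrays with a JSON sidecar
#'
#' The archive stores the input tensors plus labels; the sidecar records the
#' extraction parameters so a run is reproducible from its artifacts.
#'
#' @param inputs 3D array (H x W x N) of model inputs.
#' @param labels Integer class indices (1-based), length N.
#' @param path Output path (`.rds`); sidecar written to `<path>.json`.
#' @param params Named list of extraction parameters to record.
#' @return `path`, invisibly.
#' @export
save_feature_archive <- function(inputs, labels, path, params = list()) {
  saveRDS(list(inputs = inputs, labels = labels), path)
  jsonlite::write_json(c(list(n = length(labels), dim = dim(inputs)), params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_feature_archive
#' @export
load_feature_archive <- function(path) readRDS(path)

#' Featurize a list of segments into a model-input batch
#'
#' @param segments List of [segment()] objects.
#' @param size Model input size (pixels).
#' @param ... Passed to [spectrogram_image()].
#' @return List with `inputs` (H x W x N array) and `labels` (integer
#'   indices into [cough_classes()], NA where unlabelled).
#' @export
featurize_segments <- function(segments, size = c(224, 224), ...) {
  if (length(size) == 1) size <- c(size, size)
  n <- length(segments)
  inputs <- array(0, dim = c(size[1], size[2], n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    inputs[, , i] <- spectrogram_to_input(spectrogram_image(segments[[i]], ...), size)
    labels[i] <- if (is.null(segments[[i]]$label)) NA_integer_
                 else match(segments[[i]]$label, COUGH_CLASSES)
  }
  list(inputs = inputs, labels = labels)
}
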