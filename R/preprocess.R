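# Segmentation into fixed-length clips and pre-emphasis filtering.

#' Construct an audio segment
#'
#' A segment is a fixed-length clip (exactly `round(duration_s * sample_rate)`
#' samples once produced by [segment_audio()]), optionally carrying a class
#' label and a provenance id.
#'
#' @param samples Numeric amplitude vector.
#' @param sample_rate Rate in Hz.
#' @param label Optional class label (one of [cough_classes()]).
#' @param source_id Optional provenance string.
#' @return An object of class `segment`.
#' @export
segment <- function(samples, sample_rate, label = NULL, source_id = NULL) {
  if (!is.null(label) && !label %in% COUGH_CLASSES)
    stopf("unknown label '%s'; expected one of: %s", label,
          paste(COUGH_CLASSES, collapse = ", "))
  structure(list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
                 label = label, source_id = source_id),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment: %d samples @ %g Hz%s%s>\n", length(x$samples), x$sample_rate,
              if (is.null(x$label)) "" else paste0(", label=", x$label),
              if (is.null(x$source_id)) "" else paste0(", src=", x$source_id)))
  invisible(x)
}

#' Cut a waveform into fixed-duration segments
#'
#' Consecutive non-overlapping windows of `duration_s` seconds are taken.
#' A trailing remainder at least `min_keep_s` seconds long is zero-padded to
#' full length (trailing zeros); shorter remainders are dropped. An input
#' shorter than one window yields exactly one zero-padded segment.
#'
#' @param w A [waveform()].
#' @param duration_s Segment duration in seconds (default 3).
#' @param min_keep_s Minimum remainder worth keeping, seconds (default 0.5).
#' @param label,source_id Passed through to every [segment()].
#' @return List of [segment()] objects.
#' @export
segment_audio <- function(w, duration_s = 3.0, min_keep_s = 0.5,
                          label = NULL, source_id = NULL) {
  stopifnot(inherits(w, "waveform"))
  if (length(w$samples) == 0) stopf("cannot segment an empty waveform")
  if (duration_s <= 0) stopf("duration_s must be positive")
  L <- round(duration_s * w$sample_rate)
  n <- length(w$samples)
  n_full <- n %/% L
  rem <- n - n_full * L

  pieces <- list()
  for (i in seq_len(n_full)) {
    pieces[[i]] <- w$samples[((i - 1) * L + 1):(i * L)]
  }
  keep_rem <- (n_full == 0) || (rem >= round(min_keep_s * w$sample_rate) && rem > 0)
  if (keep_rem && (rem > 0 || n_full == 0)) {
    tail_part <- if (rem > 0) w$samples[(n_full * L + 1):n] else numeric(0)
    pieces[[length(pieces) + 1]] <- c(tail_part, numeric(L - length(tail_part)))
  }
  lapply(seq_along(pieces), function(i) {
    sid <- if (is.null(source_id)) NULL else sprintf("%s#%d", source_id, i)
    segment(pieces[[i]], w$sample_rate, label = label, source_id = sid)
  })
}

#' Apply pre-emphasis filtering
#'
#' First-order high-pass filter y[n] = x[n] - mu * x[n-1] (y[1] = x[1]),
#' boosting high frequencies before spectral analysis. The coefficient is
#' restricted to the conventional range [0.9, 1] unless `allow_any_mu`.
#'
#' @param s A [segment()] (or [waveform()]).
#' @param mu Pre-emphasis coefficient, default 0.97.
#' @param allow_any_mu Set TRUE to permit coefficients outside [0.9, 1].
#' @return Object of the same class with filtered samples.
#' @export
pre_emphasize <- function(s, mu = 0.97, allow_any_mu = FALSE) {
  if (!allow_any_mu && (mu < 0.9 || mu > 1))
    stopf("pre-emphasis coefficient %g outside [0.9, 1]; set allow_any_mu = TRUE to override", mu)
  x <- s$samples
  if (length(x) == 0) stopf("cannot pre-emphasize an empty signal")
  s$samples <- x - mu * c(0, x[-length(x)])
  s
}

#' Invert pre-emphasis
#'
#' Exact inverse of [pre_emphasize()]: y'[n] = y[n] + mu * y'[n-1].
#'
#' @inheritParams pre_emphasize
#' @return Object with the original samples restored (to rounding).
#' @export
de_emphasize <- function(s, mu = 0.97) {
  y <- s$samples
  s$samples <- as.numeric(signal::filter(1, c(1, -mu), y))
  s
}

#' Read a dataset manifest CSV
#'
#' The manifest maps audio files to labels; required columns `file` and
#' `label`, optional `subject_id` and any extras. Paths are interpreted
#' relative to `dir` when given.
#'
#' @param path CSV path (header row required).
#' @param dir Optional directory to resolve `file` against.
#' @return data.frame with at least columns file, label.
#' @export
read_manifest <- function(path, dir = NULL) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(m)))
    stopf("manifest %s must have 'file' and 'label' columns", path)
  bad <- setdiff(unique(m$label), COUGH_CLASSES)
  if (length(bad))
    stopf("manifest has unknown labels: %s", paste(bad, collapse = ", "))
  if (!is.null(dir)) m$file <- file.path(dir, m$file)
  m
}

#' Preprocess a manifest of recordings into labelled segments
#'
#' Loads each WAV, optionally trims silence, peak-normalizes, segments to
#' `duration_s`, and applies pre-emphasis.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param rate Target sample rate (Hz); inputs at other rates are resampled.
#' @param duration_s Segment duration (s).
#' @param mu Pre-emphasis coefficient; `NA` skips pre-emphasis.
#' @param trim Apply the optional [trim_silence()] stage (default FALSE).
#' @return List of [segment()] objects (one recording may yield several).
#' @export
preprocess_manifest <- function(manifest, rate = 16000, duration_s = 3.0,
                                mu = 0.97, trim = FALSE) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    w <- load_wav(manifest$file[i], target_rate = rate)
    if (trim) w <- trim_silence(w)
    w <- peak_normalize(w)
    segs <- segment_audio(w, duration_s = duration_s,
                          label = manifest$label[i],
                          source_id = basename(manifest$file[i]))
    if (!is.na(mu)) segs <- lapply(segs, pre_emphasize, mu = mu)
    out <- c(out, segs)
  }
  out
}
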