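# RIFF/WAVE reading and writing (PCM 8/16/32-bit and IEEE float32).
# Hand-written on readBin/writeBin: no WAV package is among this package's
# dependencies, and the subset of the format needed here is small and fixed.

#' Construct a Waveform
#'
#' A waveform is a mono sequence of amplitudes (nominally in [-1, 1]) plus a
#' sample rate in Hz; the unit of all audio preprocessing.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stopf("samples must be numeric")
  if (length(samples) == 0) stopf("waveform must be non-empty")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stopf("sample_rate must be a single positive number")
  structure(list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), peak %.4f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Read a WAV file as a mono waveform
#'
#' Parses a RIFF/WAVE file (PCM 8/16/32-bit integer or IEEE float32).
#' Multi-channel audio is averaged to mono; integer PCM is rescaled to
#' [-1, 1]. If `target_rate` differs from the file's rate the signal is
#' polyphase-resampled and the original rate recorded in attributes.
#'
#' @param path Path to a .wav file.
#' @param target_rate Optional rate in Hz to resample to (default: keep).
#' @return A [waveform()].
#' @export
load_wav <- function(path, target_rate = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  if (!identical(riff, "RIFF")) stopf("not a RIFF/WAV file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- rawToChar(readBin(con, "raw", 4))
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("corrupt WAV (missing fmt/data chunk): %s", path)
  if (fmt$audio_format == 65534) stopf("WAVE_FORMAT_EXTENSIBLE is not supported: %s", path)

  x <- switch(as.character(fmt$audio_format),
    "1" = switch(as.character(fmt$bits),
      "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1, signed = FALSE)) - 128) / 128,
      "16" = readBin(data_raw, "integer", length(data_raw) %/% 2, 2, signed = TRUE,
                     endian = "little") / 32768,
      "32" = readBin(data_raw, "integer", length(data_raw) %/% 4, 4,
                     endian = "little") / 2147483648,
      stopf("unsupported PCM bit depth: %d", fmt$bits)),
    "3" = readBin(data_raw, "double", length(data_raw) %/% 4, 4, endian = "little"),
    stopf("unsupported WAV audio format code: %d", fmt$audio_format))

  if (length(x) == 0) stopf("empty audio in %s", path)
  if (fmt$n_channels > 1) {
    usable <- (length(x) %/% fmt$n_channels) * fmt$n_channels
    x <- colMeans(matrix(x[seq_len(usable)], nrow = fmt$n_channels))
  }
  w <- waveform(x, fmt$sample_rate)
  if (!is.null(target_rate) && target_rate != fmt$sample_rate) {
    w <- resample_waveform(w, target_rate)
    attr(w, "native_rate") <- fmt$sample_rate
  }
  w
}

#' Write a mono waveform to a WAV file
#'
#' @param w A [waveform()]; samples are clipped to [-1, 1] for PCM output.
#' @param path Output path.
#' @param bits 16 for PCM16 (default) or "float" for IEEE float32.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(w$samples)
  is_float <- identical(bits, "float")
  bytes_per <- if (is_float) 4L else 2L
  data_size <- n * bytes_per

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (is_float) 3 else 1), con, 2, endian = "little")  # format code
  writeBin(1L, con, 2, endian = "little")                                  # mono
  writeBin(as.integer(w$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(w$sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(8 * bytes_per), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (is_float) {
    writeBin(w$samples, con, 4, endian = "little")
  } else {
    q <- as.integer(pmin(pmax(round(w$samples * 32768), -32768), 32767))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}

#' Peak-normalize a waveform
#'
#' Scales so the maximum absolute amplitude is exactly 1. An all-zero signal
#' is returned unchanged. Idempotent.
#'
#' @param w A [waveform()].
#' @return Normalized [waveform()].
#' @export
peak_normalize <- function(w) {
  stopifnot(inherits(w, "waveform"))
  pk <- max(abs(w$samples))
  if (pk == 0) return(w)
  w$samples <- w$samples / pk
  w
}

#' Resample a waveform to a new rate (polyphase)
#'
#' @param w A [waveform()].
#' @param new_rate Target rate in Hz.
#' @return Resampled [waveform()].
#' @export
resample_waveform <- function(w, new_rate) {
  stopifnot(inherits(w, "waveform"))
  if (new_rate == w$sample_rate) return(w)
  g <- gcd_int(round(new_rate), round(w$sample_rate))
  p <- round(new_rate) / g
  q <- round(w$sample_rate) / g
  y <- signal::resample(w$samples, p, q)
  waveform(as.numeric(y), new_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Trim low-energy leading/trailing audio
#'
#' Optional stand-in for manual endpoint editing: drops leading and trailing
#' 25 ms frames whose RMS falls below `threshold` times the peak frame RMS.
#' Off by default throughout the pipeline.
#'
#' @param w A [waveform()].
#' @param frame_s Analysis frame length in seconds.
#' @param threshold Fraction of peak frame RMS below which a frame counts as
#'   silence.
#' @return Trimmed [waveform()] (unchanged if everything is below threshold).
#' @export
trim_silence <- function(w, frame_s = 0.025, threshold = 0.01) {
  stopifnot(inherits(w, "waveform"))
  L <- max(1L, round(frame_s * w$sample_rate))
  nf <- length(w$samples) %/% L
  if (nf < 2) return(w)
  m <- matrix(w$samples[seq_len(nf * L)], nrow = L)
  rms <- sqrt(colMeans(m^2))
  keep <- rms >= threshold * max(rms)
  if (!any(keep)) return(w)
  first <- which(keep)[1]; last <- max(which(keep))
  lo <- (first - 1) * L + 1
  hi <- min(length(w$samples), last * L)
  if (last == nf) hi <- length(w$samples)  # keep the ragged tail
  waveform(w$samples[lo:hi], w$sample_rate)
}
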